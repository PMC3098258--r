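---
title: "Gene-phenotype association networks: models and methods"
author: "phenonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-phenotype association networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Model-organism phenotype repositories annotate gene knockouts with
terms from a phenotype ontology (for the laboratory mouse, the
Mammalian Phenotype ontology, a rooted DAG in which "level 1" terms —
the children of the root — name broad phenotype domains and deeper
terms are increasingly granular). Such annotations define a bipartite
graph linking genes to phenotype terms: genes are related through the
phenotypes they share, and phenotypes through the genes that produce
them. phenonet turns ontology-annotated gene-phenotype associations
into weighted gene-gene and phenotype-phenotype networks, extracts
and characterises their community structure, tests communities for
functional coherence against resampled controls, maps them to
high-level phenotype groups and across networks, and clusters
high-level phenotypes by gene sharing.

Everything operates on plain-text inputs (OBO 1.2 ontologies,
two-column annotation TSVs, matrices as TSV), and a synthetic-data
generator with planted module structure makes every stage testable
without any external download.

## Ontology levels and granularity weights

A term's level is its shortest-path distance from the root (root
children = level 1). For multi-parent terms the paths can disagree;
we take the shortest, the common convention in ontology analysis, and
it makes levels deterministic. Only `is_a` relationships define the
DAG; other relationship types are ignored, and obsolete terms are
dropped at parse time.

For a term $j$, let $n_j$ be the number of strict descendants of $j$
(reachable through any parent path) carrying at least one annotation
in the data set. The granularity weight is, by default,

$$g_j = \frac{1}{1 + n_j},$$

so that broad terms with large annotated subtrees are down-weighted
and specific annotations dominate. The alternative `"linear"` scheme
$g_j = 1 + n_j$ weights terms *up* with their annotated subtree and is
kept because the opposite convention is also defensible when broad
coverage, not specificity, should drive the signal; the scheme is
recorded on the ontology object so a run is self-describing.

Annotation usage peaks at intermediate levels (level 5 for curated
mouse phenotype data), which motivates analysing the biadjacency
matrix at the most frequently used level; `levelUsageHistogram()`
reports the peak for any data set.

## The weighted biadjacency matrix

At analysis level $L$, the matrix $B$ has genes as rows and level-$L$
terms as columns:

$$B_{ij} = \sum_{t \in T_{ij}} g_t,$$

where $T_{ij}$ are the annotated terms of gene $i$ that are
descendants-or-self of column term $j$. A term exactly at level $L$
counts as its own descendant-or-self (otherwise level-$L$ annotations
would be silently discarded; `includeSelf = FALSE` restores the
strictly-below reading). Multi-parent terms can have several level-$L$
ancestors and then contribute to every qualifying column — one
annotation, several columns, by design. Columns that receive no
contribution are dropped; row and column order is lexicographic so
all outputs are deterministic.

Transposing $B$ swaps the roles of genes and phenotype terms, and the
entire downstream pipeline applies unchanged to $B^\top$ — the
phenotype-phenotype network is literally the gene pipeline run on the
transpose, not a second implementation.

## The pairwise association score d

For two genes $i_1, i_2$ and a level-$L$ phenotype $j$, let $u$ and
$v$ be their granularity-weight profiles over the annotated
descendant-or-self terms of $j$ (the data-set-wide domain; entries are
$g_t$ where the gene is annotated to $t$, 0 elsewhere). The
per-phenotype similarity is the two-sided two-sample Wilcoxon rank-sum
p-value of $u$ against $v$: identical profiles give $p = 1$, strongly
divergent profiles give small $p$. All pair-by-phenotype p-values are
pooled and FDR-corrected (Benjamini-Hochberg by default) into
similarities $q$, and

$$d_{i_1 i_2} = \frac{1}{|\,\mathrm{columns}\,|} \sum_j q_{i_1 i_2, j}$$

averages over *all* level-$L$ columns, so $d \in [0, 1]$ and scales
with the number of phenotypes a pair shares — with a few hundred
columns, meaningful associations sit at $d$ of order $10^{-3}$ to
$10^{-1}$, which is where the shipped reference cut-offs for the
published mouse networks live (`referenceCutoffs()`).

**Gating.** Which columns are scored for a pair is the one genuinely
open design point, exposed as the `gating` argument. The canonical
default, `"shared"`, scores only columns under which *both* genes are
annotated; unshared columns contribute 0. This makes the score's
contract exact — genes sharing no level-$L$ phenotype have $d = 0$,
annotation-identical genes are maximal among their pairs — and keeps
$d$ proportional to the FDR-weighted count of shared phenotypes. The
alternative `"either"` also scores one-sided columns (one gene
annotated, the other's profile all zero). We measured the latter on
planted-module data: one-sided columns dominate the pooled collection,
Benjamini-Hochberg inflates their small p-values toward the middle of
the scale, and $d$ degrades into a measure of total annotation volume
(planted-module recovery collapses from ARI $\approx 1$ to
ARI $\approx 0.06$). `"shared"` is therefore the default; `"either"`
remains available for sensitivity analysis.

The rank-sum p-value uses the exact null distribution for tie-free
samples of up to 10 per side and the normal approximation with tie and
continuity correction otherwise (the hot loop runs a dedicated
implementation, unit-tested against `stats::wilcox.test()`).
Degenerate comparisons — every observation tied — return $p = 1$,
which is the correct "indistinguishable" reading. For tractability,
pair enumeration is restricted to pairs sharing at least one column;
all other pairs are $d = 0$ by construction.

## Networks, cut-offs, topology

`buildNetwork()` keeps edges with $d \ge d_\mathrm{cutoff}$ and drops
isolated nodes. Cut-offs for real data were historically chosen by
inspecting the $d$ distribution; `suggestCutoff()` automates this as
an upper quantile (default 0.9; the packaged analyses use 0.8) of the
nonzero scores. On planted data this threshold cleanly separates
within-module from between-module pairs.

Topology diagnostics are classical unweighted quantities on the
binarized graph: the empirical degree distribution $P(k)$, local
clustering coefficients $C_i$ (degree-<2 nodes get $C = 0$), and
$C(k)$, the mean coefficient at degree $k$. The scale-free exponent
$\gamma$ is minus the slope of the least-squares line on the log-log
plot of $P(k)$ — the line-of-best-fit convention, chosen deliberately
over maximum-likelihood fitting to match how such networks have been
characterised; `fit_r2` qualifies how linear the plot actually is,
and fewer than three distinct positive degrees flags the fit as
degenerate rather than reporting a meaningless slope.

Significance of clustering and modularity is assessed against
degree-preserving rewiring nulls: each replicate applies repeated
double-edge swaps (10 per edge by default, rejecting self-loops and
multi-edges), so the degree multiset is preserved exactly — the
implementation verifies this per replicate rather than assuming it.
One-sided empirical p-values report the fraction of replicates whose
mean clustering coefficient or spectral modularity reaches the
observed value.

## Spectral community extraction

Communities come from recursive leading-eigenvector bisection of the
modularity matrix $\mathbf{B} = A - \mathbf{k}\mathbf{k}^\top / 2m$
(generalized form for subgroups), accepting a split only when it
increases $Q = \sum_c (e_{cc} - a_c^2)$, with a Kernighan-Lin-style
refinement sweep after each split (on by default; each pass greedily
moves every vertex once and keeps the best intermediate state).
Numerical choices that make the result deterministic: vertices are
processed in sorted name order, the dense symmetric eigensolver is
used (networks here are at most a few thousand nodes), zero
eigenvector entries join the $+$ group, the eigenvector's sign is
fixed by placing the lexicographically smallest vertex in the $+$
group, and a subgroup whose leading eigenvalue is non-positive (below
$10^{-10}$) is indivisible. Community detection runs on the binarized
graph; $Q$ is always recomputed independently from the final labels.

Hubs are nodes with degree strictly above the 80th percentile of the
degree distribution — "strictly" means a regular graph has no hubs.

## Enrichment against resampled controls

For a similarity matrix (expression correlation, binary
tissue-expression correlation, phylogenetic-profile correlation, or a
$d$ matrix computed on Gene Ontology annotations), the within vector
pools the values of all unordered within-community pairs, and the
control pools the same quantity from pseudo-communities of identical
sizes resampled from the network's gene set (1000 replicates by
default; the test suite uses 100-200 for speed). A one-sided
two-sample Wilcoxon test asks whether within values are
stochastically greater. Expression, tissue and phylogenetic
similarity all use Pearson correlation; phylogenetic profiles are
integer copy-number vectors per species. GO similarity runs the full
$d$ pipeline per branch at the branch's most used level (biological
process 5, cellular component 5, molecular function 2 by default).

Protein interactions are counted, not averaged: the observed
statistic is the number of physical-interaction pairs falling inside
a community (evidence filtered to the 14 physical experimental-system
labels), and the null is the same count in independently resampled
pseudo-communities. The reported p-value is by default the
normal-theory upper tail of the null count distribution at the
observed value (`test = "ztail"`). The classical one-sample Wilcoxon
of null counts against the observed value is available
(`test = "signed-rank"`) but is not the default because the observed
count is itself random under the null: the signed-rank construction
is then miscalibrated (simulations in the test suite show
$P(p < 0.05) \approx 0.3$ on structure-free data), while the plain
resampling rank p (`test = "empirical"`) is floor-limited at
$1/(n_\mathrm{boot}+1)$. The normal tail is continuous, calibrated
under exchangeability (the count is a sum of many pair indicators, so
the CLT applies), and agrees with the empirical p where both are
informative.

Hub function is tested per GO term with a one-tailed Fisher's exact
test of hub membership against term annotation over the network's
gene universe (the global background; a per-community background is a
documented alternative the package does not default to), with BH
q-values. Level-1 term sharing within communities is summarised by
binning each gene pair's shared level-1 term count as
$\{0, 1, 2, \ge 3\}$ and testing the within-community rows against
all pairs in a $2 \times 4$ independence layout — 3 degrees of
freedom, the layout that matches how such sharing tables are
reported; the binning is configurable in the one place it is defined.

## Community mapping

A gene's level-1 group is the argmax column of its level-1
biadjacency row (ties yield an explicit sentinel, all-zero rows are
unassigned). The probability that a community of size $x$ and a group
of size $y$ drawn independently and uniformly from an $N$-gene
universe intersect in exactly $z$ genes is hypergeometric,

$$P(Z = z) = \binom{x}{z}\binom{N - x}{y - z}\Big/\binom{N}{y},$$

and assignments are scored by the upper tail $P(Z \ge z_\mathrm{obs})$,
displayed as $-\log_{10} p$. The implementation is verified against
exhaustive enumeration of all subset pairs for every $N \le 8$.
Cross-network community comparison uses the same tail probability on
the common (orthology-mapped) universe, or the symmetric mean overlap
fraction $\bar p = (z/x + z/y)/2$. Heat-map rows are ordered by
hierarchical clustering of the $-\log p$ rows with Euclidean
distances.

## Clustering high-level phenotypes with AU support

Level-1 terms are clustered by gene sharing: distance
$1 - \mathrm{cor}$ between raw weighted biadjacency columns (a
zero-variance column has no defined correlation and is placed at
maximal distance 1, with a warning), average linkage. Support comes
from multiscale bootstrap: gene rows are resampled with replacement
at scales $r \in \{0.5, 0.6, \ldots, 1.4\}$ of the row count
(replicates split evenly across scales; shipped default
$10^4$ total, tests use $10^3$), each observed cluster's recovery
frequency $\mathrm{BP}_r$ is recorded, and the approximately unbiased
value extrapolates the signed distance via weighted least squares on

$$z_r = \Phi^{-1}(1 - \mathrm{BP}_r) = v\sqrt{r} + c/\sqrt{r},
\qquad \mathrm{AU} = 1 - \Phi(v - c),$$

with binomial weights. BP is reported at the scale nearest 1.
Clusters recovered identically at every scale have no cross-scale
information and take $\mathrm{AU} = \mathrm{BP}$; the root cluster has
support 1 by definition; BP values at the boundary are clamped by
half a count before the probit transform. Bootstrapping resamples
*rows* (genes) because the tree lives on term columns and gene
sharing is what the distances measure. Clustering at levels other
than 1 works mechanically but is not part of the package's validated
scope.

## The synthetic generator

`syntheticConfig()` defaults define the package's study conditions:
300 genes in 5 equal modules; a depth-8 ontology with 8 level-1
subtrees, binary branching (~2000 terms) and a 3% multi-parent rate
(the extra parent is drawn from the same upper level so term levels
stay well-defined); Poisson(8) annotations per gene with level
targeted around the mid-ontology usage peak; module fidelity 0.9 and
pleiotropy noise rate 0.05. Auxiliary data are planted to mirror the
enrichment hypotheses: expression by a shared per-module factor
(within-module correlation 0.6 over 50 samples), binary tissue
expression biased to module-preferred tissues (0.8 vs 0.1
background), two-density PPI blocks (0.15 within, 0.01 between, plus
~8% decoy rows carrying non-physical evidence labels to exercise the
filter), integer phylogenetic copy-number profiles copying a module
base profile with probability 0.7, and three GO branches (depths
6/6/3 so the 5/5/2 analysis levels exist) with module-coherent
annotations. `nullBundle()` keeps the marginals but removes every
planted effect (fidelity at chance, zero correlations, equal PPI
densities) for type-I-error checks. Output is byte-identical for
identical configs, with a manifest of file digests.

What the generator does *not* emulate matters for interpreting green
tests: real annotation is sparse, biased by research attention, and
has heavy-tailed per-gene annotation counts; real gene networks are
scale-free (the planted networks are dense module blobs, so the
$\gamma$ estimate on synthetic data is honest but meaningless);
ontology structure is far less regular than a near-uniform tree; and
module sizes in nature are not equal. Passing recovery and
calibration tests demonstrates that the machinery measures what it
claims under known truth — not that mouse data will show any
particular effect size.

## Problem sizes and budgets

The shipped analyses and tests run at desk scale by choice: the
planted acceptance bundle uses the 300-gene defaults with analysis
level 3 (32 level-1-subtree-derived columns), enrichment at 100-200
resampling replicates, rewiring nulls at 200-1000 replicates, and
bootstrap cluster support at 1000-5000 replicates; published-scale
defaults (1000 rewires, $10^4$ bootstrap replicates) remain the
function defaults. Determinism is end-to-end: every stochastic stage
derives its own seed from the run seed, and rerunning a pipeline
configuration reproduces byte-identical artifacts.

## Known limitations

The per-phenotype Wilcoxon compares weight *profiles*, not term
identity: two genes annotated to disjoint but similarly sized term
sets under the same phenotype class are similar for that class. This
is intentional (sharing the class is the signal) but means $d$ cannot
separate sub-structure within a single level-$L$ subtree; analyse at
a deeper level when that matters. Pooled FDR correction treats all
pair-phenotype tests as one family; a per-phenotype family is a
plausible alternative the package does not implement. The
hypergeometric overlap model assumes communities and groups are
unordered samples from a shared universe, which ignores degree
structure; and all topology diagnostics binarize edge weights.
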