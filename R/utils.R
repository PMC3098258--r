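# Shared helpers: deterministic TSV IO and small utilities.

# Deterministic TSV writer: fixed column order, no quoting surprises,
# full precision via format(..., digits = 15) for numerics.
writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA"
      else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, header = TRUE, comment = "#") {
  utils::read.table(path, sep = "\t", header = header,
                    comment.char = comment, stringsAsFactors = FALSE,
                    quote = "", check.names = FALSE)
}

# Write a labelled numeric matrix as TSV with a leading id column.
writeMatrixTsv <- function(m, path, idCol = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idCol, colnames(m))
  writeTsv(df, path)
}

readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# Canonical unordered-pair key (a < b lexicographically).
pairKey <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "\r")
}

# Derive a child seed from a base seed and a stage tag, staying < 2^31.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}
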