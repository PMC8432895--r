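`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalise taxon names for cross-table matching
#'
#' Taxon labels arriving from different sources (tree tip labels, matrix
#' headers, classification tables) often differ only in whitespace; spaces are
#' mapped to underscores and surrounding whitespace trimmed so that exact
#' string matching can be used everywhere downstream.
#'
#' @param x character vector of taxon labels.
#' @return character vector of normalised labels.
#' @export
normalize_taxon_names <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}

## Stable numeric formatting for machine outputs: 10 significant digits keeps
## re-run diffs byte-identical without printing platform noise.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Square labelled matrix TSV: first column + header row carry taxon names.
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2, format_num))
  colnames(df) <- colnames(m)
  df <- cbind(taxon = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labelled matrix from TSV/CSV
#'
#' Accepts the layouts used for pairwise score and distance matrices: a header
#' row of taxon names and either a leading label column or row names. The
#' separator is sniffed from the first line (tab beats comma).
#'
#' @param path file path.
#' @return numeric matrix with matching row and column names.
#' @export
read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (!is.numeric(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- normalize_taxon_names(rownames(m))
  colnames(m) <- normalize_taxon_names(colnames(m))
  if (nrow(m) != ncol(m)) {
    stop("matrix in '", path, "' is not square (", nrow(m), " x ", ncol(m), ")")
  }
  m
}
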