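#' Shared single-copy genes between two genomes
#'
#' Intersection of the gene_id sets of two prepared maps (single-copy,
#' chromosome-localised loci with coordinates). Missing genes in either genome
#' are thereby discarded from the comparison.
#'
#' @param map_a,map_b [gene_map()] objects.
#' @return character vector of shared gene_ids.
#' @export
shared_single_copy <- function(map_a, map_b) {
  a <- map_a$loci$gene_id[!is.na(map_a$loci$start)]
  b <- map_b$loci$gene_id[!is.na(map_b$loci$start)]
  shared <- intersect(a, b)
  if (length(shared) == 0L) {
    stop("no comparable genes between '", map_a$taxon_id, "' and '",
         map_b$taxon_id, "'")
  }
  shared
}

## Neighbour matrix: for each gene of the shared-restricted per-sequence
## orders, up to k gene_ids on each flank (NA past sequence ends). Rows are
## named by focal gene. Columns 1..k upstream (nearest first), k+1..2k
## downstream.
neighbor_matrix <- function(map, shared, k = 2L) {
  loci <- map$loci[!is.na(map$loci$start) & map$loci$gene_id %in% shared, ,
                   drop = FALSE]
  ord <- order(loci$seq_id, loci$start, loci$end, loci$gene_id,
               method = "radix")
  g <- loci$gene_id[ord]
  s <- loci$seq_id[ord]
  n <- length(g)
  if (anyDuplicated(g)) {
    stop("duplicated gene_ids in map '", map$taxon_id,
         "'; filter to single-copy loci first")
  }
  nb <- matrix(NA_character_, n, 2L * k)
  for (off in seq_len(k)) {
    if (off >= n) next
    up <- c(rep(NA_character_, off), g[seq_len(n - off)])
    up[c(rep(FALSE, off), s[seq_len(n - off)] != s[-seq_len(off)])] <- NA
    dn <- c(g[-seq_len(off)], rep(NA_character_, off))
    dn[c(s[seq_len(n - off)] != s[-seq_len(off)], rep(FALSE, off))] <- NA
    nb[, off] <- up
    nb[, k + off] <- dn
  }
  rownames(nb) <- g
  nb
}

#' Neighbourhood window of a gene
#'
#' The up-to-`2k`-gene window around a focal gene in the gene order of one
#' genome, after restricting each sequence's order to a shared gene set:
#' non-shared genes are skipped, and windows never cross sequence boundaries.
#'
#' @param map a [gene_map()].
#' @param gene focal gene_id (must be in `shared`).
#' @param shared character vector of shared gene_ids defining the restricted
#'   order (defaults to all genes with coordinates).
#' @param k neighbours per side (default 2, giving the 4-gene GOC window).
#' @return list with `focal_gene`, `members` (gene_ids, focal excluded),
#'   `upstream`, `downstream`, and `complete` (TRUE iff k genes per flank).
#' @export
neighborhood <- function(map, gene, shared = NULL, k = 2L) {
  if (is.null(shared)) {
    shared <- map$loci$gene_id[!is.na(map$loci$start)]
  }
  if (!gene %in% shared) {
    stop("gene '", gene, "' not in the shared gene set")
  }
  nb <- neighbor_matrix(map, shared, k)
  if (!gene %in% rownames(nb)) {
    stop("gene '", gene, "' has no coordinates in map '", map$taxon_id, "'")
  }
  row <- nb[gene, ]
  up <- row[seq_len(k)]
  dn <- row[k + seq_len(k)]
  members <- c(rev(up[!is.na(up)]), dn[!is.na(dn)])
  list(focal_gene = gene, members = unname(members),
       upstream = unname(rev(up[!is.na(up)])),
       downstream = unname(dn[!is.na(dn)]),
       complete = sum(!is.na(row)) == 2L * k)
}

#' Gene Order Conservation score for a genome pair
#'
#' For every shared single-copy gene, the 2 nearest shared genes on each
#' flank form its neighbourhood window in each genome; the per-gene score is
#' the fraction of window members conserved between the two genomes, giving
#' the levels 1, 0.75, 0.5, 0.25, 0 when 4, 3, 2, 1, 0 of the 4 genes are in
#' the same neighbourhood. Per-gene scores are summed into the pair's total
#' GOC score and normalised by the number of scored genes.
#'
#' Two completeness modes are provided. In `"strict"` mode (default) only
#' genes with full 4-gene windows in both genomes are scored, so scores are
#' exact quarters and self-comparison normalises to 1. In `"relaxed"` mode
#' genes near sequence ends are scored too, with denominator
#' `max(|window_a|, |window_b|)`.
#'
#' The default neighbour rule counts a window member as conserved if it lies
#' anywhere within the focal gene's window in the other genome (a symmetric
#' set intersection, tolerant of local inversions); `neighbor_rule =
#' "same_side"` additionally requires it to sit on the same flank.
#'
#' @param map_a,map_b [gene_map()] objects, already filtered to single-copy
#'   chromosome-localised loci (see [filter_status()],
#'   [restrict_to_chromosomes()]).
#' @param mode "strict" or "relaxed" window completeness handling.
#' @param k neighbours per side (default 2).
#' @param neighbor_rule "window" (set intersection) or "same_side".
#' @return object of class `goc_pair`: taxon ids, `n_shared`, `n_scored`,
#'   named `per_gene_scores`, `category_tally`, `total` and `normalized`
#'   (NA with a flag when no gene could be scored).
#' @export
goc_pair <- function(map_a, map_b, mode = c("strict", "relaxed"), k = 2L,
                     neighbor_rule = c("window", "same_side")) {
  mode <- match.arg(mode)
  neighbor_rule <- match.arg(neighbor_rule)
  shared <- shared_single_copy(map_a, map_b)
  na <- neighbor_matrix(map_a, shared, k)
  nb <- neighbor_matrix(map_b, shared, k)
  genes <- rownames(na)
  nb <- nb[genes, , drop = FALSE]

  cnt_a <- rowSums(!is.na(na))
  cnt_b <- rowSums(!is.na(nb))

  ## conserved members: for each column of A's windows, is the gene anywhere
  ## (or same flank) in B's window of the same focal gene?
  m <- integer(length(genes))
  cols_b <- if (neighbor_rule == "window") seq_len(2L * k) else NULL
  for (i in seq_len(2L * k)) {
    jj <- cols_b %||% (if (i <= k) seq_len(k) else k + seq_len(k))
    hit <- rep(FALSE, length(genes))
    for (j in jj) {
      hit <- hit | (!is.na(na[, i]) & !is.na(nb[, j]) & na[, i] == nb[, j])
    }
    m <- m + hit
  }

  if (mode == "strict") {
    scored <- cnt_a == 2L * k & cnt_b == 2L * k
    denom <- rep(2L * k, length(genes))
  } else {
    denom <- pmax(cnt_a, cnt_b)
    scored <- denom > 0L
  }
  sc <- m[scored] / denom[scored]
  names(sc) <- genes[scored]
  total <- sum(sc)
  n_scored <- length(sc)
  normalized <- if (n_scored > 0L) total / n_scored else NA_real_
  tally <- table(factor(sc, levels = sort(unique(c(0, 0.25, 0.5, 0.75, 1, sc)))))
  structure(list(
    taxon_a = map_a$taxon_id, taxon_b = map_b$taxon_id,
    n_shared = length(shared), n_scored = n_scored,
    per_gene_scores = sc, category_tally = tally,
    total = total, normalized = normalized,
    undefined = n_scored == 0L,
    mode = mode, k = k, neighbor_rule = neighbor_rule),
    class = "goc_pair")
}

#' @export
print.goc_pair <- function(x, ...) {
  cat("<goc_pair>", x$taxon_a, "vs", x$taxon_b, "(", x$mode, "mode )\n")
  cat("  shared genes:", x$n_shared, " scored:", x$n_scored, "\n")
  cat("  total GOC:", format(x$total), " normalized:",
      format(round(x$normalized, 4)), "\n")
  invisible(x)
}

#' All-pairs GOC matrix
#'
#' Computes [goc_pair()] once per unordered taxon pair and mirrors the result
#' into symmetric matrices of total and normalised scores. Diagonal entries
#' hold the self-comparison (normalised 1 in strict mode; total equals the
#' number of scorable genes).
#'
#' @param maps list of [gene_map()] objects with unique taxon ids.
#' @param ... scoring options passed to [goc_pair()].
#' @return object of class `goc_matrix` with elements `taxa`, `total`,
#'   `normalized`, `n_shared`, `n_scored` (all symmetric matrices) and `opts`.
#' @export
goc_matrix <- function(maps, ...) {
  taxa <- vapply(maps, function(m) m$taxon_id, "")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon_id: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  n <- length(taxa)
  if (n < 2L) stop("need at least 2 gene maps")
  tot <- nrm <- nsh <- nsc <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    for (j in i:n) {
      p <- goc_pair(maps[[i]], maps[[j]], ...)
      tot[i, j] <- tot[j, i] <- p$total
      nrm[i, j] <- nrm[j, i] <- p$normalized
      nsh[i, j] <- nsh[j, i] <- p$n_shared
      nsc[i, j] <- nsc[j, i] <- p$n_scored
    }
  }
  structure(list(taxa = taxa, total = tot, normalized = nrm,
                 n_shared = nsh, n_scored = nsc, opts = list(...)),
            class = "goc_matrix")
}

#' @export
print.goc_matrix <- function(x, ...) {
  cat("<goc_matrix>", length(x$taxa), "taxa,",
      choose(length(x$taxa), 2), "unique pairs\n")
  off <- x$normalized[upper.tri(x$normalized)]
  cat("  normalized GOC range:", format(round(range(off, na.rm = TRUE), 4)), "\n")
  invisible(x)
}

#' Write a GOC matrix
#'
#' `write_goc_matrix` writes the square labelled matrix (taxon header row and
#' column); `write_goc_pairs` writes the long per-pair table
#' (taxon_a, taxon_b, n_shared, n_scored, total, normalized).
#'
#' @param gm a [goc_matrix()].
#' @param path output TSV path.
#' @param scale "normalized" or "total" for the square layout.
#' @export
write_goc_matrix <- function(gm, path, scale = c("normalized", "total")) {
  scale <- match.arg(scale)
  write_matrix_tsv(gm[[scale]], path)
}

#' @rdname write_goc_matrix
#' @export
write_goc_pairs <- function(gm, path) {
  n <- length(gm$taxa)
  idx <- which(upper.tri(gm$total), arr.ind = TRUE)
  df <- data.frame(
    taxon_a = gm$taxa[idx[, 1]], taxon_b = gm$taxa[idx[, 2]],
    n_shared = gm$n_shared[idx], n_scored = gm$n_scored[idx],
    total = gm$total[idx], normalized = gm$normalized[idx])
  write_tsv(df, path)
}
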