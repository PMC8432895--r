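#' Chromosome assignment tables between a reference and a target genome
#'
#' For each reference chromosome, tallies where its shared orthologs land on
#' the target's chromosomes. The chromosome's "intactness" is the fraction of
#' its shared genes found on the single best-matching (majority) target
#' chromosome — the quantity behind statements like "chromosomes remained
#' 80–92% intact".
#'
#' @param ref,target [gene_map()] objects, chromosome-restricted.
#' @param min_genes minimum shared genes a reference chromosome needs for a
#'   table (default 5; below it percentages are not meaningful).
#' @return data.frame of class `assignment_table` with one row per
#'   (reference chromosome, target chromosome) combination observed:
#'   columns ref_chr, target_chr, count, fraction, majority (logical),
#'   intactness (repeated per ref_chr), tie (TRUE when the majority count is
#'   tied and broken by smallest target seq_id).
#' @export
chromosome_assignment <- function(ref, target, min_genes = 5L) {
  shared <- shared_single_copy(ref, target)
  rl <- ref$loci[!is.na(ref$loci$start) & ref$loci$gene_id %in% shared, ]
  tl <- target$loci[!is.na(target$loci$start) & target$loci$gene_id %in% shared, ]
  tchr <- tl$seq_id[match(rl$gene_id, tl$gene_id)]
  tab <- table(ref_chr = rl$seq_id, target_chr = tchr)
  keep <- rowSums(tab) >= min_genes
  if (!any(keep)) {
    stop("no reference chromosome has >= ", min_genes, " shared genes")
  }
  tab <- tab[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(rownames(tab), function(rc) {
    counts <- tab[rc, ]
    counts <- counts[counts > 0]
    counts <- counts[order(names(counts))]   # ties -> smallest target seq_id
    maj <- names(counts)[which.max(counts)]
    tie <- sum(counts == max(counts)) > 1L
    data.frame(ref_chr = rc, target_chr = names(counts),
               count = as.integer(counts),
               fraction = as.numeric(counts) / sum(counts),
               majority = names(counts) == maj,
               intactness = max(counts) / sum(counts),
               tie = tie, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("assignment_table", "data.frame")
  attr(out, "ref_taxon") <- ref$taxon_id
  attr(out, "target_taxon") <- target$taxon_id
  out
}

#' Summarise per-chromosome intactness
#'
#' @param tables an `assignment_table` from [chromosome_assignment()].
#' @return list with `intactness` (named vector, percent, one entry per
#'   reference chromosome), `min`, `max` (percent) and a formatted `range`
#'   string such as "80-92%".
#' @export
intactness_summary <- function(tables) {
  stopifnot(nrow(tables) >= 1L)
  v <- tapply(tables$intactness, tables$ref_chr, function(x) x[1]) * 100
  v <- stats::setNames(as.vector(v), names(v))
  v <- v[order(names(v))]
  list(intactness = v, min = min(v), max = max(v),
       range = if (min(v) == max(v)) {
         sprintf("%g%%", round(min(v)))
       } else {
         sprintf("%g-%g%%", round(min(v)), round(max(v)))
       })
}

#' Ideogram link table for a genome pair
#'
#' One row per shared single-copy gene, with its coordinates in both genomes,
#' in the layout consumed by ideogram plotting tools.
#'
#' @param ref,target [gene_map()] objects.
#' @return data.frame with columns ref_chr, ref_start, ref_end, target_chr,
#'   target_start, target_end, gene_id. Empty (with a warning) when no genes
#'   are shared.
#' @export
ideogram_links <- function(ref, target) {
  shared <- tryCatch(shared_single_copy(ref, target), error = function(e) character())
  if (length(shared) == 0L) {
    warning("no shared single-copy genes between '", ref$taxon_id, "' and '",
            target$taxon_id, "'")
    return(data.frame(ref_chr = character(), ref_start = numeric(),
                      ref_end = numeric(), target_chr = character(),
                      target_start = numeric(), target_end = numeric(),
                      gene_id = character()))
  }
  rl <- ref$loci[!is.na(ref$loci$start) & ref$loci$gene_id %in% shared, ]
  tl <- target$loci[!is.na(target$loci$start) & target$loci$gene_id %in% shared, ]
  j <- match(rl$gene_id, tl$gene_id)
  out <- data.frame(ref_chr = rl$seq_id, ref_start = rl$start,
                    ref_end = rl$end, target_chr = tl$seq_id[j],
                    target_start = tl$start[j], target_end = tl$end[j],
                    gene_id = rl$gene_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
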