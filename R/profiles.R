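## lowercase base count per position, via raw comparison ('a'..'z')
lowercase_mask <- function(seq_string) {
  r <- charToRaw(seq_string)
  r >= as.raw(97L) & r <= as.raw(122L)
}

#' Soft-masked fraction in fixed-size windows
#'
#' Reads a soft-masked FASTA (lowercase = repeat-masked) and reports, for
#' non-overlapping windows tiling each sequence, the fraction of masked
#' bases. The last window of a sequence may be short; its fraction uses its
#' actual length. N bases are counted by their case, as written.
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences.
#' @param window window size in bp (default 1 Mb).
#' @return data.frame with columns seq_id, window_start, window_end (1-based
#'   inclusive) and masked_fraction.
#' @export
window_masked_fraction <- function(fasta, window = 1e6) {
  if (window <= 0) stop("window must be positive")
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readBStringSet(fasta)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- fasta
  }
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    len <- nchar(s)
    mask <- lowercase_mask(s)
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    frac <- vapply(seq_along(starts), function(i) {
      mean(mask[starts[i]:ends[i]])
    }, numeric(1))
    data.frame(seq_id = id, window_start = starts, window_end = ends,
               masked_fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene counts in fixed-size windows
#'
#' Assigns each gene with coordinates to the window containing its start
#' position (a gene straddling a window boundary counts once, in its start
#' window) and tallies genes per window.
#'
#' @param map a [gene_map()].
#' @param window window size in bp (default 1 Mb).
#' @param seq_lengths optional named vector of sequence lengths; when given,
#'   windows tile each full sequence (zero-count windows included), otherwise
#'   windows run up to the last gene start.
#' @return data.frame with columns seq_id, window_start, window_end,
#'   gene_count.
#' @export
window_gene_density <- function(map, window = 1e6, seq_lengths = NULL) {
  if (window <= 0) stop("window must be positive")
  loci <- map$loci[!is.na(map$loci$start), , drop = FALSE]
  seqs <- unique(loci$seq_id)
  out <- lapply(seqs, function(id) {
    st <- loci$start[loci$seq_id == id]
    bin <- floor((st - 1) / window)            # 0-based window index
    len <- if (!is.null(seq_lengths) && id %in% names(seq_lengths)) {
      seq_lengths[[id]]
    } else {
      max(st)
    }
    nbin <- max(ceiling(len / window), max(bin) + 1)
    counts <- tabulate(bin + 1L, nbins = nbin)
    starts <- (seq_len(nbin) - 1) * window + 1
    ends <- starts + window - 1
    if (!is.null(seq_lengths) && id %in% names(seq_lengths)) {
      ends <- pmin(ends, len)
    }
    data.frame(seq_id = id, window_start = starts, window_end = ends,
               gene_count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a window profile as BED-like TSV
#'
#' Coordinates are emitted 0-based half-open (BED convention); remaining
#' columns are copied as-is.
#'
#' @param profile data.frame from [window_masked_fraction()] or
#'   [window_gene_density()] (or their merge).
#' @param path output path.
#' @export
write_window_profile <- function(profile, path) {
  df <- profile
  df$window_start <- df$window_start - 1
  names(df)[names(df) == "window_start"] <- "start"
  names(df)[names(df) == "window_end"] <- "end"
  write_tsv(df, path)
}
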