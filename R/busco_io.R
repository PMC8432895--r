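#' Ordered gene-position map for one genome
#'
#' A `gene_map` holds one taxon's single-copy ortholog complement with
#' coordinates: one row per BUSCO locus with its status
#' (Complete/Duplicated/Fragmented/Missing), sequence, 1-based inclusive
#' start/end and strand. Loci with coordinates are kept sorted by
#' (seq_id, start, end, gene_id) so that gene order along each sequence can be
#' read off directly; Missing loci carry status only.
#'
#' @param taxon_id taxon label.
#' @param loci data.frame with columns gene_id, seq_id, start, end, strand,
#'   status. Coordinate columns may be NA only for Missing loci.
#' @param chromosome_ids optional character vector of seq_ids designated as
#'   chromosomes (set by [restrict_to_chromosomes()]).
#' @return an object of class `gene_map`.
#' @export
gene_map <- function(taxon_id, loci, chromosome_ids = NULL) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L)
  need <- c("gene_id", "seq_id", "start", "end", "strand", "status")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns: ", paste(need, collapse = ", "))
  }
  loci <- as.data.frame(loci)[need]
  loci$gene_id <- as.character(loci$gene_id)
  loci$seq_id <- as.character(loci$seq_id)
  loci$start <- as.numeric(loci$start)
  loci$end <- as.numeric(loci$end)
  loci$strand <- as.character(loci$strand)
  loci$status <- as.character(loci$status)
  has_coord <- !is.na(loci$start)
  bad <- has_coord & loci$start > loci$end
  if (any(bad)) {
    stop("start > end for loci: ", paste(head(loci$gene_id[bad]), collapse = ", "))
  }
  if (any(!has_coord & loci$status != "Missing")) {
    stop("non-Missing loci without coordinates: ",
         paste(head(loci$gene_id[!has_coord & loci$status != "Missing"]),
               collapse = ", "))
  }
  ord <- order(loci$seq_id, loci$start, loci$end, loci$gene_id,
               method = "radix", na.last = TRUE)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(taxon_id = taxon_id, loci = loci,
                 chromosome_ids = chromosome_ids),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  tab <- table(factor(x$loci$status,
                      levels = c("Complete", "Duplicated", "Fragmented", "Missing")))
  cat("<gene_map> taxon:", x$taxon_id, "\n")
  cat("  loci:", nrow(x$loci), "on", length(unique(stats::na.omit(
    x$loci$seq_id[!is.na(x$loci$start)]))), "sequences\n")
  cat("  status:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (!is.null(x$chromosome_ids)) {
    cat("  chromosomes:", length(x$chromosome_ids), "\n")
  }
  invisible(x)
}

## Column layouts of the BUSCO "full table" dialects.
##   v2/v3: Busco id, Status, Contig, Start, End, Score, Length
##   v4/v5: Busco id, Status, Sequence, Gene Start, Gene End, Strand, Score,
##          Length [, OrthoDB url, Description]
## Missing rows have the id and status only. Some builds emit the sequence as
## "seq:start-end"; the prefix before the first ':' is the sequence name.

#' Read a BUSCO full table into a gene map
#'
#' Parses the tab-separated "full table" written by BUSCO versions 2 through 5
#' into a [gene_map()]. The dialect (column layout) is sniffed from the header
#' and row shape when `dialect = "auto"`: v4/v5 tables carry a Strand column,
#' v2/v3 do not. Missing loci are retained with status only; Fragmented loci
#' that lack coordinates (emitted by some BUSCO versions) are dropped.
#'
#' @param path path to a full table TSV; comment lines start with `#`.
#' @param dialect one of "auto", "v2", "v3", "v4", "v5".
#' @param taxon_id taxon label; defaults to the file name without extension.
#' @return a [gene_map()].
#' @export
read_busco_table <- function(path, dialect = c("auto", "v2", "v3", "v4", "v5"),
                             taxon_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(taxon_id)) {
    taxon_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header <- lines[is_comment]
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)

  if (dialect == "auto") {
    if (any(grepl("Strand", header, fixed = TRUE))) {
      dialect <- "v5"
    } else if (any(grepl("\tContig\t", header, fixed = TRUE))) {
      dialect <- "v2"
    } else if (length(ncols) && max(ncols) >= 8L) {
      dialect <- "v5"
    } else {
      dialect <- "v2"
    }
  }
  v45 <- dialect %in% c("v4", "v5")
  full_n <- if (v45) 8L else 7L

  if (length(body_idx) == 0L) {
    return(gene_map(taxon_id, data.frame(
      gene_id = character(), seq_id = character(), start = numeric(),
      end = numeric(), strand = character(), status = character())))
  }

  ok <- ncols >= full_n | ncols == 2L | ncols == 3L
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("malformed BUSCO table row at line ", body_idx[bad], " of '", path,
         "': expected ", full_n, " (or 2) columns, got ", ncols[bad])
  }

  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  gene_id <- get(1L)
  status <- get(2L)
  seq_id <- get(3L)
  start_c <- get(4L)
  end_c <- get(5L)
  strand <- if (v45) get(6L) else rep(NA_character_, length(fields))

  has_coord <- ncols >= full_n & !is.na(start_c)
  start <- suppressWarnings(as.numeric(gsub(",", "", start_c)))
  end <- suppressWarnings(as.numeric(gsub(",", "", end_c)))
  bad_num <- has_coord & (is.na(start) | is.na(end))
  if (any(bad_num)) {
    stop("non-numeric coordinates at line ", body_idx[which(bad_num)[1]],
         " of '", path, "'")
  }

  ## coordinate-less rows: keep Missing, drop coordinate-less Fragmented
  keep <- has_coord | status == "Missing"
  gene_id <- gene_id[keep]; status <- status[keep]; seq_id <- seq_id[keep]
  start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  has_coord <- has_coord[keep]

  seq_id[has_coord] <- sub(":.*$", "", seq_id[has_coord])
  seq_id[!has_coord] <- NA_character_
  start[!has_coord] <- NA_real_
  end[!has_coord] <- NA_real_
  strand[!has_coord | is.na(strand)] <- "unknown"
  strand[!strand %in% c("+", "-")] <- "unknown"

  gene_map(taxon_id, data.frame(
    gene_id = gene_id, seq_id = seq_id, start = start, end = end,
    strand = strand, status = status, stringsAsFactors = FALSE))
}

#' Filter loci by BUSCO status
#'
#' @param map a [gene_map()].
#' @param statuses character vector of statuses to retain, or the preset
#'   `"single-copy"` (Complete only — the set used for GOC scoring) or
#'   `"single-copy+fragmented"` (Complete and Fragmented — the set used for
#'   chromosome-level synteny summaries). Duplicated loci are always excluded
#'   by both presets.
#' @return a filtered [gene_map()].
#' @export
filter_status <- function(map, statuses = "single-copy") {
  stopifnot(inherits(map, "gene_map"))
  if (identical(statuses, "single-copy")) {
    statuses <- "Complete"
  } else if (identical(statuses, "single-copy+fragmented")) {
    statuses <- c("Complete", "Fragmented")
  }
  loci <- map$loci[map$loci$status %in% statuses, , drop = FALSE]
  gene_map(map$taxon_id, loci, map$chromosome_ids)
}

#' Restrict a gene map to chromosome-scale sequences
#'
#' Drops loci on unplaced scaffolds so that only genes localised to
#' chromosomes enter synteny analyses. The chromosomes can be named
#' explicitly, matched by a name pattern, or selected by a minimum sequence
#' length (given per-sequence lengths).
#'
#' @param map a [gene_map()].
#' @param chromosomes explicit character vector of chromosome seq_ids.
#' @param pattern regular expression matched against seq_ids.
#' @param min_length minimum sequence length in bp; requires `seq_lengths`.
#' @param seq_lengths named numeric vector of sequence lengths (bp).
#' @return a [gene_map()] with `chromosome_ids` recorded; loci elsewhere
#'   removed (coordinate-less Missing loci are kept).
#' @export
restrict_to_chromosomes <- function(map, chromosomes = NULL, pattern = NULL,
                                    min_length = NULL, seq_lengths = NULL) {
  stopifnot(inherits(map, "gene_map"))
  seqs <- unique(map$loci$seq_id[!is.na(map$loci$seq_id)])
  if (!is.null(chromosomes)) {
    sel <- intersect(as.character(chromosomes), seqs)
  } else if (!is.null(pattern)) {
    sel <- seqs[grepl(pattern, seqs)]
  } else if (!is.null(min_length)) {
    if (is.null(seq_lengths)) {
      stop("min_length selection requires seq_lengths")
    }
    keep <- names(seq_lengths)[seq_lengths >= min_length]
    sel <- intersect(keep, seqs)
  } else {
    stop("supply one of chromosomes, pattern or min_length")
  }
  if (length(sel) == 0L) {
    stop("chromosome selector matched no sequences for taxon '",
         map$taxon_id, "'")
  }
  keep_row <- is.na(map$loci$seq_id) | map$loci$seq_id %in% sel
  gene_map(map$taxon_id, map$loci[keep_row, , drop = FALSE],
           chromosome_ids = sort(sel))
}

#' Gene order along one sequence
#'
#' Returns the gene_ids on `seq_id` sorted by (start, end, gene_id); the
#' lexicographic gene_id tie-break makes the order deterministic.
#'
#' @param map a [gene_map()].
#' @param seq_id sequence name present in the map.
#' @return character vector of gene_ids in positional order.
#' @export
ordered_gene_list <- function(map, seq_id) {
  stopifnot(inherits(map, "gene_map"))
  loci <- map$loci[!is.na(map$loci$seq_id) & map$loci$seq_id == seq_id, ,
                   drop = FALSE]
  if (nrow(loci) == 0L) {
    stop("seq_id '", seq_id, "' not present in map for taxon '",
         map$taxon_id, "'")
  }
  loci$gene_id[order(loci$start, loci$end, loci$gene_id, method = "radix")]
}

#' Write a gene map as a normalised position table
#'
#' @param map a [gene_map()].
#' @param path output TSV path (columns: taxon_id, gene_id, seq_id, start,
#'   end, strand, status).
#' @export
write_gene_map <- function(map, path) {
  df <- cbind(taxon_id = map$taxon_id, map$loci)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a gene map in BUSCO full-table layout
#'
#' Emits a full table in the requested dialect; re-reading with
#' [read_busco_table()] round-trips the map exactly (v2/v3 tables carry no
#' strand, so strand degrades to "unknown" under those dialects).
#'
#' @param map a [gene_map()].
#' @param path output path.
#' @param dialect "v2" or "v5" column layout.
#' @export
write_busco_table <- function(map, path, dialect = c("v5", "v2")) {
  dialect <- match.arg(dialect)
  loci <- map$loci
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "v5") {
    writeLines(c("# BUSCO version is: 5.0.0",
                 paste("# Busco id", "Status", "Sequence", "Gene Start",
                       "Gene End", "Strand", "Score", "Length", sep = "\t")),
               con)
  } else {
    writeLines(c("# BUSCO version is: 2.0",
                 paste("# Busco id", "Status", "Contig", "Start", "End",
                       "Score", "Length", sep = "\t")), con)
  }
  for (i in seq_len(nrow(loci))) {
    if (loci$status[i] == "Missing" && is.na(loci$start[i])) {
      writeLines(paste(loci$gene_id[i], "Missing", sep = "\t"), con)
    } else if (dialect == "v5") {
      strand <- if (loci$strand[i] %in% c("+", "-")) loci$strand[i] else "+"
      writeLines(paste(loci$gene_id[i], loci$status[i], loci$seq_id[i],
                       format(loci$start[i], scientific = FALSE),
                       format(loci$end[i], scientific = FALSE), strand,
                       "100.0", format(loci$end[i] - loci$start[i] + 1,
                                       scientific = FALSE), sep = "\t"), con)
    } else {
      writeLines(paste(loci$gene_id[i], loci$status[i], loci$seq_id[i],
                       format(loci$start[i], scientific = FALSE),
                       format(loci$end[i], scientific = FALSE), "100.0",
                       format(loci$end[i] - loci$start[i] + 1,
                              scientific = FALSE), sep = "\t"), con)
    }
  }
  invisible(path)
}
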