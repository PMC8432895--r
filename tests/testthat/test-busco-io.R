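# BUSCO full-table parsing across dialects, filtering, ordering.

v5_lines <- c(
  "# BUSCO version is: 5.beta",
  "# The lineage dataset is: insecta_odb10",
  paste("# Busco id", "Status", "Sequence", "Gene Start", "Gene End",
        "Strand", "Score", "Length", sep = "\t"),
  "100043at50557\tComplete\tchr2\t1200\t5600\t+\t975.0\t4401",
  "100155at50557\tComplete\tchr1\t900\t2400\t-\t800.1\t1501",
  "100200at50557\tComplete\tchr1\t10\t500\t+\t651.2\t491",
  "100300at50557\tDuplicated\tchr3\t100\t900\t+\t500.0\t801",
  "100300at50557\tDuplicated\tchr4\t150\t950\t-\t499.0\t801",
  "100400at50557\tMissing")

v2_lines <- c(
  "# BUSCO version is: 2.0",
  paste("# Busco id", "Status", "Contig", "Start", "End", "Score", "Length",
        sep = "\t"),
  "BUSCOa\tComplete\tscaf1\t100\t400\t90.0\t301",
  "BUSCOb\tFragmented\tscaf2\t50\t90\t20.0\t41",
  "BUSCOc\tMissing")

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("v5 full table parses field-by-field, with Missing retained", {
  map <- read_busco_table(write_lines_tmp(v5_lines), taxon_id = "toy")
  expect_s3_class(map, "gene_map")
  row <- map$loci[map$loci$gene_id == "100043at50557", ]
  expect_equal(row$seq_id, "chr2")
  expect_equal(row$start, 1200)
  expect_equal(row$end, 5600)
  expect_equal(row$strand, "+")
  expect_equal(row$status, "Complete")
  expect_equal(sum(map$loci$status == "Missing"), 1)
  expect_true(is.na(map$loci$start[map$loci$status == "Missing"]))
  # 3 single-copy candidates after filtering out Duplicated/Missing
  expect_equal(nrow(filter_status(map, "single-copy")$loci), 3)
})

test_that("empty table (header only) gives an empty map without error", {
  map <- read_busco_table(write_lines_tmp(v5_lines[1:3]))
  expect_equal(nrow(map$loci), 0)
})

test_that("v2 dialect is auto-detected and Fragmented loci keep coordinates", {
  map <- read_busco_table(write_lines_tmp(v2_lines), taxon_id = "toy2")
  expect_equal(sort(map$loci$gene_id),
               sort(c("BUSCOa", "BUSCOb", "BUSCOc")))
  expect_equal(map$loci$strand[map$loci$gene_id == "BUSCOa"], "unknown")
  frag <- filter_status(map, "single-copy+fragmented")
  expect_setequal(frag$loci$gene_id, c("BUSCOa", "BUSCOb"))
})

test_that("malformed rows are rejected with a line number", {
  bad <- c(v5_lines[1:3], "id1\tComplete\tchr1\t100")
  expect_error(read_busco_table(write_lines_tmp(bad)), "line 4")
  nonnum <- c(v5_lines[1:3], "id1\tComplete\tchr1\tabc\t200\t+\t1\t2")
  expect_error(read_busco_table(write_lines_tmp(nonnum)), "non-numeric")
})

test_that("sequence ids of the form seq:start-end are split on the colon", {
  lines <- c(v5_lines[1:3],
             "id1\tComplete\tchr7:100-9000\t100\t9000\t+\t1.0\t8901")
  map <- read_busco_table(write_lines_tmp(lines))
  expect_equal(map$loci$seq_id, "chr7")
})

test_that("status filtering keeps exactly the requested statuses", {
  map <- read_busco_table(write_lines_tmp(v5_lines))
  expect_equal(nrow(filter_status(map, "Complete")$loci), 3)
  expect_equal(nrow(filter_status(map, c("Complete", "Duplicated"))$loci), 5)
  expect_false("100300at50557" %in%
                 filter_status(map, "single-copy")$loci$gene_id)
})

test_that("chromosome restriction by list, pattern and length threshold", {
  chroms <- c(list(chr1 = paste0("a", 1:5), chr2 = paste0("b", 1:5)),
              stats::setNames(lapply(1:4, function(i) paste0("u", i)),
                              paste0("scaffold_", 1:4)))
  map <- mk_map("t", chroms)
  by_list <- restrict_to_chromosomes(map, chromosomes = c("chr1", "chr2"))
  expect_equal(sort(by_list$chromosome_ids), c("chr1", "chr2"))
  expect_equal(nrow(by_list$loci), 10)

  by_pat <- restrict_to_chromosomes(map, pattern = "^chr")
  expect_equal(nrow(by_pat$loci), 10)

  lens <- c(chr1 = 2e7, chr2 = 1.5e7, scaffold_1 = 5e5, scaffold_2 = 4e5,
            scaffold_3 = 2e5, scaffold_4 = 9e5)
  by_len <- restrict_to_chromosomes(map, min_length = 1e7, seq_lengths = lens)
  expect_equal(sort(by_len$chromosome_ids), c("chr1", "chr2"))

  expect_error(restrict_to_chromosomes(map, pattern = "^Chr_"),
               "matched no sequences")
})

test_that("gene order is sorted by start, then end, then gene id", {
  loci <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    seq_id = "chr1",
    start = c(100, 50, 70, 200, 200),
    end = c(150, 80, 90, 260, 210),
    strand = "+", status = "Complete")
  map <- gene_map("t", loci)
  expect_equal(ordered_gene_list(map, "chr1"),
               c("gB", "gC", "gA", "gE", "gD"))  # tie at 200: end 210 first
  expect_error(ordered_gene_list(map, "chrX"), "not present")
})

test_that("ordering matches an independent sort oracle on shuffled input", {
  set.seed(42)
  n <- 50
  loci <- data.frame(
    gene_id = sprintf("g%02d", sample(n)),
    seq_id = "chr1",
    start = sample(1:20, n, replace = TRUE) * 100,
    end = numeric(n), strand = "+", status = "Complete")
  loci$end <- loci$start + sample(1:500, n)
  map <- gene_map("t", loci)
  got <- ordered_gene_list(map, "chr1")
  want <- loci$gene_id[order(loci$start, loci$end, loci$gene_id)]
  expect_equal(got, want)
  # a permutation of the sequence's genes, idempotent under reordering
  expect_setequal(got, loci$gene_id)
})

test_that("full-table writing round-trips through both dialects", {
  set.seed(7)
  chroms <- random_chroms(60, 4)
  map <- mk_map("rt", chroms)
  map$loci <- rbind(map$loci, data.frame(
    gene_id = "lostgene", seq_id = NA, start = NA, end = NA,
    strand = "unknown", status = "Missing"))
  map <- gene_map("rt", map$loci)

  f5 <- tempfile(); write_busco_table(map, f5, "v5")
  back5 <- read_busco_table(f5, taxon_id = "rt")
  expect_equal(back5$loci, map$loci)

  f2 <- tempfile(); write_busco_table(map, f2, "v2")
  back2 <- read_busco_table(f2, taxon_id = "rt")
  # v2 carries no strand; everything else survives
  expect_equal(back2$loci[setdiff(names(back2$loci), "strand")],
               map$loci[setdiff(names(map$loci), "strand")])
})

test_that("status filtering and chromosome restriction commute", {
  set.seed(11)
  chroms <- c(random_chroms(40, 3), list(scaff9 = paste0("x", 1:6)))
  map <- mk_map("t", chroms)
  map$loci$status[seq(1, 46, by = 5)] <- "Fragmented"
  map <- gene_map("t", map$loci)
  a <- restrict_to_chromosomes(filter_status(map, "Complete"),
                               pattern = "^chr")
  b <- filter_status(restrict_to_chromosomes(map, pattern = "^chr"),
                     "Complete")
  expect_equal(a$loci, b$loci)
})
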