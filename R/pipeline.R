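## Every pipeline stage writes a manifest recording inputs, options and seed
## so a run can be reproduced exactly.
write_manifest <- function(out_dir, stage, inputs, options, seed = NULL) {
  manifest <- list(stage = stage, inputs = inputs, options = options,
                   seed = seed, schema = "syntenydecay-run/1")
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

#' Read a two-column taxon-to-order classification table
#'
#' @param path TSV with columns taxon, order (no header).
#' @return named character vector (names = normalised taxon labels).
#' @export
read_order_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("taxon", "order"))
  stats::setNames(df$order, normalize_taxon_names(df$taxon))
}

#' Pipeline stage: all-pairs GOC matrix from BUSCO tables
#'
#' Reads every BUSCO full table in a directory, filters to single-copy loci
#' (optionally chromosome-restricted), computes the [goc_matrix()] and
#' writes the square matrices (normalized and total), the long pair table
#' and a run manifest.
#'
#' @param tables_dir directory of BUSCO full-table TSVs.
#' @param out_dir output directory (created).
#' @param dialect BUSCO dialect tag (default "auto").
#' @param chromosomes,pattern,min_length,seq_lengths chromosome selector
#'   forwarded to [restrict_to_chromosomes()]; all NULL = no restriction.
#' @param mode,k,neighbor_rule scoring options, see [goc_pair()].
#' @return the [goc_matrix()], invisibly.
#' @export
run_goc <- function(tables_dir, out_dir, dialect = "auto",
                    chromosomes = NULL, pattern = NULL, min_length = NULL,
                    seq_lengths = NULL, mode = "strict", k = 2L,
                    neighbor_rule = "window") {
  files <- sort(list.files(tables_dir, pattern = "\\.(tsv|txt)$",
                           full.names = TRUE))
  if (length(files) < 2L) stop("need >= 2 BUSCO tables in '", tables_dir, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  maps <- lapply(files, function(f) {
    m <- read_busco_table(f, dialect = dialect)
    m <- filter_status(m, "single-copy")
    if (!is.null(chromosomes) || !is.null(pattern) || !is.null(min_length)) {
      m <- restrict_to_chromosomes(m, chromosomes, pattern, min_length,
                                   seq_lengths)
    }
    m
  })
  gm <- goc_matrix(maps, mode = mode, k = k, neighbor_rule = neighbor_rule)
  write_goc_matrix(gm, file.path(out_dir, "goc_normalized.tsv"), "normalized")
  write_goc_matrix(gm, file.path(out_dir, "goc_total.tsv"), "total")
  write_goc_pairs(gm, file.path(out_dir, "goc_pairs.tsv"))
  write_manifest(out_dir, "goc", list(tables = basename(files)),
                 list(dialect = dialect, mode = mode, k = k,
                      neighbor_rule = neighbor_rule))
  invisible(gm)
}

#' Pipeline stage: unit-height patristic distance matrix
#'
#' @param tree_file newick file.
#' @param out_dir output directory.
#' @return the distance matrix, invisibly.
#' @export
run_distmat <- function(tree_file, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_phylo(tree_file)
  d <- patristic_matrix(tree, rescale = TRUE)
  write_distance_matrix(d, file.path(out_dir, "phylo_distance.tsv"))
  write_manifest(out_dir, "distmat", list(tree = basename(tree_file)),
                 list(rescale = "unit-height"))
  invisible(d)
}

#' Pipeline stage: decay model comparison and order-interaction tests
#'
#' Loads a GOC matrix, a distance matrix and a taxon-to-order table, runs
#' [compare_models()], the order-interaction [permutation_test()], and the
#' same interaction test after excluding each order in `exclude_orders`;
#' writes a JSON report, the tidy pair table and the null-F draws.
#'
#' @param goc_file square labelled GOC matrix (TSV or CSV).
#' @param dist_file square labelled distance matrix (TSV or CSV).
#' @param orders_file two-column TSV: taxon, order (no header).
#' @param out_dir output directory.
#' @param n_perm permutations (default 4999).
#' @param seed RNG seed (recorded in the report).
#' @param min_taxa_per_order see [build_pair_dataset()].
#' @param exclude_orders orders to re-test without (e.g. the dominant one).
#' @param response "normalized" or "total" (matrix values are used as given;
#'   the flag is recorded in the report).
#' @return list with `comparison`, `interaction`, `exclusions`, invisibly.
#' @export
run_fit <- function(goc_file, dist_file, orders_file, out_dir,
                    n_perm = 4999L, seed = 1L, min_taxa_per_order = 4L,
                    exclude_orders = character(), response = "normalized") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  M <- read_matrix_file(goc_file)
  D <- read_matrix_file(dist_file)
  ord <- read_order_table(orders_file)

  cmp <- compare_models(M, D, ord, n_perm = n_perm, seed = seed,
                        min_taxa_per_order = min_taxa_per_order)
  best <- cmp$form[1]
  inter <- permutation_test(M, D, ord, form = best, test = "interaction",
                            n_perm = n_perm, seed = seed,
                            min_taxa_per_order = min_taxa_per_order)
  pairs <- build_pair_dataset(M, D, ord,
                              min_taxa_per_order = min_taxa_per_order)
  write_tsv(pairs, file.path(out_dir, "pair_data.tsv"))

  exclusions <- lapply(exclude_orders, function(o) {
    sub <- subset_excluding(pairs, o)
    if (length(unique(sub$order)) < 2L) {
      return(list(excluded = o, F = NA, df = NA, p = NA, n = nrow(sub),
                  note = "fewer than 2 orders remain"))
    }
    it <- interaction_test(sub, form = best, n_perm = n_perm, seed = seed)
    list(excluded = o, F = it$F_obs, df = it$df, p = it$p, n = nrow(sub))
  })
  names(exclusions) <- exclude_orders

  fits <- attr(cmp, "tests")
  report <- list(
    response = response, n_pairs = nrow(pairs), seed = seed, n_perm = n_perm,
    models = lapply(fits, function(t) {
      list(form = t$form, F = t$F_obs, df = t$df, p = t$p,
           n = t$fit$n, n_dropped = t$fit$n_dropped,
           coefficients = apply(t$fit$coefficients, 1, as.list))
    }),
    ranking = cmp$form, best = best,
    interaction = list(F = inter$F_obs, df = inter$df, p = inter$p),
    exclusions = exclusions,
    note = paste("model F statistics are computed on each form's own",
                 "response scale; ranking by F follows the permutational",
                 "distance-regression convention"))
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  null_df <- data.frame(perm = seq_len(n_perm))
  for (t in fits) null_df[[t$form]] <- t$null_F
  null_df$interaction <- inter$null_F
  write_tsv(null_df, file.path(out_dir, "null_F.tsv"))
  write_manifest(out_dir, "fit",
                 list(goc = basename(goc_file), dist = basename(dist_file),
                      orders = basename(orders_file)),
                 list(n_perm = n_perm, min_taxa_per_order = min_taxa_per_order,
                      exclude_orders = exclude_orders, response = response),
                 seed = seed)
  invisible(list(comparison = cmp, interaction = inter,
                 exclusions = exclusions))
}

#' Pipeline stage: chromosome-level synteny summaries
#'
#' @param ref_table BUSCO full table of the reference genome.
#' @param target_tables character vector of BUSCO tables to compare against.
#' @param out_dir output directory.
#' @param dialect BUSCO dialect tag.
#' @param statuses status preset (default "single-copy+fragmented", the set
#'   used for chromosome-level comparisons).
#' @param min_genes see [chromosome_assignment()].
#' @return list of per-target results, invisibly.
#' @export
run_chromsynt <- function(ref_table, target_tables, out_dir,
                          dialect = "auto",
                          statuses = "single-copy+fragmented",
                          min_genes = 5L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- filter_status(read_busco_table(ref_table, dialect), statuses)
  res <- lapply(target_tables, function(tf) {
    tgt <- filter_status(read_busco_table(tf, dialect), statuses)
    tab <- chromosome_assignment(ref, tgt, min_genes = min_genes)
    summ <- intactness_summary(tab)
    links <- ideogram_links(ref, tgt)
    base <- file.path(out_dir, paste0(ref$taxon_id, "_vs_", tgt$taxon_id))
    write_tsv(as.data.frame(tab), paste0(base, "_assignment.tsv"))
    write_tsv(data.frame(ref_chr = names(summ$intactness),
                         intactness_pct = unname(summ$intactness)),
              paste0(base, "_intactness.tsv"))
    write_tsv(links, paste0(base, "_links.tsv"))
    list(assignment = tab, intactness = summ, links = links)
  })
  names(res) <- vapply(target_tables,
                       function(f) sub("\\.[^.]*$", "", basename(f)), "")
  write_manifest(out_dir, "chromsynt",
                 list(ref = basename(ref_table),
                      targets = basename(target_tables)),
                 list(dialect = dialect, statuses = statuses,
                      min_genes = min_genes))
  invisible(res)
}

#' Pipeline stage: write a complete synthetic dataset
#'
#' Simulates tip genomes under a [sim_config()] and writes BUSCO tables, the
#' tree, the taxon-to-order table and the ground-truth event counts.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param out_dir output directory.
#' @param dialect BUSCO dialect to emit.
#' @return the [simulate_tips()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir, dialect = "v5") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_tips(config)
  write_busco_tables(sim$tips, file.path(out_dir, "busco_tables"), dialect)
  ape::write.tree(config$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(
    data.frame(taxon = names(config$orders), order = unname(config$orders)),
    file.path(out_dir, "orders.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(branch_events = sim$truth$branch_events,
         tip_cumulative = as.data.frame(sim$truth$tip_cumulative),
         seed = config$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, "simulate", list(),
                 list(n_chromosomes = config$n_chromosomes,
                      n_genes = config$n_genes,
                      rate_intra = config$rate_intra,
                      rate_inter = config$rate_inter,
                      rate_loss = config$rate_loss,
                      inversion_mean_len = config$inversion_mean_len,
                      dialect = dialect),
                 seed = config$seed)
  invisible(sim)
}
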