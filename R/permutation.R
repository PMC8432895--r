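## Precompute the fixed geometry of the within-order pair design: taxon
## indices per pair, order labels and distances. Only the synteny responses
## change under permutation (tip labels of the synteny matrix are shuffled;
## the tree and the classification stay put).
pair_geometry <- function(goc, dist, orders, min_taxa_per_order = 4L,
                          response = "normalized") {
  M <- if (inherits(goc, "goc_matrix")) goc[[response]] else as.matrix(goc)
  rownames(M) <- normalize_taxon_names(rownames(M))
  colnames(M) <- normalize_taxon_names(colnames(M))
  base <- build_pair_dataset(goc, dist, orders,
                             min_taxa_per_order = min_taxa_per_order,
                             response = response)
  taxa <- rownames(M)
  list(M = M[taxa, taxa], taxa = taxa,
       ia = match(base$taxon_a, taxa), ib = match(base$taxon_b, taxa),
       order = base$order, d = base$d, base = base)
}

perm_F <- function(geom, perm, form, grouping, test) {
  y <- geom$M[cbind(perm[geom$ia], perm[geom$ib])]
  tr <- transform_pairs(geom$d, y, form)
  eng <- fit_engine(tr$xt[tr$ok], tr$yt[tr$ok],
                    geom$order[tr$ok], grouping)
  if (test == "model") eng$F else eng$F_interaction
}

#' Permutational F-test of a synteny decay model
#'
#' Significance of a [fit_decay()] F statistic by permutation: the tip
#' labels of the synteny matrix are randomly permuted while the phylogeny
#' (distance matrix) and the taxonomic classification stay fixed, the
#' within-order pair dataset is rebuilt, and the F statistic recomputed. The
#' p-value uses the add-one estimator `(1 + #{F_null >= F_obs}) /
#' (1 + n_perm)`, so it is never exactly zero. This sidesteps the
#' non-independence of pairwise observations that invalidates the parametric
#' F distribution.
#'
#' @param goc,dist,orders,min_taxa_per_order,response as in
#'   [build_pair_dataset()].
#' @param form model form, see [fit_decay()].
#' @param grouping "by_order" or "common".
#' @param test "model" (F against intercept-only) or "interaction"
#'   (common-slope vs per-order-slope F).
#' @param n_perm number of permutations (default 4999).
#' @param seed RNG seed, recorded in the result.
#' @param within_order permute tip labels only within orders (sensitivity
#'   option; default FALSE = global permutation across all taxa).
#' @return object of class `perm_test` with `F_obs`, `df`, `null_F`,
#'   `n_perm`, `p`, `seed` and the observed `fit`.
#' @export
permutation_test <- function(goc, dist, orders,
                             form = c("exponential", "linear", "power"),
                             grouping = c("by_order", "common"),
                             test = c("model", "interaction"),
                             n_perm = 4999L, seed = NULL,
                             min_taxa_per_order = 4L,
                             response = c("normalized", "total"),
                             within_order = FALSE) {
  form <- match.arg(form)
  grouping <- match.arg(grouping)
  test <- match.arg(test)
  response <- match.arg(response)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (test == "interaction" && grouping != "by_order") {
    stop("interaction test requires by_order grouping")
  }
  geom <- pair_geometry(goc, dist, orders, min_taxa_per_order, response)
  if (test == "interaction" && length(unique(geom$order)) < 2L) {
    stop("interaction test needs at least 2 orders")
  }
  fit <- fit_decay(geom$base, form = form, grouping = grouping,
                   allow_drop = TRUE)
  F_obs <- if (test == "model") fit$F else fit$F_interaction
  df <- if (test == "model") fit$df else fit$df_interaction

  if (!is.null(seed)) set.seed(seed)
  nt <- length(geom$taxa)
  ## order membership per taxon, for within-order permutation
  tax_ord <- rep(NA_character_, nt)
  tax_ord[geom$ia] <- geom$order
  tax_ord[geom$ib] <- geom$order
  null_F <- vapply(seq_len(n_perm), function(i) {
    if (within_order) {
      perm <- seq_len(nt)
      for (o in unique(stats::na.omit(tax_ord))) {
        idx <- which(tax_ord == o)
        perm[idx] <- sample(idx)
      }
    } else {
      perm <- sample.int(nt)
    }
    perm_F(geom, perm, form, grouping, test)
  }, numeric(1))

  p <- (1 + sum(null_F >= F_obs, na.rm = TRUE)) / (1 + n_perm)
  structure(list(F_obs = F_obs, df = df, null_F = null_F, n_perm = n_perm,
                 p = p, seed = seed, test = test, form = form,
                 grouping = grouping, within_order = within_order,
                 fit = fit),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  lab <- if (x$test == "model") "model" else "order-interaction"
  cat(sprintf("<perm_test> %s F-test, %s form\n", lab, x$form))
  cat(sprintf("  F(%d, %d) = %.5g;  permutational p = %.4g  (n_perm = %d%s)\n",
              x$df[1], x$df[2], x$F_obs, x$p, x$n_perm,
              if (!is.null(x$seed)) paste0(", seed = ", x$seed) else ""))
  invisible(x)
}

#' Permutational test for order-specific decay rates from a pair table
#'
#' Nested-model F-test of whether groups (orders) differ in decay slope:
#' full model = per-order intercepts and slopes; reduced = per-order
#' intercepts, one common slope; `F = ((RSS_red - RSS_full)/q) /
#' (RSS_full/df_full)` with `q = m - 1`. Works directly on a pair table; the
#' null distribution permutes the synteny responses across pair
#' observations. When the original matrices are available, prefer
#' `permutation_test(..., test = "interaction")`, which permutes tip labels
#' of the synteny matrix instead.
#'
#' @param pairs a `pair_data` data.frame with >= 2 orders.
#' @param form model form, see [fit_decay()].
#' @param n_perm,seed as in [permutation_test()].
#' @return a `perm_test` object.
#' @export
interaction_test <- function(pairs, form = c("exponential", "linear", "power"),
                             n_perm = 4999L, seed = NULL) {
  form <- match.arg(form)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(unique(pairs$order)) < 2L) {
    stop("interaction test needs at least 2 orders")
  }
  fit <- fit_decay(pairs, form = form, grouping = "by_order",
                   allow_drop = TRUE)
  F_obs <- fit$F_interaction
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pairs)
  null_F <- vapply(seq_len(n_perm), function(i) {
    y <- pairs$y[sample.int(n)]
    tr <- transform_pairs(pairs$d, y, form)
    fit_engine(tr$xt[tr$ok], tr$yt[tr$ok], pairs$order[tr$ok],
               "by_order")$F_interaction
  }, numeric(1))
  p <- (1 + sum(null_F >= F_obs, na.rm = TRUE)) / (1 + n_perm)
  structure(list(F_obs = F_obs, df = fit$df_interaction, null_F = null_F,
                 n_perm = n_perm, p = p, seed = seed, test = "interaction",
                 form = form, grouping = "by_order", within_order = FALSE,
                 fit = fit),
            class = "perm_test")
}

#' Compare decay model forms by permutational F
#'
#' Fits the linear, exponential and power-law forms with by-order grouping,
#' attaches a permutational p-value to each, and ranks the forms by their
#' model F statistic (not by information criteria, which behave poorly for
#' distance-matrix responses). Each form's F is computed against the
#' intercept-only model on its own transformed response scale, so the
#' cross-form comparison mixes scales; the shared degrees of freedom make
#' the F values comparable in practice, but the ranking should be read as
#' the field's convention, not a likelihood ratio.
#'
#' @inheritParams permutation_test
#' @param forms model forms to compare.
#' @return data.frame of class `model_comparison`, ranked by F: columns
#'   form, F, df1, df2, p, n, n_dropped.
#' @export
compare_models <- function(goc, dist, orders, n_perm = 4999L, seed = NULL,
                           forms = c("exponential", "linear", "power"),
                           grouping = "by_order", min_taxa_per_order = 4L,
                           response = c("normalized", "total"),
                           within_order = FALSE) {
  response <- match.arg(response)
  tests <- lapply(forms, function(f) {
    permutation_test(goc, dist, orders, form = f, grouping = grouping,
                     test = "model", n_perm = n_perm, seed = seed,
                     min_taxa_per_order = min_taxa_per_order,
                     response = response, within_order = within_order)
  })
  out <- data.frame(
    form = forms,
    F = vapply(tests, function(t) t$F_obs, numeric(1)),
    df1 = vapply(tests, function(t) t$df[1], numeric(1)),
    df2 = vapply(tests, function(t) t$df[2], numeric(1)),
    p = vapply(tests, function(t) t$p, numeric(1)),
    n = vapply(tests, function(t) t$fit$n, numeric(1)),
    n_dropped = vapply(tests, function(t) t$fit$n_dropped, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$F), ]
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  attr(out, "seed") <- seed
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Synteny decay model comparison (ranked by model F; permutational p)\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 6)
  print(df)
  cat("Best-fitting form:", x$form[1], "\n")
  cat("Note: each F is computed on its form's own response scale.\n")
  invisible(x)
}
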