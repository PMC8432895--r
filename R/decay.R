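#' Build the within-group pair dataset for decay regression
#'
#' Joins a pairwise synteny (GOC) matrix with a patristic distance matrix and
#' a taxon classification, keeping only pairs of taxa that belong to the same
#' group (taxonomic order): cross-order pairs are never used. Taxon names are
#' normalised (spaces to underscores) before matching; the taxon sets of the
#' two matrices and the classification must agree exactly.
#'
#' @param goc a [goc_matrix()] or a plain symmetric labelled matrix of
#'   synteny scores.
#' @param dist symmetric labelled matrix of phylogenetic distances
#'   (see [patristic_matrix()]).
#' @param orders taxon classification: named character vector
#'   (names = taxa, values = order) or a two-column data.frame (taxon,
#'   order).
#' @param min_taxa_per_order orders with fewer taxa are dropped with a
#'   message (default 4).
#' @param response which scale of a `goc_matrix` to use: "normalized"
#'   (default) or "total"; ignored for a plain matrix.
#' @return data.frame of class `pair_data` with columns taxon_a, taxon_b,
#'   order, d (phylogenetic distance) and y (synteny score); the response
#'   scale is recorded in attribute `"response"`.
#' @export
build_pair_dataset <- function(goc, dist, orders, min_taxa_per_order = 4L,
                               response = c("normalized", "total")) {
  response <- match.arg(response)
  M <- if (inherits(goc, "goc_matrix")) goc[[response]] else as.matrix(goc)
  rownames(M) <- normalize_taxon_names(rownames(M))
  colnames(M) <- normalize_taxon_names(colnames(M))
  D <- as.matrix(dist)
  rownames(D) <- normalize_taxon_names(rownames(D))
  colnames(D) <- normalize_taxon_names(colnames(D))

  if (is.data.frame(orders)) {
    ord <- stats::setNames(as.character(orders[[2]]),
                           normalize_taxon_names(orders[[1]]))
  } else {
    ord <- stats::setNames(as.character(orders), normalize_taxon_names(names(orders)))
  }

  taxa <- rownames(M)
  miss_d <- setdiff(taxa, rownames(D))
  miss_g <- setdiff(rownames(D), taxa)
  if (length(miss_d) || length(miss_g)) {
    stop("taxa present in one matrix only: ",
         paste(c(miss_d, miss_g), collapse = ", "))
  }
  miss_o <- setdiff(taxa, names(ord))
  if (length(miss_o)) {
    stop("unclassified taxa: ", paste(miss_o, collapse = ", "))
  }
  D <- D[taxa, taxa]
  ord <- ord[taxa]

  sizes <- table(ord)
  small <- names(sizes)[sizes < min_taxa_per_order]
  if (length(small)) {
    message("dropping orders with < ", min_taxa_per_order, " taxa: ",
            paste(small, collapse = ", "))
  }
  keep_orders <- setdiff(names(sizes), small)

  rows <- list()
  for (o in keep_orders) {
    idx <- which(ord == o)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    rows[[o]] <- data.frame(
      taxon_a = taxa[cmb[1, ]], taxon_b = taxa[cmb[2, ]], order = o,
      d = D[cbind(cmb[1, ], cmb[2, ])],
      y = M[cbind(cmb[1, ], cmb[2, ])], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pair_data", "data.frame")
  attr(out, "response") <- if (inherits(goc, "goc_matrix")) response else "as-given"
  out
}

#' Remove one order from a pair dataset
#'
#' @param pairs a `pair_data` data.frame.
#' @param order_name the order to drop (must be present).
#' @return the pair dataset without that order's pairs.
#' @export
subset_excluding <- function(pairs, order_name) {
  if (!order_name %in% pairs$order) {
    stop("order '", order_name, "' not present in the pair dataset")
  }
  resp <- attr(pairs, "response")
  out <- pairs[pairs$order != order_name, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_data", "data.frame")
  attr(out, "response") <- resp
  out
}

## Response/predictor transform per model form; rows failing the domain
## requirements of the transform (y <= 0 under log models, d <= 0 under the
## power law) are flagged, not silently lost.
transform_pairs <- function(d, y, form) {
  if (form == "linear") {
    list(xt = d, yt = y, ok = is.finite(d) & is.finite(y))
  } else if (form == "exponential") {
    ok <- is.finite(d) & is.finite(y) & y > 0
    list(xt = d, yt = suppressWarnings(log(y)), ok = ok)
  } else if (form == "power") {
    ok <- is.finite(d) & is.finite(y) & y > 0 & d > 0
    list(xt = suppressWarnings(log(d)), yt = suppressWarnings(log(y)), ok = ok)
  } else {
    stop("unknown model form '", form, "'")
  }
}

## Core least-squares engine on the transformed scale. Returns coefficients,
## sums of squares, the overall F against the intercept-only model, and the
## interaction (common-slope vs per-group-slope) F when grouping = by_order.
fit_engine <- function(xt, yt, order, grouping) {
  n <- length(yt)
  if (grouping == "by_order") {
    f <- factor(order)
    m <- nlevels(f)
    Z <- matrix(0, n, m)
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    X <- cbind(Z, Z * xt)
    colnames(X) <- c(paste0("int.", levels(f)), paste0("slope.", levels(f)))
    p <- 2L * m
  } else {
    m <- 1L
    X <- cbind(intercept = rep(1, n), slope = xt)
    p <- 2L
  }
  fit <- stats::lm.fit(X, yt)
  RSS <- sum(fit$residuals^2)
  TSS <- sum((yt - mean(yt))^2)
  ESS <- TSS - RSS
  df_model <- p - 1L
  df_resid <- n - p
  Fstat <- (ESS / df_model) / (RSS / df_resid)

  res <- list(coefficients = fit$coefficients, fitted = fit$fitted.values,
              residuals = fit$residuals, RSS = RSS, ESS = ESS, TSS = TSS,
              df_model = df_model, df_resid = df_resid, F = Fstat,
              n = n, m = m)
  if (grouping == "by_order" && m >= 2L) {
    Xr <- cbind(Z, slope = xt)
    RSS_red <- sum(stats::lm.fit(Xr, yt)$residuals^2)
    q <- m - 1L
    res$F_interaction <- ((RSS_red - RSS) / q) / (RSS / df_resid)
    res$df_interaction <- c(q, df_resid)
    res$RSS_reduced <- RSS_red
  }
  res
}

#' Fit a synteny decay model
#'
#' Ordinary least squares fit of synteny score against phylogenetic distance
#' under one of three forms, each linearised by its natural transform:
#'
#' * `linear`: `y ~ d`
#' * `exponential`: `log(y) ~ d` (so `y = exp(a + b d)`, decay rate `-b`)
#' * `power`: `log(y) ~ log(d)` (so `y = exp(a) d^b`)
#'
#' With `grouping = "by_order"` (default) each order receives its own
#' intercept and slope in a single design, giving `2m` parameters for `m`
#' orders; the model F statistic compares the fit to the intercept-only model
#' on the same transformed response, on `(2m - 1, n - 2m)` degrees of
#' freedom. Because the pairwise observations are not independent, this F is
#' descriptive; use [permutation_test()] (or [compare_models()]) for
#' inference.
#'
#' Pairs outside the transform's domain (`y <= 0` under log models, `d <= 0`
#' under the power law) are dropped with their count reported; if more than
#' `max_drop_frac` of pairs would be dropped, the fit stops unless
#' `allow_drop = TRUE`.
#'
#' @param pairs a `pair_data` data.frame from [build_pair_dataset()] (any
#'   data.frame with columns d, y and, for by-order fits, order works).
#' @param form "exponential", "linear" or "power".
#' @param grouping "by_order" (per-order intercept and slope) or "common".
#' @param max_drop_frac largest tolerated fraction of domain-dropped pairs
#'   (default 0.01).
#' @param allow_drop set TRUE to proceed past `max_drop_frac` with a warning.
#' @return object of class `decay_fit`.
#' @export
fit_decay <- function(pairs, form = c("exponential", "linear", "power"),
                      grouping = c("by_order", "common"),
                      max_drop_frac = 0.01, allow_drop = FALSE) {
  form <- match.arg(form)
  grouping <- match.arg(grouping)
  stopifnot(all(c("d", "y") %in% names(pairs)))
  if (grouping == "by_order" && !"order" %in% names(pairs)) {
    stop("by_order grouping needs an 'order' column")
  }
  tr <- transform_pairs(pairs$d, pairs$y, form)
  n_dropped <- sum(!tr$ok)
  if (n_dropped > 0) {
    frac <- n_dropped / nrow(pairs)
    msg <- sprintf("%d of %d pairs outside the %s model domain dropped",
                   n_dropped, nrow(pairs), form)
    if (frac > max_drop_frac && !allow_drop) {
      stop(msg, " (", round(100 * frac, 1),
           "% > limit); pass allow_drop = TRUE to proceed")
    }
    warning(msg)
  }
  keep <- tr$ok
  used <- pairs[keep, , drop = FALSE]
  eng <- fit_engine(tr$xt[keep], tr$yt[keep],
                    if (grouping == "by_order") used$order else NULL, grouping)

  if (grouping == "by_order") {
    levs <- levels(factor(used$order))
    coefs <- cbind(intercept = eng$coefficients[paste0("int.", levs)],
                   slope = eng$coefficients[paste0("slope.", levs)])
    rownames(coefs) <- levs
  } else {
    coefs <- matrix(eng$coefficients, 1,
                    dimnames = list("common", c("intercept", "slope")))
  }

  structure(list(
    coefficients = coefs, form = form, grouping = grouping,
    F = eng$F, df = c(eng$df_model, eng$df_resid),
    F_interaction = eng$F_interaction, df_interaction = eng$df_interaction,
    RSS = eng$RSS, ESS = eng$ESS, TSS = eng$TSS,
    sigma = sqrt(eng$RSS / eng$df_resid),
    n = eng$n, n_orders = eng$m, n_dropped = n_dropped,
    data = used, transformed = list(xt = tr$xt[keep], yt = tr$yt[keep]),
    fitted_transformed = eng$fitted, residuals_transformed = eng$residuals,
    response = attr(pairs, "response") %||% "as-given",
    call = match.call()),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", x$form, "model,", x$grouping, "grouping\n")
  cat("  n =", x$n, "pairs",
      if (x$n_dropped) paste0("(", x$n_dropped, " dropped)"), "\n")
  cat(sprintf("  F(%d, %d) = %.4g\n", x$df[1], x$df[2], x$F))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
fitted.decay_fit <- function(object, ...) {
  back_transform(object$fitted_transformed, object$form)
}

#' @export
residuals.decay_fit <- function(object,
                                type = c("transformed", "response"), ...) {
  type <- match.arg(type)
  if (type == "transformed") {
    object$residuals_transformed
  } else {
    object$data$y - fitted(object)
  }
}

back_transform <- function(eta, form) {
  if (form == "linear") eta else exp(eta)
}

#' Predict from a decay fit
#'
#' @param object a `decay_fit`.
#' @param newdata data.frame with column `d` and, for by-order fits, `order`;
#'   defaults to the fitted data.
#' @param type "response" (synteny-score scale, default) or "transformed"
#'   (the scale the least squares ran on).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.decay_fit <- function(object, newdata = NULL,
                              type = c("response", "transformed"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  d <- newdata$d
  xt <- if (object$form == "power") log(d) else d
  if (object$grouping == "by_order") {
    o <- as.character(newdata$order)
    unknown <- setdiff(unique(o), rownames(object$coefficients))
    if (length(unknown)) {
      stop("order(s) not in fit: ", paste(unknown, collapse = ", "))
    }
    eta <- object$coefficients[o, "intercept"] +
      object$coefficients[o, "slope"] * xt
  } else {
    eta <- object$coefficients[1, "intercept"] +
      object$coefficients[1, "slope"] * xt
  }
  eta <- unname(eta)
  if (type == "transformed") eta else back_transform(eta, object$form)
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- predict(object, type = "transformed")
  out <- as.data.frame(replicate(nsim, {
    back_transform(eta + stats::rnorm(length(eta), 0, object$sigma),
                   object$form)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.decay_fit <- function(object, ...) {
  rate <- switch(object$form,
                 exponential = -object$coefficients[, "slope"],
                 power = -object$coefficients[, "slope"],
                 linear = -object$coefficients[, "slope"])
  structure(list(fit = object, decay_rate = rate), class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  f <- x$fit
  cat("Synteny decay model:", f$form, "(", f$grouping, "grouping )\n")
  cat("Response:", f$response, "GOC score;", f$n, "within-order pairs")
  if (f$n_dropped) cat(";", f$n_dropped, "pairs dropped (transform domain)")
  cat("\n\nCoefficients (", switch(f$form,
      exponential = "log y ~ d", power = "log y ~ log d", linear = "y ~ d"),
      "):\n", sep = "")
  print(round(f$coefficients, 4))
  cat("\nDecay rate (-slope) per unit phylogenetic distance:\n")
  print(round(x$decay_rate, 4))
  cat(sprintf("\nModel F(%d, %d) = %.5g vs intercept-only\n",
              f$df[1], f$df[2], f$F))
  if (!is.null(f$F_interaction)) {
    cat(sprintf("Slope-heterogeneity F(%d, %d) = %.5g (common vs per-order slopes)\n",
                f$df_interaction[1], f$df_interaction[2], f$F_interaction))
  }
  cat("Note: pairwise observations are non-independent; use permutation_test()\n")
  cat("for p-values rather than the parametric F distribution.\n")
  invisible(x)
}

#' Plot a decay fit
#'
#' Scatter of synteny score against phylogenetic distance, coloured by order,
#' with the fitted decay curve per order.
#'
#' @param x a `decay_fit`.
#' @param log_y plot the response axis on a log scale (default TRUE for log
#'   models).
#' @param ... passed to [graphics::plot()].
#' @export
plot.decay_fit <- function(x, log_y = x$form != "linear", ...) {
  df <- x$data
  ords <- rownames(x$coefficients)
  cols <- grDevices::hcl.colors(max(3L, length(ords)), "Dark 3")[seq_along(ords)]
  names(cols) <- ords
  col <- if (x$grouping == "by_order") cols[df$order] else "grey30"
  graphics::plot(df$d, df$y, col = col, pch = 16, cex = 0.6,
                 log = if (log_y) "y" else "",
                 xlab = "phylogenetic distance (unit tree height)",
                 ylab = paste0("GOC score (", x$response, ")"), ...)
  for (o in ords) {
    dd <- if (x$grouping == "by_order") df$d[df$order == o] else df$d
    grid_d <- seq(min(dd), max(dd), length.out = 100)
    nd <- data.frame(d = grid_d, order = o)
    graphics::lines(grid_d, predict(x, nd), col = cols[[o]], lwd = 2)
  }
  if (x$grouping == "by_order") {
    graphics::legend("topright", legend = ords, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
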