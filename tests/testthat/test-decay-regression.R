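# Pair dataset construction, decay model fitting, permutational inference.

test_that("pair dataset holds exactly the within-order pairs", {
  taxa <- c("a1", "a2", "b1", "b2")
  orders <- stats::setNames(c("A", "A", "B", "B"), taxa)
  M <- matrix(runif(16, 0.2, 1), 4, 4, dimnames = list(taxa, taxa))
  M[lower.tri(M)] <- t(M)[lower.tri(M)]; diag(M) <- 1
  D <- matrix(runif(16, 0.1, 2), 4, 4, dimnames = list(taxa, taxa))
  D[lower.tri(D)] <- t(D)[lower.tri(D)]; diag(D) <- 0
  pairs <- build_pair_dataset(M, D, orders, min_taxa_per_order = 2)
  expect_equal(nrow(pairs), 2)                 # C(2,2) per order
  expect_setequal(pairs$order, c("A", "B"))
  expect_equal(pairs$y[pairs$order == "A"], M["a1", "a2"])
  expect_equal(pairs$d[pairs$order == "B"], D["b1", "b2"])
})

test_that("pair counts and df bookkeeping match the insect-study design", {
  # 143 taxa in 5 orders sized 79/23/16/14/11: 3,081 pairs in the largest
  # order and 3,600 in total; by-order df (9, 3590); interaction (4, 3590);
  # after dropping the largest order, 519 pairs and interaction df (3, 511)
  sizes <- c(Lepidoptera = 79, Coleoptera = 23, Diptera = 16,
             Hymenoptera = 14, Hemiptera = 11)
  set.seed(101)
  study <- sim_matrix_study(unname(sizes),
                            decay = list(order1 = 1, order2 = 2, order3 = 3,
                                         order4 = 2.5, order5 = 1.5))
  names(study$orders) <- names(study$orders)
  ords <- stats::setNames(names(sizes)[as.integer(sub("order", "", study$orders))],
                          names(study$orders))
  expect_equal(length(ords), 143)
  pairs <- build_pair_dataset(study$M, study$D, ords)
  expect_equal(nrow(pairs), 3600)
  expect_equal(sum(pairs$order == "Lepidoptera"), 3081)

  fit <- fit_decay(pairs, "exponential")
  expect_equal(fit$df, c(9, 3590))
  expect_equal(fit$df_interaction, c(4, 3590))

  sub <- subset_excluding(pairs, "Lepidoptera")
  expect_equal(nrow(sub), 519)
  fs <- fit_decay(sub, "exponential")
  expect_equal(fs$df_interaction, c(3, 511))
})

test_that("double-loop oracle reproduces the pair dataset on random classifications", {
  set.seed(55)
  study <- sim_matrix_study(c(5, 6, 4))
  pairs <- build_pair_dataset(study$M, study$D, study$orders,
                              min_taxa_per_order = 2)
  taxa <- names(study$orders)
  want <- 0
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i < j && study$orders[i] == study$orders[j]) {
      want <- want + 1
      row <- pairs[pairs$taxon_a == taxa[i] & pairs$taxon_b == taxa[j], ]
      expect_equal(nrow(row), 1)
      expect_equal(row$y, study$M[i, j])
      expect_equal(row$d, study$D[i, j])
    }
  }
  expect_equal(nrow(pairs), want)
})

test_that("mismatched taxa and unclassified taxa are reported", {
  study <- sim_matrix_study(c(4, 4), seed = 1)
  D2 <- study$D[-1, -1]
  expect_error(build_pair_dataset(study$M, D2, study$orders), "t001")
  o2 <- study$orders[-1]
  expect_error(build_pair_dataset(study$M, study$D, o2), "unclassified")
})

test_that("small orders are dropped with a message", {
  study <- sim_matrix_study(c(6, 2), seed = 3)
  expect_message(pairs <- build_pair_dataset(study$M, study$D, study$orders,
                                             min_taxa_per_order = 4),
                 "order2")
  expect_setequal(unique(pairs$order), "order1")
})

test_that("noiseless exponential data are recovered exactly", {
  d <- seq(0.1, 2, length.out = 40)
  pairs <- data.frame(order = "X", d = d, y = exp(2 - 3 * d))
  fit <- fit_decay(pairs, "exponential")
  expect_equal(unname(coef(fit)["X", "slope"]), -3, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["X", "intercept"]), 2, tolerance = 1e-10)
  expect_lt(fit$RSS, 1e-18)
  # power-law data likewise under the power form
  pairs2 <- data.frame(order = "X", d = d, y = exp(1) * d^-1.5)
  fit2 <- fit_decay(pairs2, "power")
  expect_equal(unname(coef(fit2)["X", "slope"]), -1.5, tolerance = 1e-10)
})

test_that("coefficients land within 3 standard errors under log-noise", {
  set.seed(202)
  pairs <- sim_pairs(2, 20, intercepts = c(0.5, -0.2),
                     slopes = c(-1.5, -3), sigma = 0.05)
  fit <- fit_decay(pairs, "exponential")
  X <- stats::model.matrix(~ 0 + factor(order) + factor(order):d, data = pairs)
  se <- sqrt(diag(solve(crossprod(X))) * fit$sigma^2)
  est <- c(coef(fit)[, "intercept"], coef(fit)[, "slope"])
  truth <- c(0.5, -0.2, -1.5, -3)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("fits agree with the normal-equations oracle to 1e-8 relative", {
  set.seed(303)
  for (rep in 1:6) {
    m <- sample(2:4, 1)
    pairs <- sim_pairs(m, sample(15:40, 1),
                       intercepts = runif(m, -1, 1),
                       slopes = runif(m, -4, -0.5), sigma = 0.2)
    for (form in c("linear", "exponential", "power")) {
      fit <- fit_decay(pairs, form)
      want <- oracle_ols(pairs$d, pairs$y, pairs$order, form)
      expect_equal(unname(coef(fit)[, "intercept"]), c(want$intercepts),
                   tolerance = 1e-8)
      expect_equal(unname(coef(fit)[, "slope"]), c(want$slopes),
                   tolerance = 1e-8)
      expect_equal(fit$F, want$F, tolerance = 1e-8)
      expect_equal(fit$df, want$df)
    }
  }
})

test_that("degrees of freedom follow the 2m-parameter design for m = 2..6", {
  set.seed(404)
  for (m in 2:6) {
    pairs <- sim_pairs(m, 12)
    fit <- fit_decay(pairs, "exponential")
    n <- nrow(pairs)
    expect_equal(fit$df, c(2 * m - 1, n - 2 * m))
    expect_equal(fit$df[1] + fit$df[2] + 1, n)
    expect_equal(fit$df_interaction, c(m - 1, n - 2 * m))
  }
})

test_that("pairs outside the log domain are dropped or escalate", {
  pairs <- sim_pairs(2, 30, sigma = 0.05)
  pairs$y[1] <- 0
  expect_warning(fit <- fit_decay(pairs, "exponential", allow_drop = TRUE),
                 "dropped")
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$n, nrow(pairs) - 1)
  pairs$y[1:5] <- 0                       # > 1% of 60 pairs
  expect_error(fit_decay(pairs, "exponential"), "allow_drop")
  # linear form keeps zero responses
  expect_silent(fit_decay(pairs, "linear"))
})

test_that("predictions back-transform onto the response scale", {
  set.seed(9)
  pairs <- sim_pairs(2, 25, slopes = c(-1, -2), sigma = 0.05)
  fit <- fit_decay(pairs, "exponential")
  pr <- predict(fit)
  expect_equal(log(pr), predict(fit, type = "transformed"))
  expect_equal(pr, exp(fit$fitted_transformed))
  expect_equal(residuals(fit, "response"), pairs$y - pr)
  nd <- data.frame(d = c(0.5, 1), order = "order1")
  expect_equal(predict(fit, nd),
               exp(coef(fit)["order1", "intercept"] +
                     coef(fit)["order1", "slope"] * c(0.5, 1)))
  expect_error(predict(fit, data.frame(d = 1, order = "nope")), "not in fit")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_equal(dim(sims), c(nrow(pairs), 2))
  expect_true(all(sims > 0))
})

test_that("permutation p-values respect the add-one bound and reproduce by seed", {
  set.seed(31)
  study <- sim_matrix_study(c(10, 10), decay = list(order1 = 2, order2 = 2),
                            sigma = 0.1)
  p1 <- permutation_test(study$M, study$D, study$orders, n_perm = 99, seed = 17)
  p2 <- permutation_test(study$M, study$D, study$orders, n_perm = 99, seed = 17)
  expect_identical(p1$null_F, p2$null_F)
  expect_identical(p1$p, p2$p)
  expect_gte(p1$p, 1 / 100)
  expect_lte(p1$p, 1)
  # strong signal: observed F separates completely from the null
  expect_equal(p1$p, 1 / 100)
  expect_error(permutation_test(study$M, study$D, study$orders, n_perm = 0),
               "n_perm")
})

test_that("interaction test requires 2+ orders and detects none when absent", {
  pairs1 <- sim_pairs(1, 30)
  expect_error(interaction_test(pairs1, n_perm = 19), "at least 2 orders")
  set.seed(61)
  pairs <- sim_pairs(3, 40, slopes = rep(-2, 3), sigma = 0.1)
  it <- interaction_test(pairs, n_perm = 99, seed = 1)
  expect_gte(it$p, 0.01)
  expect_equal(it$df[1], 2)
})

test_that("excluding orders partitions the pair dataset", {
  pairs <- sim_pairs(3, 10)
  expect_error(subset_excluding(pairs, "orderZ"), "not present")
  removed <- lapply(paste0("order", 1:3), function(o) {
    pairs[pairs$order == o, ]
  })
  expect_equal(nrow(subset_excluding(pairs, "order2")), 20)
  expect_equal(sum(vapply(removed, nrow, 1L)), nrow(pairs))
})

test_that("model comparison ranks forms and carries permutational p-values", {
  set.seed(71)
  study <- sim_matrix_study(c(12, 12), decay = list(order1 = 1.5, order2 = 3),
                            sigma = 0.1)
  cmp <- compare_models(study$M, study$D, study$orders, n_perm = 49, seed = 2)
  expect_equal(cmp$form[1], "exponential")
  expect_true(all(diff(cmp$F) <= 0))
  expect_true(all(cmp$p >= 1 / 50 & cmp$p <= 1))
})
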