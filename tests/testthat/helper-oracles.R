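# Fixture builders and independent oracles used across the suite.

## quick gene_map from a list of chromosome -> gene-id vectors
mk_map <- function(taxon, chroms, spacing = 10000, status = "Complete") {
  parts <- lapply(names(chroms), function(s) {
    g <- chroms[[s]]
    st <- (seq_along(g) - 1) * spacing + 1
    data.frame(gene_id = g, seq_id = s, start = st, end = st + 1999,
               strand = "+", status = status, stringsAsFactors = FALSE)
  })
  gene_map(taxon, do.call(rbind, parts))
}

## random genome over n genes / k chromosomes, order shuffled
random_chroms <- function(n, k, shuffle = TRUE) {
  genes <- sprintf("g%04d", seq_len(n))
  if (shuffle) genes <- sample(genes)
  sizes <- diff(c(0, sort(sample(seq_len(n - 1), k - 1)), n))
  chroms <- split(genes, rep(seq_len(k), sizes))
  names(chroms) <- sprintf("chr%02d", seq_len(k))
  chroms
}

## independent GOC oracle: per-gene loops over explicit ordered lists,
## windows via index arithmetic and set intersection
oracle_goc <- function(map_a, map_b, mode = "strict", k = 2) {
  coords <- function(m) m$loci[!is.na(m$loci$start), ]
  ga <- coords(map_a)$gene_id
  gb <- coords(map_b)$gene_id
  shared <- intersect(ga, gb)
  windows <- function(map) {
    loci <- map$loci[!is.na(map$loci$start) & map$loci$gene_id %in% shared, ]
    w <- list()
    for (s in unique(loci$seq_id)) {
      sub <- loci[loci$seq_id == s, ]
      ord <- sub$gene_id[order(sub$start, sub$end, sub$gene_id)]
      for (i in seq_along(ord)) {
        lo <- max(1, i - k); hi <- min(length(ord), i + k)
        w[[ord[i]]] <- setdiff(ord[lo:hi], ord[i])
      }
    }
    w
  }
  wa <- windows(map_a)
  wb <- windows(map_b)
  scores <- c()
  for (g in shared) {
    A <- wa[[g]]; B <- wb[[g]]
    if (mode == "strict") {
      if (length(A) == 2 * k && length(B) == 2 * k) {
        scores[g] <- length(intersect(A, B)) / (2 * k)
      }
    } else {
      dn <- max(length(A), length(B))
      if (dn > 0) scores[g] <- length(intersect(A, B)) / dn
    }
  }
  list(per_gene = scores, total = sum(scores),
       normalized = if (length(scores)) sum(scores) / length(scores) else NA)
}

## patristic-distance oracle: root paths from the raw edge table
oracle_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  plen <- numeric(nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root_path <- function(i) {
    path <- c(); node <- i
    while (parent[node] != 0) { path <- c(path, node); node <- parent[node] }
    path
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) {
    pi_ <- root_path(i)
    for (j in (i + 1):nt) {
      pj <- root_path(j)
      onpath <- c(setdiff(pi_, pj), setdiff(pj, pi_))
      d[i, j] <- d[j, i] <- sum(plen[onpath])
    }
  }
  d
}

## normal-equations OLS oracle for the by-order decay design
oracle_ols <- function(d, y, order, form) {
  yt <- switch(form, linear = y, exponential = log(y), power = log(y))
  xt <- switch(form, power = log(d), d)
  f <- factor(order)
  m <- nlevels(f)
  X <- matrix(0, length(yt), 2 * m)
  for (i in seq_len(m)) {
    sel <- f == levels(f)[i]
    X[sel, i] <- 1
    X[sel, m + i] <- xt[sel]
  }
  beta <- solve(t(X) %*% X, t(X) %*% yt)
  res <- yt - X %*% beta
  RSS <- sum(res^2)
  TSS <- sum((yt - mean(yt))^2)
  df1 <- 2 * m - 1
  df2 <- length(yt) - 2 * m
  list(intercepts = beta[seq_len(m)], slopes = beta[m + seq_len(m)],
       F = ((TSS - RSS) / df1) / (RSS / df2), RSS = RSS,
       df = c(df1, df2))
}

## pair data simulated directly from a decay law (no genomes involved)
sim_pairs <- function(n_orders = 2, pairs_per_order = 50,
                      intercepts = rep(0, n_orders),
                      slopes = rep(-2, n_orders), sigma = 0.1,
                      form = "exponential", d_range = c(0.05, 2)) {
  rows <- lapply(seq_len(n_orders), function(i) {
    d <- runif(pairs_per_order, d_range[1], d_range[2])
    eta <- intercepts[i] + slopes[i] *
      (if (form == "power") log(d) else d)
    y <- if (form == "linear") {
      eta + rnorm(pairs_per_order, 0, sigma)
    } else {
      exp(eta + rnorm(pairs_per_order, 0, sigma))
    }
    data.frame(taxon_a = sprintf("o%d_a%03d", i, seq_len(pairs_per_order)),
               taxon_b = sprintf("o%d_b%03d", i, seq_len(pairs_per_order)),
               order = paste0("order", i), d = d, y = y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pair_data", "data.frame")
  out
}

## symmetric matrices + classification for taxon-level permutation tests
sim_matrix_study <- function(order_sizes, decay = NULL, sigma = 0.1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  orders <- rep(paste0("order", seq_along(order_sizes)), order_sizes)
  taxa <- sprintf("t%03d", seq_along(orders))
  names(orders) <- taxa
  nt <- length(taxa)
  tr <- ape::rtree(nt, tip.label = sample(taxa))
  D <- patristic_matrix(tr, rescale = TRUE)[taxa, taxa]
  M <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      y <- if (is.null(decay)) {
        exp(rnorm(1, 0, sigma))          # independent of distance
      } else {
        rate <- decay[[orders[i]]] %||% decay[[1]]
        exp(-rate * D[i, j] + rnorm(1, 0, sigma))
      }
      M[i, j] <- M[j, i] <- y
    }
  }
  diag(M) <- 1
  list(M = M, D = D, orders = orders)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
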