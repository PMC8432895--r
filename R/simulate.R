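#' Simulation configuration for gene-order evolution
#'
#' Bundles the parameters of the neutral rearrangement simulator. Events of
#' three classes occur independently along each branch with Poisson counts
#' proportional to branch length:
#'
#' * intra-chromosomal (`rate_intra`): with probability 0.5 a segment
#'   inversion (segment length geometric with mean `inversion_mean_len`,
#'   clipped to the chromosome), otherwise a single-gene transposition to a
#'   uniform position on the same chromosome;
#' * inter-chromosomal (`rate_inter`): a single gene moved to a uniform
#'   position on a uniformly chosen other chromosome;
#' * loss (`rate_loss`): a uniformly chosen gene becomes Missing.
#'
#' The defaults emulate an insect-scale study: ~100 chromosome-level genomes
#' in 5 named orders, 1300 shared single-copy genes on 15 chromosomes,
#' frequent intra-chromosomal reshuffling against rare translocations, and
#' order-specific shuffling rates spanning roughly an order of magnitude so
#' that gene-order conservation decays at visibly different rates per order.
#'
#' @param n_chromosomes chromosomes in the ancestral genome.
#' @param n_genes single-copy genes in the ancestral genome.
#' @param tree an [ape::phylo]; defaults to [sim_order_tree()] with 5 orders
#'   of 20 taxa, unit height.
#' @param orders named character vector taxon -> order; defaults to the
#'   classification that comes with the default tree.
#' @param rate_intra expected intra-chromosomal events per unit branch
#'   length.
#' @param rate_inter expected inter-chromosomal single-gene translocations
#'   per unit branch length.
#' @param rate_loss expected gene losses per unit branch length.
#' @param inversion_mean_len mean genes per inverted segment (>= 1).
#' @param group_rates named list order -> list(rate_intra =, rate_inter =)
#'   overriding the base rates on branches wholly within that order's clade.
#' @param seed RNG seed recorded and used by [simulate_tips()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 15L, n_genes = 1300L, tree = NULL,
                       orders = NULL, rate_intra = 650, rate_inter = 5,
                       rate_loss = 5, inversion_mean_len = 8,
                       group_rates = NULL, seed = NULL) {
  if (n_genes < n_chromosomes) stop("n_genes must be >= n_chromosomes")
  if (any(c(rate_intra, rate_inter, rate_loss) < 0)) {
    stop("rates must be non-negative")
  }
  if (inversion_mean_len < 1) stop("inversion_mean_len must be >= 1")
  if (is.null(tree)) {
    ot <- sim_order_tree()
    tree <- ot$tree
    if (is.null(orders)) orders <- ot$orders
    if (is.null(group_rates)) {
      ## order-specific shuffling intensity: one slow decayer
      ## (Lepidoptera-like), one fast, spanning ~8x
      fac <- c(0.3, 0.6, 1, 1.5, 2.5)
      levs <- unique(unname(orders))
      group_rates <- stats::setNames(lapply(seq_along(levs), function(i) {
        list(rate_intra = rate_intra * fac[((i - 1) %% 5) + 1],
             rate_inter = rate_inter)
      }), levs)
    }
  }
  if (is.null(orders)) {
    stop("orders (taxon -> order classification) required with a custom tree")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes), tree = tree, orders = orders,
                 rate_intra = rate_intra, rate_inter = rate_inter,
                 rate_loss = rate_loss,
                 inversion_mean_len = inversion_mean_len,
                 group_rates = group_rates, seed = seed),
            class = "sim_config")
}

#' Simulate an order-structured ultrametric phylogeny
#'
#' Builds a unit-height tree of `n_orders` monophyletic groups on a ladder
#' backbone (deep splits between 0.7 and 1.0 of tree height), each group a
#' coalescent subtree of `taxa_per_order` tips with crown depth
#' `crown_depth`. Used as the default study design of the simulator.
#'
#' @param n_orders number of groups (default 5; names cycle through common
#'   insect orders).
#' @param taxa_per_order tips per group (default 20).
#' @param crown_depth depth of each group's crown (default 0.4).
#' @param order_names optional character vector of group names.
#' @return list with `tree` (an [ape::phylo]) and `orders` (named character
#'   vector taxon -> order).
#' @export
sim_order_tree <- function(n_orders = 5L, taxa_per_order = 20L,
                           crown_depth = 0.4, order_names = NULL) {
  stopifnot(crown_depth > 0, crown_depth < 0.7)
  if (is.null(order_names)) {
    pool <- c("Coleoptera", "Lepidoptera", "Diptera", "Hymenoptera",
              "Hemiptera", "Orthoptera", "Odonata", "Blattodea")
    order_names <- if (n_orders <= length(pool)) pool[seq_len(n_orders)] else
      paste0("Order", seq_len(n_orders))
  }
  sub_nwk <- character(n_orders)
  orders <- character(0)
  for (i in seq_len(n_orders)) {
    labs <- sprintf("%s_sp%02d", order_names[i], seq_len(taxa_per_order))
    orders <- c(orders, stats::setNames(rep(order_names[i], taxa_per_order),
                                        labs))
    if (taxa_per_order == 1L) {
      sub_nwk[i] <- labs
    } else {
      st <- ape::rcoal(taxa_per_order, tip.label = labs)
      depth <- max(ape::node.depth.edgelength(st))
      st$edge.length <- st$edge.length * crown_depth / depth
      sub_nwk[i] <- sub(";$", "", ape::write.tree(st))
    }
  }
  ## ladder backbone: successive joins between 0.7 and 1.0 of tree height
  joins <- seq(0.7, 1.0, length.out = max(n_orders - 1L, 1L))
  nwk <- sprintf("%s:%g", sub_nwk[1], joins[1] - crown_depth)
  cur_h <- joins[1]
  for (i in seq_len(n_orders - 1L)) {
    stem_i <- joins[i] - crown_depth
    nwk <- sprintf("(%s,%s:%g)", nwk, sub_nwk[i + 1], stem_i)
    if (i < n_orders - 1L) {
      nwk <- sprintf("%s:%g", nwk, joins[i + 1] - joins[i])
      cur_h <- joins[i + 1]
    }
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  list(tree = tree, orders = orders)
}

## internal genome representation while evolving: list of character vectors
## (ordered gene ids per chromosome) + lost gene ids
map_to_chromlist <- function(map) {
  loci <- map$loci[!is.na(map$loci$start), ]
  seqs <- unique(loci$seq_id)
  chrom <- lapply(seqs, function(s) ordered_gene_list(map, s))
  names(chrom) <- seqs
  list(chrom = chrom,
       lost = map$loci$gene_id[map$loci$status == "Missing"])
}

chromlist_to_map <- function(cl, taxon_id, spacing = 10000L, gene_len = 2000L) {
  parts <- lapply(names(cl$chrom), function(s) {
    g <- cl$chrom[[s]]
    if (length(g) == 0L) return(NULL)
    start <- (seq_along(g) - 1) * spacing + 1
    data.frame(gene_id = g, seq_id = s, start = start,
               end = start + gene_len - 1, strand = "+",
               status = "Complete", stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, parts)
  if (length(cl$lost)) {
    loci <- rbind(loci, data.frame(
      gene_id = cl$lost, seq_id = NA_character_, start = NA_real_,
      end = NA_real_, strand = "unknown", status = "Missing",
      stringsAsFactors = FALSE))
  }
  gene_map(taxon_id, loci, chromosome_ids = names(cl$chrom))
}

#' Simulate the ancestral genome
#'
#' Distributes `n_genes` over `n_chromosomes` near-evenly (multinomial), in
#' order g0001..gN, with synthetic coordinates spaced 10 kb apart, all
#' Complete.
#'
#' @param config a [sim_config()].
#' @return a [gene_map()] for taxon "ancestor".
#' @export
simulate_ancestral_genome <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$n_chromosomes
  sizes <- as.integer(stats::rmultinom(1, config$n_genes - k,
                                       rep(1 / k, k))) + 1L
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  chrom <- split(genes, rep(seq_len(k), sizes))
  names(chrom) <- sprintf("chr%02d", seq_len(k))
  chromlist_to_map(list(chrom = chrom, lost = character()), "ancestor")
}

## one rearrangement step on a chromlist; returns list(cl, type)
apply_intra <- function(cl, inversion_mean_len) {
  sizes <- lengths(cl$chrom)
  if (sum(sizes) < 2L) return(list(cl = cl, type = "none"))
  ci <- sample.int(length(sizes), 1L, prob = sizes)
  g <- cl$chrom[[ci]]
  n <- length(g)
  if (stats::runif(1) < 0.5) {                       # segment inversion
    L <- min(1L + stats::rgeom(1, 1 / inversion_mean_len), n)
    s <- sample.int(n - L + 1L, 1L)
    g[s:(s + L - 1L)] <- rev(g[s:(s + L - 1L)])
    type <- "inversion"
  } else {                                           # single-gene transposition
    if (n >= 2L) {
      i <- sample.int(n, 1L)
      gene <- g[i]
      g <- g[-i]
      j <- sample.int(length(g) + 1L, 1L)
      g <- append(g, gene, after = j - 1L)
    }
    type <- "transposition"
  }
  cl$chrom[[ci]] <- g
  list(cl = cl, type = type)
}

apply_inter <- function(cl) {
  sizes <- lengths(cl$chrom)
  if (length(sizes) < 2L || sum(sizes) < 1L) return(cl)
  ci <- sample.int(length(sizes), 1L, prob = sizes)
  g <- cl$chrom[[ci]]
  i <- sample.int(length(g), 1L)
  gene <- g[i]
  cl$chrom[[ci]] <- g[-i]
  others <- setdiff(seq_along(sizes), ci)
  cj <- others[sample.int(length(others), 1L)]
  h <- cl$chrom[[cj]]
  j <- sample.int(length(h) + 1L, 1L)
  cl$chrom[[cj]] <- append(h, gene, after = j - 1L)
  cl
}

apply_loss <- function(cl) {
  sizes <- lengths(cl$chrom)
  if (sum(sizes) < 1L) return(cl)
  ci <- sample.int(length(sizes), 1L, prob = sizes)
  g <- cl$chrom[[ci]]
  i <- sample.int(length(g), 1L)
  cl$lost <- c(cl$lost, g[i])
  cl$chrom[[ci]] <- g[-i]
  cl
}

#' Evolve a genome along one branch
#'
#' Applies Poisson numbers of intra-chromosomal, inter-chromosomal and loss
#' events (see [sim_config()]) and re-spaces coordinates.
#'
#' @param map a [gene_map()].
#' @param branch_length branch length (>= 0).
#' @param rates list with rate_intra, rate_inter, rate_loss.
#' @param inversion_mean_len mean inverted-segment length in genes.
#' @return list with `map` (evolved [gene_map()]) and `events` (named counts
#'   of inversion, transposition, inter, loss).
#' @export
evolve_genome <- function(map, branch_length, rates,
                          inversion_mean_len = 8) {
  stopifnot(branch_length >= 0)
  cl <- map_to_chromlist(map)
  res <- evolve_chromlist(cl, branch_length, rates, inversion_mean_len)
  list(map = chromlist_to_map(res$cl, map$taxon_id), events = res$events)
}

evolve_chromlist <- function(cl, branch_length, rates, inversion_mean_len) {
  n_intra <- stats::rpois(1, rates$rate_intra * branch_length)
  n_inter <- stats::rpois(1, rates$rate_inter * branch_length)
  n_loss <- stats::rpois(1, rates$rate_loss * branch_length)
  ev <- c(inversion = 0L, transposition = 0L, inter = n_inter, loss = n_loss)
  for (i in seq_len(n_intra)) {
    step <- apply_intra(cl, inversion_mean_len)
    cl <- step$cl
    if (step$type %in% names(ev)) ev[step$type] <- ev[step$type] + 1L
  }
  for (i in seq_len(n_inter)) cl <- apply_inter(cl)
  for (i in seq_len(n_loss)) cl <- apply_loss(cl)
  list(cl = cl, events = ev)
}

#' Simulate genomes at the tips of a phylogeny
#'
#' Pre-order traversal from the ancestral genome, applying [evolve_genome()]
#' events along every branch. Branches whose descendant tips all belong to
#' one order use that order's `group_rates` override (when given); other
#' (backbone) branches use the base rates.
#'
#' @param config a [sim_config()].
#' @return list with `tips` (named list of [gene_map()]s), `truth`
#'   (per-branch event counts with parent/child node ids, and per-tip
#'   cumulative counts) and `config`.
#' @export
simulate_tips <- function(config) {
  tree <- config$tree
  if (is.null(tree$tip.label) || anyNA(tree$tip.label)) {
    stop("tree tips must be labelled")
  }
  miss <- setdiff(tree$tip.label, names(config$orders))
  if (length(miss)) stop("unclassified tips: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(config$group_rates %||% list()),
                   unique(unname(config$orders)))
  if (length(extra)) {
    stop("group_rates for unknown orders: ", paste(extra, collapse = ", "))
  }
  anc <- simulate_ancestral_genome(config)   # seeds the RNG from config$seed
  ntip <- length(tree$tip.label)

  ## orders represented under each node; a branch gets an order's rates only
  ## when every descendant tip belongs to that order
  node_ords <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) node_ords[[i]] <- unname(config$orders[tree$tip.label[i]])
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    node_ords[[par]] <- union(node_ords[[par]], node_ords[[chd]])
  }
  node_order <- vapply(node_ords, function(o) {
    if (length(o) == 1L) o else NA_character_
  }, "")

  pre <- ape::reorder.phylo(tree, "cladewise")
  root <- ntip + 1L
  genomes <- vector("list", ntip + tree$Nnode)
  genomes[[root]] <- map_to_chromlist(anc)
  ev_log <- vector("list", nrow(pre$edge))
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; chd <- pre$edge[e, 2]
    ord <- node_order[chd]
    gr <- if (!is.na(ord) && !is.null(config$group_rates[[ord]])) {
      config$group_rates[[ord]]
    } else list()
    rates <- list(rate_intra = gr$rate_intra %||% config$rate_intra,
                  rate_inter = gr$rate_inter %||% config$rate_inter,
                  rate_loss = gr$rate_loss %||% config$rate_loss)
    res <- evolve_chromlist(genomes[[par]], pre$edge.length[e], rates,
                            config$inversion_mean_len)
    genomes[[chd]] <- res$cl
    ev_log[[e]] <- data.frame(
      parent = par, child = chd, branch_length = pre$edge.length[e],
      intra = unname(res$events["inversion"] + res$events["transposition"]),
      inter = unname(res$events["inter"]),
      loss = unname(res$events["loss"]))
  }
  branch_events <- do.call(rbind, ev_log)

  tips <- lapply(seq_len(ntip), function(i) {
    chromlist_to_map(genomes[[i]], tree$tip.label[i])
  })
  names(tips) <- tree$tip.label

  ## per-tip cumulative events along the root path
  cum <- t(vapply(seq_len(ntip), function(i) {
    node <- i
    tot <- c(intra = 0, inter = 0, loss = 0)
    while (node != root) {
      row <- branch_events[branch_events$child == node, ]
      tot <- tot + c(row$intra, row$inter, row$loss)
      node <- row$parent
    }
    tot
  }, numeric(3)))
  rownames(cum) <- tree$tip.label

  list(tips = tips,
       truth = list(branch_events = branch_events, tip_cumulative = cum,
                    seed = config$seed),
       config = config)
}

#' Write simulated genomes as BUSCO full tables
#'
#' One table per tip, in the requested dialect; [read_busco_table()]
#' round-trips them exactly.
#'
#' @param tips named list of [gene_map()]s (from [simulate_tips()]).
#' @param dir output directory (created if needed).
#' @param dialect "v5" or "v2".
#' @return invisibly, the written file paths.
#' @export
write_busco_tables <- function(tips, dir, dialect = c("v5", "v2")) {
  dialect <- match.arg(dialect)
  if (length(tips) == 0L) stop("no tip genomes to write")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory '", dir, "'")
  }
  paths <- vapply(names(tips), function(tx) {
    p <- file.path(dir, paste0(tx, ".tsv"))
    write_busco_table(tips[[tx]], p, dialect = dialect)
    p
  }, "")
  invisible(paths)
}
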