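#' Read and validate a newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract needed
#' downstream: every edge has a branch length (zero-length branches are
#' allowed) and tip labels are unique.
#'
#' @param path newick file path, or a newick string via `text`.
#' @param text newick string (alternative to `path`).
#' @return an [ape::phylo] object.
#' @export
read_phylo <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

## root-to-tip path lengths
tip_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  h <- d[seq_along(tree$tip.label)]
  names(h) <- tree$tip.label
  h
}

#' Rescale a tree to unit height
#'
#' Divides every branch length by the maximum root-to-tip path length so the
#' total tree height becomes 1 (for a non-ultrametric tree, "height" is taken
#' as the deepest tip). Patristic distances scale by the same constant.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return the rescaled tree.
#' @export
rescale_to_unit_height <- function(tree) {
  h <- max(tip_heights(tree))
  if (h <= 0) stop("tree height is zero; cannot rescale")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Patristic distance matrix
#'
#' Pairwise sum of branch lengths along the tree path between tips, in tip
#' order.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param rescale rescale the tree to unit height first (default TRUE — the
#'   scale used as the regression predictor).
#' @return symmetric numeric matrix with zero diagonal, dimnames = tip
#'   labels.
#' @export
patristic_matrix <- function(tree, rescale = TRUE) {
  if (rescale) tree <- rescale_to_unit_height(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Write a patristic distance matrix
#'
#' Square labelled TSV, taxon header row and column.
#'
#' @param d matrix from [patristic_matrix()].
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  write_matrix_tsv(d, path)
}
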