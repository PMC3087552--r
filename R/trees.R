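#' Pairwise GTR ML distance matrix of an alignment
#'
#' @param aln Alignment tibble.
#' @param params [gtr_params()] object shared across pairs (typically
#'   estimated once from a concatenated alignment).
#' @return A symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(aln, params = gtr_params()) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(aln$taxon, aln$taxon))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- gtr_ml_distance(aln$sequence[i],
                                            aln$sequence[j], params)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()] for 4+ taxa; the exact
#' three-point formulas for 3 taxa). Negative branch-length estimates are
#' clamped to zero. The result is unrooted.
#'
#' @param D Symmetric distance matrix with taxa as dimnames.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (anyNA(D) || any(!is.finite(D))) abort("NaN/Inf in distance matrix")
  n <- nrow(D)
  if (n < 3L) abort("neighbor joining needs at least 3 taxa")
  if (n == 3L) {
    taxa <- rownames(D)
    b <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    tr <- ape::read.tree(text = paste0("(", taxa[1], ":0,", taxa[2],
                                       ":0,", taxa[3], ":0);"))
    tr$edge.length <- pmax(b[match(tr$edge[, 2], seq_len(3))], 0)
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' @param tree An [ape::phylo] tree.
#' @return A rooted tree; leaf-to-leaf path lengths are preserved.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) == 2L) {
    total <- sum(tree$edge.length)
    tr <- tree
    tr$edge.length <- rep(total / 2, nrow(tr$edge))
    return(tr)
  }
  phangorn::midpoint(tree)
}

#' Patristic distance between two leaves
#'
#' The sum of branch lengths along the unique path between `taxon_a` and
#' `taxon_b`.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param taxon_a,taxon_b Leaf labels.
#' @return Distance in substitutions per site.
#' @export
patristic_distance <- function(tree, taxon_a, taxon_b) {
  if (!all(c(taxon_a, taxon_b) %in% tree$tip.label)) {
    abort("both taxa must be leaves of the tree")
  }
  if (taxon_a == taxon_b) return(0)
  D <- ape::cophenetic.phylo(tree)
  D[taxon_a, taxon_b]
}

#' Total branch length of a tree
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  sum(tree$edge.length)
}
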