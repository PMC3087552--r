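# Branch-length comparison of a tree against a reference, via bipartitions.

# All bipartitions (including trivial single-leaf splits) of an unrooted
# tree, as a tibble of (key, length). The key is the sorted, comma-joined
# block NOT containing the lexicographically smallest taxon. A degree-2 root
# is collapsed first so the two root edges contribute one partition with the
# summed length.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  # tips below each edge (child side), by post-order accumulation
  tips_below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) tips_below[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    tips_below[[parent]] <- c(tips_below[[parent]], tips_below[[child]])
  }
  smallest <- min(tree$tip.label)
  all_tips <- tree$tip.label
  keys <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    block <- tips_below[[tree$edge[e, 2]]]
    if (smallest %in% block) block <- setdiff(all_tips, block)
    keys[e] <- paste(sort(block), collapse = ",")
  }
  len <- vapply(split(tree$edge.length, keys), sum, numeric(1))
  tibble(key = names(len), length = unname(len))
}

#' Compare a tree to a reference: scaling factor and branch-score
#'
#' Branches of the two trees are matched by bipartition over the union of
#' their partitions, a partition absent from one tree contributing length 0.
#' The scaling factor `K = sum(b_ref * b_comp) / sum(b_comp^2)` is the
#' least-squares minimizer of `sum((K * b_comp - b_ref)^2)`; `K > 1` means
#' the comparison tree is globally slower than the reference. The score is
#' the root-mean-square residual after scaling,
#' `sqrt(sum((K * b_comp - b_ref)^2) / n)` over the `n` union partitions: it
#' is 0 exactly when the comparison tree is a perfect rescaling of the
#' reference, and grows with lineage-specific accelerations/decelerations or
#' topological conflict on long branches, regardless of overall divergence.
#'
#' @param comp Comparison tree ([ape::phylo]).
#' @param ref Reference tree with the same leaf set.
#' @return A one-row tibble of class `tree_comparison`: `scaling_factor`,
#'   `k_score`, `n_partitions_union`, `n_shared`.
#' @export
compare_trees <- function(comp, ref) {
  if (!setequal(comp$tip.label, ref$tip.label)) {
    abort("trees must share the same leaf set")
  }
  bc <- tree_bipartitions(comp)
  br <- tree_bipartitions(ref)
  keys <- union(bc$key, br$key)
  b_comp <- bc$length[match(keys, bc$key)]
  b_comp[is.na(b_comp)] <- 0
  b_ref <- br$length[match(keys, br$key)]
  b_ref[is.na(b_ref)] <- 0
  if (all(b_comp == 0)) {
    abort("scaling factor undefined: comparison tree has all-zero branches")
  }
  K <- sum(b_ref * b_comp) / sum(b_comp^2)
  resid <- K * b_comp - b_ref
  res <- tibble(
    scaling_factor = K,
    k_score = sqrt(sum(resid^2) / length(keys)),
    n_partitions_union = length(keys),
    n_shared = length(intersect(bc$key, br$key))
  )
  class(res) <- c("tree_comparison", class(res))
  res
}

#' Clock-likeness (neutral-evolution) filter
#'
#' Keeps intron sets whose tree-vs-reference branch score is at most
#' `k_max` (inclusive).
#'
#' @param tree_stats Tibble with columns `set_id` and `k_score`.
#' @param k_max Maximum allowed score.
#' @return A list with `kept` (filtered `tree_stats`) and `outcomes`.
#' @export
filter_neutral_evolution <- function(tree_stats, k_max = 0.1) {
  passed <- tree_stats$k_score <= k_max
  outcomes <- filter_outcome(tree_stats$set_id, "k_score", passed,
                             sprintf("k_score=%.4f", tree_stats$k_score))
  list(kept = tree_stats[passed, , drop = FALSE], outcomes = outcomes)
}

#' Divergence filter
#'
#' Keeps intron sets whose scaling factor is strictly below `k_scale_max`
#' (slow introns rescale with a large factor) and whose total branch length
#' of the three-reference-taxon tree is strictly above `primate_tbl_min`
#' substitutions per position.
#'
#' @param tree_stats Tibble with columns `set_id`, `scaling_factor` and
#'   `primate_tbl`.
#' @param k_scale_max Strict upper bound on the scaling factor.
#' @param primate_tbl_min Strict lower bound on the three-taxon total branch
#'   length.
#' @return A list with `kept` and `outcomes`.
#' @export
filter_divergence <- function(tree_stats, k_scale_max = 1.15,
                              primate_tbl_min = 0.075) {
  passed <- tree_stats$scaling_factor < k_scale_max &
    tree_stats$primate_tbl > primate_tbl_min
  outcomes <- filter_outcome(
    tree_stats$set_id, "divergence", passed,
    sprintf("K=%.4f tbl=%.4f", tree_stats$scaling_factor,
            tree_stats$primate_tbl))
  list(kept = tree_stats[passed, , drop = FALSE], outcomes = outcomes)
}

#' Calibrate the branch-score threshold for a planted acceleration
#'
#' The branch score used here is a root-mean-square residual, so its scale
#' depends on the reference tree. For synthetic-clade analyses the
#' operational threshold is derived from the study design itself: the score
#' that a noise-free intron tree with one pendant branch multiplied by
#' `accel_factor` would attain against the reference, halved. Clock-like
#' trees score near 0 and fully accelerated trees score near the computed
#' value, so the midpoint separates the two populations symmetrically.
#'
#' @param ref Reference tree.
#' @param accel_taxon Leaf whose pendant branch carries the acceleration.
#' @param accel_factor Branch-length multiplier of the acceleration.
#' @return The calibrated threshold (half the noise-free accelerated score).
#' @export
calibrate_k_threshold <- function(ref, accel_taxon, accel_factor = 5) {
  comp <- ref
  tip <- match(accel_taxon, comp$tip.label)
  if (is.na(tip)) abort("accel_taxon is not a leaf of the reference tree")
  edge <- which(comp$edge[, 2] == tip)
  comp$edge.length[edge] <- comp$edge.length[edge] * accel_factor
  compare_trees(comp, ref)$k_score / 2
}

#' @export
tidy.tree_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}
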