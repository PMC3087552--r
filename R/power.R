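#' Per-intron tree-comparison statistics on a simulated clade
#'
#' Convenience used to evaluate the power of the clock-likeness and
#' divergence rules on simulated data: stacks each orthologous intron's
#' sequences (the simulator's substitution-only classes stay equal-length),
#' concatenates all usable sets into a reference alignment, estimates GTR
#' parameters and the reference tree from it, and compares each per-intron
#' tree against that reference.
#'
#' @param sim A [simulate_clade()] result.
#' @return A tibble with `set_id`, `class`, `scaling_factor`, `k_score`,
#'   `primate_tbl`; the estimated reference tree is attached as attribute
#'   `ref_tree`.
#' @export
intron_tree_stats <- function(sim) {
  sp <- sim$config$species
  ref <- sp[1]
  truth <- sim$truth_introns
  sets <- truth |>
    mutate(set_id = paste0(ref, "_g", sprintf("%04d", .data$gene_index),
                           ".intron", .data$intron_index))
  ids <- unique(sets$set_id)
  alns <- list()
  for (id in ids) {
    rows <- sets[sets$set_id == id, ]
    if (length(unique(nchar(rows$sequence))) != 1L) next
    alns[[id]] <- align_set(rows, sp)
  }
  concat <- concat_alignments(alns)
  params <- estimate_gtr_params(concat)
  ref_tree <- nj_tree(distance_matrix(concat, params))
  prim <- sp[1:3]
  out <- map(names(alns), function(id) {
    tr <- nj_tree(distance_matrix(alns[[id]], params))
    cmpr <- compare_trees(tr, ref_tree)
    rows <- sets[sets$set_id == id, ]
    paln <- align_set(rows[rows$species %in% prim, ], prim)
    ptr <- nj_tree(distance_matrix(paln, params))
    tibble(set_id = id, class = rows$class[1],
           scaling_factor = cmpr$scaling_factor, k_score = cmpr$k_score,
           primate_tbl = total_branch_length(ptr))
  })
  res <- list_rbind(out)
  attr(res, "ref_tree") <- ref_tree
  res
}
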