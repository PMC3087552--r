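#' Configuration for the end-to-end marker pipeline
#'
#' Inputs may be given either as file paths (`genome_paths`,
#' `annotation_paths`, `orthology_paths`, `hit_paths`, `snp_path`,
#' `repeat_path`) or as the in-memory result of [simulate_clade()] via
#' `sim`; `sim` takes precedence.
#'
#' @param species Ordered species vector; the first is the reference.
#' @param primate_species The three-taxon subset used by the divergence
#'   filter (defaults to the first three species).
#' @param sim Optional [simulate_clade()] result used as input.
#' @param genome_paths,annotation_paths Named (by species) paths to FASTA /
#'   GFF3 files.
#' @param orthology_paths Paths to pairwise orthology TSVs.
#' @param hit_paths Named (by species) paths to BLAST outfmt-6 hit tables;
#'   `NULL` skips the single-copy stage.
#' @param snp_path Optional reference-species SNP TSV.
#' @param repeat_path Optional RepeatMasker `.out` file for the reference
#'   species.
#' @param thresholds A [filter_thresholds()]; pair limits default to
#'   [pair_limits_default()] on `species`.
#' @param max_gap_fraction,min_block_len Alignment column-filter settings
#'   (see [filter_alignment_columns()]).
#' @param k_max Branch-score limit of the clock-likeness filter
#'   (inclusive). The published operational value for the original score
#'   implementation is 0.1; for synthetic clades a value calibrated with
#'   [calibrate_k_threshold()] is appropriate.
#' @param k_scale_max Strict scaling-factor limit of the divergence filter.
#' @param primate_tbl_min Strict minimum three-taxon total branch length
#'   (substitutions/position).
#' @param manual_exclusions Set ids removed by the final visual-inspection
#'   stage.
#' @param extraction_cap Intron extraction cap (nt).
#' @param out_dir Optional output directory: stage counts, outcomes, marker
#'   report, reference tree and final alignments are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(species, primate_species = species[1:3],
                            sim = NULL,
                            genome_paths = NULL, annotation_paths = NULL,
                            orthology_paths = NULL, hit_paths = NULL,
                            snp_path = NULL, repeat_path = NULL,
                            thresholds = NULL,
                            max_gap_fraction = 0.5, min_block_len = 5L,
                            k_max = 0.1, k_scale_max = 1.15,
                            primate_tbl_min = 0.075,
                            manual_exclusions = character(),
                            extraction_cap = 50000L,
                            out_dir = NULL) {
  if (!all(primate_species %in% species) || length(primate_species) != 3L) {
    abort("primate_species must be three of `species`")
  }
  if (is.null(thresholds)) {
    thresholds <- filter_thresholds(
      pair_limits = pair_limits_default(species),
      extraction_cap = extraction_cap)
  }
  structure(list(
    species = species, ref_species = species[1],
    primate_species = primate_species, sim = sim,
    genome_paths = genome_paths, annotation_paths = annotation_paths,
    orthology_paths = orthology_paths, hit_paths = hit_paths,
    snp_path = snp_path, repeat_path = repeat_path,
    thresholds = thresholds, max_gap_fraction = max_gap_fraction,
    min_block_len = min_block_len, k_max = k_max,
    k_scale_max = k_scale_max, primate_tbl_min = primate_tbl_min,
    manual_exclusions = manual_exclusions,
    extraction_cap = extraction_cap, out_dir = out_dir
  ), class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    return(list(genomes = sim$genomes,
                gene_models = sim$gene_models,
                orthology = sim$orthology,
                hits = sim$hits, snps = sim$snps, repeats = NULL))
  }
  sp <- config$species
  genomes <- setNames(map(sp, function(s) {
    read_genome_fasta(config$genome_paths[[s]])
  }), sp)
  gene_models <- list_rbind(map(sp, function(s) {
    read_gene_models(config$annotation_paths[[s]], s)
  }))
  orthology <- map(config$orthology_paths, read_orthology_table)
  hits <- NULL
  if (!is.null(config$hit_paths)) {
    hits <- list_rbind(map(sp, function(s) {
      read_blast_hits(config$hit_paths[[s]]) |> mutate(species = s)
    }))
  }
  snps <- if (!is.null(config$snp_path)) read_snp_table(config$snp_path)
  repeats <- if (!is.null(config$repeat_path)) read_repeatmasker(config$repeat_path)
  list(genomes = genomes, gene_models = gene_models, orthology = orthology,
       hits = hits, snps = snps, repeats = repeats)
}

# per-set alignment of the given taxa, ordered as in `species`
align_set <- function(rows, species) {
  rows <- rows[match(species, rows$species), ]
  align_sequences(rows$species, rows$sequence)
}

#' Run the full marker-mining pipeline
#'
#' Stages, in order: intron extraction, orthologous-set construction, the
#' deterministic cascade (reference length, length conservation, flank size,
#' single-copy), alignment and column filtering, reference-tree construction
#' from the concatenated single-copy survivors, the clock-likeness
#' (branch-score) filter, the divergence filter (scaling factor +
#' three-taxon total branch length), a manual-exclusion step mirroring the
#' final visual inspection, and marker annotation.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `marker_pipeline`: a list with `reports`
#'   (final marker tibble, ordered by three-taxon total branch length
#'   descending), `stage_counts`, `outcomes`, `ref_tree`, `params`
#'   (estimated GTR parameters), `tree_stats` (per-set comparison
#'   statistics for all sets reaching the tree stage), `final_sets`
#'   (long intron tibble of the final markers) and `config`.
#' @export
run_pipeline <- function(config) {
  inputs <- load_pipeline_inputs(config)
  sp <- config$species
  ref <- config$ref_species

  introns <- list_rbind(map(sp, function(s) {
    models <- inputs$gene_models[inputs$gene_models$species == s, ]
    extract_introns(inputs$genomes[[s]], models,
                    max_len = config$extraction_cap)
  }))
  gene_sets <- cross_orthology_tables(inputs$orthology, sp, anchor = ref)
  sets <- match_introns(gene_sets, introns, anchor = ref)

  casc <- run_cascade(sets, config$thresholds, ref, hits = inputs$hits)
  kept <- casc$kept
  stage_counts <- casc$stage_counts
  outcomes <- list(casc$outcomes)

  # --- alignment stage ------------------------------------------------------
  ids <- unique(kept$set_id)
  usable <- character(); alns <- list(); aln_len <- integer()
  aln_outcomes <- list()
  for (id in ids) {
    rows <- kept[kept$set_id == id, ]
    if (any(rows$high_n)) {
      aln_outcomes[[id]] <- filter_outcome(id, "alignment", FALSE, "high_n")
      next
    }
    a <- filter_alignment_columns(align_set(rows, sp),
                                  config$max_gap_fraction,
                                  config$min_block_len)
    if (alignment_length(a) == 0L) {
      aln_outcomes[[id]] <- filter_outcome(id, "alignment", FALSE, "emptied")
      next
    }
    usable <- c(usable, id)
    alns[[id]] <- a
    aln_len[[id]] <- alignment_length(a)
    aln_outcomes[[id]] <- filter_outcome(id, "alignment", TRUE, "")
  }
  outcomes <- c(outcomes, list(list_rbind(unname(aln_outcomes))))
  stage_counts <- bind_rows(stage_counts,
                            tibble(stage = "alignment",
                                   survivors = length(usable)))
  if (length(usable) == 0L) {
    warn("no usable intron sets survive to the tree stage")
    return(empty_pipeline_result(config, stage_counts,
                                 list_rbind(outcomes)))
  }

  # --- reference tree -------------------------------------------------------
  concat <- concat_alignments(alns[usable])
  params <- estimate_gtr_params(concat)
  ref_tree <- nj_tree(distance_matrix(concat, params))

  # --- per-set trees, clock-likeness and divergence filters -----------------
  prim <- config$primate_species
  stats_rows <- map(usable, function(id) {
    rows <- kept[kept$set_id == id, ]
    tr <- tryCatch(nj_tree(distance_matrix(alns[[id]], params)),
                   error = function(e) NULL)
    if (is.null(tr)) {
      return(tibble(set_id = id, scaling_factor = NA_real_,
                    k_score = NA_real_, n_partitions_union = NA_integer_,
                    n_shared = NA_integer_, primate_tbl = NA_real_,
                    hc_distance = NA_real_))
    }
    cmpr <- compare_trees(tr, ref_tree)
    paln <- align_set(rows[rows$species %in% prim, ], prim)
    ptr <- tryCatch(nj_tree(distance_matrix(paln, params)),
                    error = function(e) NULL)
    tibble(set_id = id,
           scaling_factor = cmpr$scaling_factor, k_score = cmpr$k_score,
           n_partitions_union = cmpr$n_partitions_union,
           n_shared = cmpr$n_shared,
           primate_tbl = if (is.null(ptr)) NA_real_ else
             total_branch_length(ptr),
           hc_distance = if (is.null(ptr)) NA_real_ else
             patristic_distance(ptr, prim[1], prim[2]))
  })
  tree_stats <- list_rbind(stats_rows)
  defined <- tree_stats |> filter(!is.na(.data$k_score),
                                  !is.na(.data$primate_tbl))

  kf <- filter_neutral_evolution(defined, k_max = config$k_max)
  outcomes <- c(outcomes, list(kf$outcomes))
  stage_counts <- bind_rows(stage_counts,
                            tibble(stage = "k_score",
                                   survivors = nrow(kf$kept)))

  dvf <- filter_divergence(kf$kept, k_scale_max = config$k_scale_max,
                           primate_tbl_min = config$primate_tbl_min)
  outcomes <- c(outcomes, list(dvf$outcomes))
  stage_counts <- bind_rows(stage_counts,
                            tibble(stage = "divergence",
                                   survivors = nrow(dvf$kept)))

  final_stats <- dvf$kept
  visual_pass <- !final_stats$set_id %in% config$manual_exclusions
  outcomes <- c(outcomes, list(
    filter_outcome(final_stats$set_id, "visual", visual_pass, "")))
  final_stats <- final_stats[visual_pass, , drop = FALSE]
  stage_counts <- bind_rows(stage_counts,
                            tibble(stage = "visual",
                                   survivors = nrow(final_stats)))

  # --- annotation & report --------------------------------------------------
  final_sets <- semi_join(kept, final_stats, by = "set_id")
  ref_rows <- final_sets |> filter(.data$species == ref)
  if (!is.null(inputs$snps)) {
    ref_rows <- snp_density(ref_rows, inputs$snps)
  } else {
    ref_rows <- ref_rows |> mutate(snp_count = NA_integer_,
                                   snp_density = NA_real_)
  }
  msat_flags <- final_sets |>
    group_by(.data$set_id) |>
    summarise(
      microsatellite = paste(sort(unique(unlist(map2(
        .data$sequence, .data$species, function(sq, s) {
          m <- find_microsatellites(sq)
          if (nrow(m) == 0L) character() else
            paste0(s, ":", m$motif, "x", m$copies)
        })))), collapse = ";"),
      .groups = "drop")
  repeat_frac <- map_dbl(seq_len(nrow(ref_rows)), function(i) {
    if (is.null(inputs$repeats)) return(NA_real_)
    repeat_content(ref_rows[i, ], inputs$repeats)$fraction_masked
  })

  # gene description from the reference-species annotation
  desc <- inputs$gene_models |>
    filter(.data$species == ref) |>
    distinct(.data$gene_id, .data$description)

  reports <- ref_rows |>
    left_join(final_stats, by = "set_id") |>
    left_join(msat_flags, by = "set_id") |>
    left_join(desc, by = "gene_id") |>
    mutate(alignment_length = unname(aln_len[.data$set_id]),
           repeat_fraction = repeat_frac) |>
    transmute(
      set_id = .data$set_id, description = .data$description,
      gene_id = .data$gene_id, intron_index = .data$intron_index,
      chromosome = .data$chromosome, intron_start = .data$start,
      ref_intron_length = .data$length,
      alignment_length = .data$alignment_length,
      upstream_exon_len = .data$upstream_exon_len,
      downstream_exon_len = .data$downstream_exon_len,
      snp_count = .data$snp_count, snp_density = .data$snp_density,
      k_score = .data$k_score, scaling_factor = .data$scaling_factor,
      hc_distance = .data$hc_distance, primate_tbl = .data$primate_tbl,
      microsatellite = .data$microsatellite,
      repeat_fraction = .data$repeat_fraction) |>
    arrange(desc(.data$primate_tbl), .data$gene_id, .data$intron_index)

  stage_counts <- bind_rows(stage_counts,
                            tibble(stage = "final",
                                   survivors = nrow(reports)))

  res <- structure(list(
    reports = reports, stage_counts = stage_counts,
    outcomes = list_rbind(outcomes), ref_tree = ref_tree,
    params = params, tree_stats = tree_stats,
    final_sets = final_sets, alignments = alns[reports$set_id],
    config = config
  ), class = "marker_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

empty_pipeline_result <- function(config, stage_counts, outcomes) {
  structure(list(
    reports = tibble(), stage_counts = stage_counts, outcomes = outcomes,
    ref_tree = NULL, params = NULL, tree_stats = tibble(),
    final_sets = tibble(), alignments = list(), config = config
  ), class = "marker_pipeline")
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(res$stage_counts, file.path(out_dir, "stage_counts.tsv"))
  write_tsv_plain(res$outcomes, file.path(out_dir, "outcomes.tsv"))
  write_marker_report(res$reports, file.path(out_dir, "marker_report.tsv"))
  if (!is.null(res$ref_tree)) {
    write_tree(midpoint_root(res$ref_tree),
               file.path(out_dir, "reference_tree.nwk"))
  }
  if (length(res$alignments) > 0L) {
    con <- file(file.path(out_dir, "marker_alignments.fasta"), "w")
    for (id in names(res$alignments)) {
      a <- res$alignments[[id]]
      writeLines(paste0(">", id, "|", a$taxon, "\n", a$sequence), con)
    }
    close(con)
  }
  invisible(out_dir)
}

#' Write the per-marker report sheet
#'
#' @param reports Marker report tibble from [run_pipeline()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(reports, path) {
  write_tsv_plain(reports, path)
}

#' Histogram of a divergence measure over a marker set
#'
#' @param df Tibble holding one row per marker.
#' @param value Name of the numeric column to bin (e.g. the
#'   reference-sister patristic distance).
#' @param bin_width Bin width in substitutions/position.
#' @return A tibble of `bin_start`, `bin_end`, `count`, with attributes
#'   `mean` and `n`.
#' @export
divergence_histogram <- function(df, value = "hc_distance",
                                 bin_width = 0.002) {
  x <- df[[value]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    out <- tibble(bin_start = numeric(), bin_end = numeric(),
                  count = integer())
    attr(out, "mean") <- NA_real_; attr(out, "n") <- 0L
    return(out)
  }
  bin <- floor(x / bin_width)
  tab <- table(bin)
  out <- tibble(bin_start = as.numeric(names(tab)) * bin_width,
                bin_end = (as.numeric(names(tab)) + 1) * bin_width,
                count = as.integer(tab))
  attr(out, "mean") <- mean(x)
  attr(out, "n") <- length(x)
  out
}

#' Pairwise divergence table for final markers
#'
#' For every marker and every requested species pair, aligns the two intron
#' sequences and reports the GTR ML distance ([species_pair_divergence()]).
#'
#' @param final_sets Long intron tibble (e.g. `$final_sets` of a pipeline
#'   result).
#' @param pairs List of 2-vectors of species names.
#' @param params [gtr_params()] used for the distances.
#' @return A tibble with `set_id` and one column per pair
#'   (`"<a>-<b>"`); `NA` marks saturated or unalignable pairs.
#' @export
pair_divergence_table <- function(final_sets, pairs,
                                  params = gtr_params()) {
  ids <- unique(final_sets$set_id)
  out <- tibble(set_id = ids)
  for (p in pairs) {
    col <- map_dbl(ids, function(id) {
      rows <- final_sets[final_sets$set_id == id, ]
      a <- rows$sequence[rows$species == p[1]]
      b <- rows$sequence[rows$species == p[2]]
      if (length(a) != 1L || length(b) != 1L) return(NA_real_)
      suppressWarnings(species_pair_divergence(a, b, params))
    })
    out[[paste0(p[1], "-", p[2])]] <- col
  }
  out
}

#' @export
tidy.marker_pipeline <- function(x, ...) {
  x$reports
}

#' @export
glance.marker_pipeline <- function(x, ...) {
  sc <- setNames(x$stage_counts$survivors, x$stage_counts$stage)
  tibble(
    n_input = unname(sc["input"]),
    n_single_copy = unname(sc["single_copy"]),
    n_clocklike = unname(sc["k_score"]),
    n_final = unname(sc["final"]),
    k_max = x$config$k_max,
    k_scale_max = x$config$k_scale_max,
    primate_tbl_min = x$config$primate_tbl_min,
    mean_hc_distance = if (nrow(x$reports) > 0)
      mean(x$reports$hc_distance, na.rm = TRUE) else NA_real_,
    mean_primate_tbl = if (nrow(x$reports) > 0)
      mean(x$reports$primate_tbl, na.rm = TRUE) else NA_real_
  )
}

#' @export
print.marker_pipeline <- function(x, ...) {
  cat("<marker_pipeline>\n")
  print(x$stage_counts, n = Inf)
  invisible(x)
}
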