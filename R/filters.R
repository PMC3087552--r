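#' Filter thresholds for the deterministic marker cascade
#'
#' Defaults follow the published mammalian study conditions: reference-intron
#' length 200-1600 nt, extraction cap 50000 nt, flanking exons of at least
#' 40 nt, relative length-difference limits per species pair, and a 1e-4
#' e-value cutoff for the single-copy test.
#'
#' @param ref_min_len,ref_max_len Inclusive reference-species intron length
#'   bounds (nt).
#' @param extraction_cap Maximum intron length retained at extraction (nt).
#' @param flank_min Minimum flanking-exon length (nt); exons strictly
#'   shorter are rejected.
#' @param pair_limits Tibble with columns `species_a`, `species_b`, `limit`:
#'   maximum allowed relative length difference for that pair. See
#'   [pair_limits_default()].
#' @param evalue_max Single-copy test e-value cutoff.
#' @param region_gap Hits on the same subject closer than this (nt) are
#'   merged into one subject region for the single-copy test.
#' @param denominator Denominator of the relative length difference:
#'   `"first"` (the first-named species of the pair, the reference
#'   convention) or `"min"` (the shorter intron).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(ref_min_len = 200L, ref_max_len = 1600L,
                              extraction_cap = 50000L, flank_min = 40L,
                              pair_limits = NULL, evalue_max = 1e-4,
                              region_gap = 1000L,
                              denominator = c("first", "min")) {
  if (ref_min_len <= 0 || ref_min_len > ref_max_len) {
    abort("need 0 < ref_min_len <= ref_max_len")
  }
  if (!is.null(pair_limits) && any(pair_limits$limit < 0)) {
    abort("pair limits must be >= 0")
  }
  structure(list(
    ref_min_len = ref_min_len, ref_max_len = ref_max_len,
    extraction_cap = extraction_cap, flank_min = flank_min,
    pair_limits = pair_limits, evalue_max = evalue_max,
    region_gap = region_gap, denominator = match.arg(denominator)
  ), class = "filter_thresholds")
}

#' Default per-pair length-conservation limits
#'
#' Given the five study species ordered as (reference, sister of reference,
#' third ingroup member, outgroup pair), reproduces the published limits:
#' 10% for the reference-sister pair, 20% for reference-third, 100% for the
#' two reference-outgroup pairs and 50% within the outgroup pair.
#'
#' @param species Character vector of exactly five species in that order.
#' @return A tibble with columns `species_a`, `species_b`, `limit`.
#' @export
pair_limits_default <- function(species) {
  if (length(species) != 5L) {
    abort("pair_limits_default() expects exactly five species")
  }
  tibble(
    species_a = c(species[1], species[1], species[1], species[1], species[4]),
    species_b = c(species[2], species[3], species[4], species[5], species[5]),
    limit = c(0.10, 0.20, 1.00, 1.00, 0.50)
  )
}

filter_outcome <- function(set_ids, stage, passed, detail = "") {
  tibble(set_id = set_ids, stage = stage, passed = passed, detail = detail)
}

#' Reference-species intron length filter
#'
#' Keeps a set iff the reference-species intron length lies within
#' `[ref_min_len, ref_max_len]`, bounds inclusive.
#'
#' @param sets Long intron-set tibble from [match_introns()].
#' @param thresholds A [filter_thresholds()] object.
#' @param ref_species Reference species name.
#' @return A list with elements `kept` (filtered `sets`) and `outcomes`
#'   (tibble of `set_id`, `stage`, `passed`, `detail`).
#' @export
filter_reference_length <- function(sets, thresholds, ref_species) {
  ref <- sets |> filter(.data$species == ref_species)
  if (nrow(ref) < n_distinct(sets$set_id)) {
    abort("every set must contain the reference species")
  }
  passed <- ref$length >= thresholds$ref_min_len &
    ref$length <= thresholds$ref_max_len
  outcomes <- filter_outcome(
    ref$set_id, "ref_length", passed,
    sprintf("ref_len=%d", ref$length))
  list(kept = semi_join(sets, ref[passed, "set_id"], by = "set_id"),
       outcomes = outcomes)
}

#' Cross-species length-conservation filter
#'
#' For every configured species pair (A, B), requires
#' `|len_A - len_B| / len_A <= limit` where A is the first-named species
#' (or the shorter intron when `denominator = "min"`). Limits are inclusive.
#'
#' @inheritParams filter_reference_length
#' @return As [filter_reference_length()].
#' @export
filter_length_conservation <- function(sets, thresholds) {
  pl <- thresholds$pair_limits
  if (is.null(pl)) abort("thresholds$pair_limits is not set")
  lens <- sets |> select("set_id", "species", "length")
  verdict <- rep(TRUE, n_distinct(lens$set_id))
  ids <- sort(unique(lens$set_id))
  len_wide <- lens |>
    pivot_wider(names_from = "species", values_from = "length") |>
    arrange(.data$set_id)
  details <- character(nrow(len_wide))
  for (i in seq_len(nrow(pl))) {
    a <- len_wide[[pl$species_a[i]]]
    b <- len_wide[[pl$species_b[i]]]
    if (is.null(a) || is.null(b)) {
      abort(paste0("pair limit references species missing from the sets: ",
                   pl$species_a[i], "-", pl$species_b[i]))
    }
    denom <- if (thresholds$denominator == "first") a else pmin(a, b)
    rel <- abs(a - b) / denom
    bad <- rel > pl$limit[i]
    details[bad & verdict] <- sprintf(
      "%s-%s rel_diff=%.4f > %.2f", pl$species_a[i], pl$species_b[i],
      rel[bad & verdict], pl$limit[i])
    verdict <- verdict & !bad
  }
  outcomes <- filter_outcome(len_wide$set_id, "length_conservation",
                             verdict, details)
  list(kept = semi_join(sets, len_wide[verdict, "set_id"], by = "set_id"),
       outcomes = outcomes)
}

#' Minimum flanking-exon size filter
#'
#' Rejects a set if any flanking exon in any species is strictly shorter
#' than `flank_min` (exons of exactly `flank_min` nt are kept).
#'
#' @inheritParams filter_reference_length
#' @return As [filter_reference_length()].
#' @export
filter_flanks <- function(sets, thresholds) {
  per_set <- sets |>
    group_by(.data$set_id) |>
    summarise(min_flank = min(.data$upstream_exon_len,
                              .data$downstream_exon_len),
              .groups = "drop")
  passed <- per_set$min_flank >= thresholds$flank_min
  outcomes <- filter_outcome(per_set$set_id, "flank", passed,
                             sprintf("min_flank=%d", per_set$min_flank))
  list(kept = semi_join(sets, per_set[passed, "set_id"], by = "set_id"),
       outcomes = outcomes)
}

# Group significant HSP rows of one query into subject regions: rows share a
# region when they hit the same subject sequence, in the same orientation,
# and overlap or lie within `region_gap` of each other.
count_subject_regions <- function(rows, region_gap) {
  lo <- pmin(rows$subject_start, rows$subject_end)
  hi <- pmax(rows$subject_start, rows$subject_end)
  fwd <- rows$subject_end >= rows$subject_start
  o <- order(rows$subject_id, fwd, lo)
  sid <- rows$subject_id[o]; fw <- fwd[o]; lo <- lo[o]; hi <- hi[o]
  new_region <- c(TRUE, sid[-1] != sid[-length(sid)] |
                    fw[-1] != fw[-length(fw)] |
                    lo[-1] > cummax_shift(hi) + region_gap)
  region <- cumsum(new_region)
  list(n_regions = max(region), rows_per_region = tabulate(region))
}

cummax_shift <- function(hi) head(cummax(hi), -1)

#' Single-copy (anti-paralog) filter
#'
#' A set is kept iff, for both flanking exons in every species, the
#' significant hits (e-value at most `evalue_max`) of the exon against its
#' own genome fall in exactly one subject region, and that region is covered
#' by exactly one HSP row (a single sub-alignment). A query with no hits at
#' all is a data error, since the self-hit must exist.
#'
#' @inheritParams filter_reference_length
#' @param hits Hit tibble with a `species` column plus the columns of
#'   [read_blast_hits()]; `query_id` must be `"<set_id>|up"` or
#'   `"<set_id>|down"`.
#' @return As [filter_reference_length()].
#' @export
filter_single_copy <- function(sets, hits, thresholds) {
  ids <- unique(sets$set_id)
  species <- unique(sets$species)
  expected <- tidyr::expand_grid(set_id = ids, species = species,
                                 side = c("up", "down"))
  h <- hits |>
    mutate(set_id = sub("\\|(up|down)$", "", .data$query_id),
           side = sub("^.*\\|", "", .data$query_id)) |>
    semi_join(expected, by = c("set_id", "species", "side"))
  have <- h |> distinct(.data$set_id, .data$species, .data$side)
  missing <- anti_join(expected, have, by = c("set_id", "species", "side"))
  if (nrow(missing) > 0L) {
    abort(paste0("no hits at all for exon query ", missing$set_id[1], "|",
                 missing$side[1], " in ", missing$species[1],
                 " (self-hit must exist)"))
  }
  sig <- h |> filter(.data$evalue <= thresholds$evalue_max)
  per_query <- sig |>
    group_by(.data$set_id, .data$species, .data$side) |>
    group_modify(function(rows, key) {
      r <- count_subject_regions(rows, thresholds$region_gap)
      tibble(n_regions = r$n_regions,
             single_hsp = all(r$rows_per_region == 1L))
    }) |>
    ungroup()
  # queries whose every hit is above the cutoff have no significant region:
  # treat as failed (the self-hit itself did not reach significance)
  per_query <- expected |>
    left_join(per_query, by = c("set_id", "species", "side")) |>
    mutate(n_regions = ifelse(is.na(.data$n_regions), 0L, .data$n_regions),
           single_hsp = ifelse(is.na(.data$single_hsp), FALSE,
                               .data$single_hsp))
  per_set <- per_query |>
    group_by(.data$set_id) |>
    summarise(passed = all(.data$n_regions == 1L & .data$single_hsp),
              max_regions = max(.data$n_regions), .groups = "drop")
  outcomes <- filter_outcome(per_set$set_id, "single_copy", per_set$passed,
                             sprintf("max_regions=%d", per_set$max_regions))
  list(kept = semi_join(sets, per_set[per_set$passed, "set_id"],
                        by = "set_id"),
       outcomes = outcomes)
}

#' Run the deterministic pre-phylogenetic filter cascade
#'
#' Applies, in order: reference length, cross-species length conservation,
#' minimum flank size and (when hit tables are supplied) the single-copy
#' test. Survivor counts per stage are recorded.
#'
#' @inheritParams filter_reference_length
#' @param hits Optional hit tibble for [filter_single_copy()]; `NULL` skips
#'   that stage.
#' @return A list with `kept` (surviving sets), `stage_counts` (tibble of
#'   `stage`, `survivors`) and `outcomes` (row-bound per-stage outcomes).
#' @export
run_cascade <- function(sets, thresholds, ref_species, hits = NULL) {
  counts <- tibble(stage = "input", survivors = n_distinct(sets$set_id))
  outcomes <- list()
  step <- function(res, stage) {
    counts <<- bind_rows(counts,
                         tibble(stage = stage,
                                survivors = n_distinct(res$kept$set_id)))
    outcomes[[stage]] <<- res$outcomes
    res$kept
  }
  kept <- sets
  if (nrow(kept) > 0L) {
    kept <- step(filter_reference_length(kept, thresholds, ref_species),
                 "ref_length")
    if (nrow(kept) > 0L)
      kept <- step(filter_length_conservation(kept, thresholds),
                   "length_conservation")
    if (nrow(kept) > 0L)
      kept <- step(filter_flanks(kept, thresholds), "flank")
    if (nrow(kept) > 0L && !is.null(hits))
      kept <- step(filter_single_copy(kept, hits, thresholds), "single_copy")
  } else {
    counts <- bind_rows(counts, tibble(
      stage = c("ref_length", "length_conservation", "flank", "single_copy"),
      survivors = 0L))
  }
  list(kept = kept, stage_counts = counts,
       outcomes = list_rbind(unname(outcomes)))
}
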