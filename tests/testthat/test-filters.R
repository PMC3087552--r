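# a minimal five-species intron-set table with controllable lengths/flanks
make_sets <- function(lens, flanks = NULL, species = c("h", "c", "m", "w", "d")) {
  # lens: named list set_id -> numeric vector of 5 lengths (species order)
  rows <- list()
  for (id in names(lens)) {
    fl <- if (is.null(flanks[[id]])) rep(100L, 5) else flanks[[id]]
    rows[[id]] <- tibble::tibble(
      set_id = id, intron_index = 1L, species = species,
      gene_id = paste0(species, "_", id), chromosome = "c", strand = "+",
      start = 0L, end = as.integer(lens[[id]]),
      length = as.integer(lens[[id]]),
      sequence = strrep("A", 10), upstream_exon_len = as.integer(fl),
      downstream_exon_len = 100L,
      upstream_exon_seq = "A", downstream_exon_seq = "A", high_n = FALSE)
  }
  dplyr::bind_rows(rows)
}

thr <- function() filter_thresholds(
  pair_limits = pair_limits_default(c("h", "c", "m", "w", "d")))

test_that("reference length bounds are inclusive", {
  sets <- make_sets(list(a = rep(150, 5), b = rep(200, 5), c = rep(1600, 5),
                         d = rep(1601, 5)))
  res <- filter_reference_length(sets, thr(), "h")
  kept <- unique(res$kept$set_id)
  expect_setequal(kept, c("b", "c"))
  expect_equal(res$outcomes$passed[res$outcomes$set_id == "a"], FALSE)
})

test_that("length conservation uses the first-named species as denominator", {
  sets <- make_sets(list(
    a = c(1000, 1101, 1000, 1000, 1000),   # 10.1% vs sister -> fail
    b = c(1000, 1100, 1000, 1000, 1000),   # exactly 10% -> keep (inclusive)
    c = c(1000, 1000, 1000, 2000, 1000),   # ref-outgroup at limit 1.00 -> keep
    d = rep(777, 5)))
  res <- filter_length_conservation(sets, thr())
  expect_setequal(unique(res$kept$set_id), c("b", "c", "d"))
  expect_match(res$outcomes$detail[res$outcomes$set_id == "a"], "h-c")
})

test_that("flank rule is strict below 40 and keeps exactly 40", {
  sets <- make_sets(list(a = rep(500, 5), b = rep(500, 5), c = rep(500, 5)),
                    flanks = list(a = c(100, 100, 100, 39, 100),
                                  b = rep(40L, 5)))
  res <- filter_flanks(sets, thr())
  expect_setequal(unique(res$kept$set_id), c("b", "c"))
})

make_hits <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      species = r$sp, query_id = r$q, subject_id = r$subj,
      percent_identity = 99, alignment_length = 100L, mismatches = 1L,
      gap_opens = 0L, query_start = 1L, query_end = 100L,
      subject_start = r$s, subject_end = r$s + 99L,
      evalue = r$e, bit_score = 180)
  }))
}

single_copy_base_hits <- function(sets) {
  rows <- list()
  for (i in seq_len(nrow(sets))) {
    for (side in c("up", "down")) {
      rows[[length(rows) + 1L]] <- list(
        sp = sets$species[i], q = paste0(sets$set_id[i], "|", side),
        subj = "chr1", s = 1000L * i, e = 1e-120)
    }
  }
  rows
}

test_that("single-copy test rejects extra subject regions and split HSPs", {
  sets <- make_sets(list(ok = rep(500, 5), dup = rep(500, 5),
                         split = rep(500, 5), weak = rep(500, 5)))
  rows <- single_copy_base_hits(sets)
  # dup: a second significant region far away in species h
  rows[[length(rows) + 1L]] <- list(sp = "h", q = "dup|up", subj = "chr2",
                                    s = 99000L, e = 1e-50)
  # split: same region covered by a second HSP (overlapping)
  rows[[length(rows) + 1L]] <- list(sp = "h", q = "split|up", subj = "chr1",
                                    s = 1000L * which(sets$set_id == "split" &
                                                        sets$species == "h"),
                                    e = 1e-30)
  # weak: second hit above the e-value cutoff -> ignored
  rows[[length(rows) + 1L]] <- list(sp = "h", q = "weak|up", subj = "chr2",
                                    s = 5000L, e = 1e-3)
  res <- filter_single_copy(sets, make_hits(rows), thr())
  expect_setequal(unique(res$kept$set_id), c("ok", "weak"))
})

test_that("nearby HSPs merge into one region but 1 region needs 1 HSP", {
  sets <- make_sets(list(near = rep(500, 5)))
  rows <- single_copy_base_hits(sets)
  # a second HSP 500 nt away on the same subject: same region (gap < 1 kb),
  # but now that region has two sub-alignments -> reject
  i <- which(sets$set_id == "near" & sets$species == "h")
  rows[[length(rows) + 1L]] <- list(sp = "h", q = "near|up", subj = "chr1",
                                    s = 1000L * i + 600L, e = 1e-40)
  res <- filter_single_copy(sets, make_hits(rows), thr())
  expect_equal(nrow(res$kept), 0L)
  expect_match(res$outcomes$detail, "max_regions=1")
})

test_that("a query with zero hits is a data error", {
  sets <- make_sets(list(a = rep(500, 5)))
  rows <- single_copy_base_hits(sets)
  rows <- rows[-1]
  expect_error(filter_single_copy(sets, make_hits(rows), thr()),
               "self-hit")
})

test_that("cascade stages are ordered, monotonic and idempotent", {
  sim <- small_sim()
  sp <- sim$config$species
  introns <- dplyr::bind_rows(lapply(sp, function(s) {
    extract_introns(sim$genomes[[s]],
                    sim$gene_models[sim$gene_models$species == s, ])
  }))
  gs <- cross_orthology_tables(sim$orthology, sp, anchor = sp[1])
  sets <- match_introns(gs, introns, anchor = sp[1])
  thr5 <- filter_thresholds(pair_limits = pair_limits_default(sp))
  casc <- run_cascade(sets, thr5, sp[1], hits = sim$hits)
  expect_true(all(diff(casc$stage_counts$survivors) <= 0))
  # every set reaching a stage has exactly one outcome at that stage
  expect_equal(anyDuplicated(casc$outcomes[, c("set_id", "stage")]), 0L)
  # idempotence: re-running on the survivors changes nothing
  again <- run_cascade(casc$kept, thr5, sp[1], hits = sim$hits)
  expect_equal(sort(unique(again$kept$set_id)),
               sort(unique(casc$kept$set_id)))
  # deterministic filters commute: flank before lengths gives the same set
  alt1 <- filter_flanks(sets, thr5)$kept
  alt2 <- filter_length_conservation(alt1, thr5)$kept
  alt3 <- filter_reference_length(alt2, thr5, sp[1])$kept
  alt4 <- filter_single_copy(alt3, sim$hits, thr5)$kept
  expect_equal(sort(unique(alt4$set_id)), sort(unique(casc$kept$set_id)))
})

test_that("empty input and infinite limits behave as documented", {
  sets <- make_sets(list(a = rep(500, 5)))
  empty <- sets[0, ]
  casc <- run_cascade(empty, thr(), "h")
  expect_true(all(casc$stage_counts$survivors == 0L))
  inf_thr <- filter_thresholds(
    ref_min_len = 1L, ref_max_len = .Machine$integer.max,
    pair_limits = pair_limits_default(c("h", "c", "m", "w", "d")) |>
      dplyr::mutate(limit = Inf))
  r1 <- filter_reference_length(sets, inf_thr, "h")
  r2 <- filter_length_conservation(sets, inf_thr)
  expect_equal(nrow(r1$kept), nrow(sets))
  expect_equal(nrow(r2$kept), nrow(sets))
})

test_that("built-in scanner agrees with generator hit tables on planted copies", {
  sim <- memo("scanner_sim",
              simulate_clade(simulation_config(n_genes = 8L, seed = 21L)))
  s <- sim$config$species[1]
  gm <- sim$gene_models[sim$gene_models$species == s, ]
  ints <- extract_introns(sim$genomes[[s]], gm)
  lab <- sim$labels
  # one duplicated and one normal gene, both flanking exons of intron 1
  pick <- function(cls) {
    id <- lab$set_id[lab$class == cls][1]
    gene <- sub("\\.intron.*$", "", id)
    gene <- sub(paste0("^", sim$config$species[1]), s, gene)
    r <- ints[ints$gene_id == gene & ints$intron_index == 1L, ]
    tibble::tibble(query_id = paste0(id, c("|up", "|down")),
                   sequence = c(r$upstream_exon_seq, r$downstream_exon_seq))
  }
  queries <- dplyr::bind_rows(pick("duplicated"), pick("normal"))
  hits <- scan_genome_hits(queries, sim$genomes[[s]])
  n_regions <- hits |>
    dplyr::group_by(query_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  dup_q <- queries$query_id[1:2]
  norm_q <- queries$query_id[3:4]
  expect_true(all(n_regions$n[n_regions$query_id %in% dup_q] == 2L))
  expect_true(all(n_regions$n[n_regions$query_id %in% norm_q] == 1L))
})
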