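test_that("sequence evolution is identity at t = 0 and matches JC expectations", {
  set.seed(1)
  anc <- random_dna(2000)
  expect_equal(evolve_sequence(anc, 0), anc)

  n <- 10000L
  anc2 <- random_dna(n)
  der <- evolve_sequence(anc2, 0.2)
  p_obs <- mean(strsplit(anc2, "")[[1]] != strsplit(der, "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 0.2))       # about 0.1401
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)

  # estimator consistency at t = 0.3 over 50 kb
  anc3 <- random_dna(50000L)
  der3 <- evolve_sequence(anc3, 0.3)
  d <- jc_distance(anc3, der3)
  p3 <- 0.75 * (1 - exp(-4 / 3 * 0.3))
  se_d <- sqrt(p3 * (1 - p3) / 50000) / (1 - 4 * p3 / 3)
  expect_lt(abs(d - 0.3), 3 * se_d)
})

test_that("the simulator is deterministic under a seed and varies across seeds", {
  cfg <- simulation_config(n_genes = 6L, seed = 33L)
  s1 <- simulate_clade(cfg)
  s2 <- simulate_clade(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$snps, s2$snps)
  s3 <- simulate_clade(simulation_config(n_genes = 6L, seed = 34L))
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("emitted FASTA/GFF3 re-ingest to exactly the generator's introns", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  for (s in sim$config$species[c(1, 4)]) {
    genome <- read_genome_fasta(file.path(dir, paste0(s, ".fa")))
    models <- read_gene_models(file.path(dir, paste0(s, ".gff3")), s)
    ints <- extract_introns(genome, models)
    truth <- sim$truth_introns[sim$truth_introns$species == s, ]
    j <- dplyr::inner_join(ints, truth, by = c("gene_id", "intron_index"),
                           suffix = c("", ".t"))
    expect_equal(nrow(j), nrow(truth))
    expect_true(all(j$sequence == j$sequence.t))
    expect_true(all(j$start == j$start.t & j$end == j$end.t))
    expect_true(all(j$strand == j$strand.t))
  }
})

test_that("mean pairwise distances across loci recover the tree path lengths", {
  sim <- memo("param_sim", simulate_clade(
    simulation_config(n_genes = 60L, seed = 55L,
                      class_props = c(normal = 1, conserved = 0,
                                      accelerated = 0, duplicated = 0,
                                      microsatellite = 0, short = 0,
                                      long = 0, length_divergent = 0,
                                      small_flank = 0))))
  tr <- sim$config$tree
  params <- gtr_params(sim$config$freqs, sim$config$rates)
  truth <- sim$truth_introns
  path <- ape::cophenetic.phylo(tr)
  for (pair in list(c("human", "chimp"), c("human", "macaque"),
                    c("cow", "dog"))) {
    a <- truth[truth$species == pair[1], ]
    b <- truth[truth$species == pair[2], ]
    j <- dplyr::inner_join(a, b, by = c("gene_index", "intron_index"),
                           suffix = c(".a", ".b"))
    d <- vapply(seq_len(nrow(j)), function(i) {
      gtr_ml_distance(j$sequence.a[i], j$sequence.b[i], params)
    }, numeric(1))
    expected <- path[pair[1], pair[2]]
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - expected), 3 * se + 0.001)
  }
})

test_that("planted classes carry the documented structural defects", {
  sim <- small_sim()
  lab <- sim$labels
  truth <- sim$truth_introns
  ref <- sim$config$species[1]
  ref_truth <- truth[truth$species == ref, ]
  ref_truth$set_id <- paste0(ref_truth$gene_id, ".intron",
                             ref_truth$intron_index)
  j <- dplyr::inner_join(ref_truth |> dplyr::select(-class), lab,
                         by = "set_id")
  expect_equal(nrow(j), nrow(ref_truth))
  expect_true(all(j$length[j$class == "short"] < 200))
  expect_true(all(j$length[j$class == "long"] > 1600))
  expect_true(all(j$length[j$class == "normal"] >= 200 &
                    j$length[j$class == "normal"] <= 1600))
  # length-divergent: the divergent taxon is >10% longer than the reference
  dv <- sim$config$divergent_taxon
  dv_truth <- truth[truth$species == dv, ]
  j2 <- dplyr::inner_join(
    ref_truth, dv_truth, by = c("gene_index", "intron_index"),
    suffix = c(".ref", ".dv"))
  j2 <- dplyr::inner_join(j2, lab,
                          by = c(set_id = "set_id"))
  delta <- abs(j2$length.dv - j2$length.ref) / j2$length.ref
  expect_true(all(delta[j2$class == "length_divergent"] > 0.10))
  expect_true(all(delta[j2$class == "normal"] == 0))
  # microsatellite class is detectable in every species
  ms_ids <- lab$set_id[lab$class == "microsatellite"]
  for (id in ms_ids) {
    g <- as.integer(sub(".*_g(\\d+)\\.intron.*", "\\1", id))
    ii <- as.integer(sub(".*intron", "", id))
    rows <- truth[truth$gene_index == g & truth$intron_index == ii, ]
    found <- vapply(rows$sequence, function(sq) {
      nrow(find_microsatellites(sq)) > 0
    }, logical(1))
    expect_true(all(found))
  }
  # duplicated class: two significant subject regions in the hit table
  dup_ids <- lab$set_id[lab$class == "duplicated"]
  h <- sim$hits[sim$hits$evalue <= 1e-4, ]
  h$set_id <- sub("\\|(up|down)$", "", h$query_id)
  n_hits <- h |>
    dplyr::filter(set_id %in% dup_ids) |>
    dplyr::count(set_id, species, query_id)
  expect_true(all(n_hits$n == 2L))
})

test_that("discrete-gamma mode preserves the mean rate", {
  set.seed(88)
  rates <- intronmine:::gamma_category_rates(0.5)
  expect_equal(mean(rates), 1)
  expect_true(all(diff(rates) > 0))
  cfg <- simulation_config(n_genes = 4L, seed = 3L, gamma_shape = 0.5)
  sim <- simulate_clade(cfg)
  expect_equal(nrow(sim$labels), 8L)
})
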