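test_that("SNP counting respects half-open intron coordinates", {
  introns <- tibble::tibble(chromosome = "chr1", start = 100L, end = 900L,
                            length = 800L)
  snps <- tibble::tibble(chromosome = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                         position = c(100L, 500L, 700L, 899L, 500L))
  out <- snp_density(introns, snps)
  expect_equal(out$snp_count, 4L)
  expect_equal(out$snp_density, 0.005)
  # SNP exactly at `end` is outside
  out2 <- snp_density(introns,
                      tibble::tibble(chromosome = "chr1", position = 900L))
  expect_equal(out2$snp_count, 0L)
  expect_equal(out2$snp_density, 0)
  # linearity: doubling the in-intron SNP list doubles the count
  out3 <- snp_density(introns, dplyr::bind_rows(snps, snps))
  expect_equal(out3$snp_count, 8L)
})

test_that("microsatellite detection matches the documented examples", {
  set.seed(9)
  flank <- random_dna(30)
  hit <- find_microsatellites(paste0(flank, "ACACACACAC", random_dna(30)))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AC")
  expect_equal(hit$copies, 5L)
  expect_equal(hit$end - hit$start, 10L)

  homo <- find_microsatellites("AAAAAAAA")
  expect_equal(homo$motif, "A")
  expect_equal(homo$copies, 8L)

  expect_equal(nrow(find_microsatellites("ACGTACGAACGT")), 0L)
})

test_that("microsatellite detection agrees with a brute-force scanner", {
  set.seed(77)
  for (i in 1:6) {
    # random sequence with planted tandems of various motif sizes
    s <- paste0(random_dna(400), strrep("TAG", 6), random_dna(300),
                strrep("A", 10), random_dna(500), strrep("GT", 7),
                random_dna(300))
    fast <- find_microsatellites(s)
    slow <- brute_microsatellites(s)
    expect_equal(fast$motif, slow$motif)
    expect_equal(fast$start, slow$start)
    expect_equal(fast$copies, slow$copies)
  }
})

test_that("repeat coverage uses interval union, not the sum", {
  intron <- tibble::tibble(chromosome = "chr1", start = 0L, end = 450L,
                           length = 450L)
  reps <- tibble::tibble(
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(10L, 50L, 0L), end = c(100L, 140L, 400L),
    repeat_class = c("SINE", "SINE", "LINE"))
  rc <- repeat_content(intron, reps)
  expect_equal(rc$fraction_masked, 130 / 450)   # union of [10,100) and [50,140)
  expect_equal(rc$classes, "SINE")
  # a single 90-nt SINE over a 450-nt intron: 0.2
  rc2 <- repeat_content(intron, reps[1, ])
  expect_equal(rc2$fraction_masked, 0.2)
  none <- repeat_content(intron, reps[3, ])
  expect_equal(none$fraction_masked, 0)
  expect_length(none$classes, 0L)
  # order invariance and bounds
  rc3 <- repeat_content(intron, reps[c(2, 3, 1), ])
  expect_equal(rc3$fraction_masked, rc$fraction_masked)
  expect_gte(rc$fraction_masked, 0)
  expect_lte(rc$fraction_masked, 1)
})

test_that("pair divergence is zero for identical alleles and about 1/1000 for one change", {
  set.seed(31)
  a <- random_dna(1000)
  expect_equal(species_pair_divergence(a, a), 0)
  b <- a
  substr(b, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 500, 500))[1]
  d <- species_pair_divergence(a, b)
  expect_equal(d, 0.001, tolerance = 0.35)
  # recovery of a known simulated distance
  der <- evolve_sequence(a, 0.05)
  d2 <- species_pair_divergence(a, der)
  expect_equal(d2, 0.05, tolerance = 0.25)
})

test_that("primer consensus applies IUPAC codes and the degeneracy cap", {
  # perfectly conserved exon: degeneracy 1, window abuts the intron
  cons <- new_alignment(paste0("s", 1:4), rep(strrep("ACGTA", 8), 4))
  fwd <- suggest_degenerate_primers(cons, "forward", window_min = 20,
                                    window_max = 20)
  expect_equal(fwd$degeneracy[1], 1)
  expect_equal(fwd$dist_to_intron[1], 0L)
  expect_equal(fwd$sequence[1], substr(strrep("ACGTA", 8), 21, 40))

  # one column {C,T} -> Y and one {A,G} -> R, degeneracy 4
  base <- strrep("A", 25)
  v1 <- base; substr(v1, 10, 10) <- "C"; substr(v1, 12, 12) <- "A"
  v2 <- base; substr(v2, 10, 10) <- "T"; substr(v2, 12, 12) <- "G"
  aln <- new_alignment(c("x", "y"), c(v1, v2))
  out <- suggest_degenerate_primers(aln, "forward", window_min = 20,
                                    window_max = 20, n_best = 10)
  w <- out[out$window_start == 0, ]
  expect_equal(substr(w$sequence, 10, 10), "Y")
  expect_equal(substr(w$sequence, 12, 12), "R")
  expect_equal(w$degeneracy, 4)

  # three fully ambiguous columns: degeneracy 64 > 48 -> no window
  v3 <- base; v4 <- base; v5 <- base; v6 <- base
  for (i in 1:3) {
    substr(v3, i, i) <- "A"; substr(v4, i, i) <- "C"
    substr(v5, i, i) <- "G"; substr(v6, i, i) <- "T"
  }
  blocked <- new_alignment(paste0("t", 1:4), c(v3, v4, v5, v6))
  expect_warning(
    none <- suggest_degenerate_primers(blocked, "forward",
                                       window_min = 25, window_max = 25),
    "degeneracy")
  expect_equal(nrow(none), 0L)
})

test_that("reverse primers are reverse complements over the same window", {
  set.seed(13)
  base <- random_dna(30)
  v1 <- base; v2 <- base; v3 <- base
  substr(v2, 7, 7) <- "A"; substr(v2, 15, 15) <- "C"
  substr(v3, 7, 7) <- "G"; substr(v3, 22, 22) <- "T"
  aln <- new_alignment(paste0("s", 1:3), c(v1, v2, v3))
  fwd <- suggest_degenerate_primers(aln, "forward", window_min = 20,
                                    window_max = 20, max_degeneracy = 1e6,
                                    n_best = 100)
  rev <- suggest_degenerate_primers(aln, "reverse", window_min = 20,
                                    window_max = 20, max_degeneracy = 1e6,
                                    n_best = 100)
  expect_gt(nrow(rev), 0L)
  for (i in seq_len(nrow(rev))) {
    f <- fwd[fwd$window_start == rev$window_start[i], ]
    expect_equal(
      rev$sequence[i],
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(f$sequence))))
  }
})

test_that("TRF .dat ingestion converts coordinates", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "Tandem Repeats Finder Program",
    "Sequence: chr1 test",
    "Parameters: 2 7 7 80 10 50 6",
    "101 130 2 15.0 2 95 0 51 50 50 0 0 1.00 AC ACACACACACACACACACACACACACACAC"
  ), f)
  out <- read_trf_dat(f)
  expect_equal(out$sequence_id, "chr1")
  expect_equal(out$start, 100L)
  expect_equal(out$end, 130L)
  expect_equal(out$motif, "AC")
  expect_equal(out$copies, 15)
})
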