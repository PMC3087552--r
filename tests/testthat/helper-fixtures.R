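# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small labelled clade exercised by several module tests
small_sim <- function() {
  memo("small_sim", simulate_clade(simulation_config(n_genes = 40L, seed = 7L)))
}

# study-scale labelled clade (500 genes, seed 1) and its pipeline run,
# shared by the acceptance checks
big_sim <- function() {
  memo("big_sim", simulate_clade(simulation_config(seed = 1L)))
}

big_run <- function() {
  memo("big_run", {
    sim <- big_sim()
    cfg <- sim$config
    k_max <- calibrate_k_threshold(cfg$tree, cfg$accel_taxon,
                                   cfg$accel_factor)
    dir <- file.path(tempdir(), "big_run_out")
    res <- run_pipeline(pipeline_config(species = cfg$species, sim = sim,
                                        k_max = k_max, out_dir = dir))
    list(res = res, dir = dir, k_max = k_max)
  })
}

small_pipeline <- function() {
  memo("small_pipeline", {
    sim <- small_sim()
    cfg <- sim$config
    k_max <- calibrate_k_threshold(cfg$tree, cfg$accel_taxon,
                                   cfg$accel_factor)
    run_pipeline(pipeline_config(species = cfg$species, sim = sim,
                                 k_max = k_max))
  })
}

# terminal stage observed for every set of a pipeline result
observed_stages <- function(res, sim) {
  removed <- res$outcomes |>
    dplyr::filter(!passed) |>
    dplyr::distinct(set_id, stage)
  final <- tibble::tibble(set_id = res$reports$set_id, stage = "final")
  dplyr::inner_join(sim$labels, dplyr::bind_rows(removed, final),
                    by = "set_id")
}

# brute-force microsatellite scanner: every motif length, every offset,
# greedy maximal extension; independent of the rle-based implementation
brute_microsatellites <- function(sequence, min_copies = 3L, min_tract = 8L) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(v)
  hits <- list()
  for (k in 1:6) {
    i <- 1L
    while (i + k <= n) {
      copies <- 1L
      while (i + (copies + 1L) * k - 1L <= n &&
             all(v[i:(i + k - 1L)] ==
                   v[(i + copies * k):(i + (copies + 1L) * k - 1L)]) &&
             !any(v[i:(i + k - 1L)] == "N")) {
        copies <- copies + 1L
      }
      if (copies >= min_copies && copies * k >= min_tract) {
        motif <- paste(v[i:(i + k - 1L)], collapse = "")
        primitive <- TRUE
        for (d in seq_len(k - 1L)) {
          if (k %% d == 0L && motif == strrep(substr(motif, 1, d), k / d)) {
            primitive <- FALSE
          }
        }
        if (primitive) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            motif = motif, copies = copies, start = i - 1L,
            end = i - 1L + copies * k)
        }
        i <- i + copies * k
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(motif = character(), copies = integer(),
                          start = integer(), end = integer()))
  }
  out <- dplyr::bind_rows(hits)
  out <- out[order(-(out$end - out$start), nchar(out$motif), out$start), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(out$start[i] < out$end[prior] & out$end[i] > out$start[prior])) {
      keep[i] <- FALSE
    }
  }
  out <- out[keep, ]
  out[order(out$start), ]
}

random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}
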