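#' Configuration for the synthetic five-species clade simulator
#'
#' The defaults emulate the study conditions of the mammalian intron-marker
#' screen: a five-taxon clade shaped `(((ref,sister),third),(out1,out2))`
#' with branch lengths giving realistic intron divergences (reference-sister
#' distance 0.014 substitutions/site), introns of 500-1500 nt flanked by
#' exons evolving at 0.3x the intron rate, and planted intron classes that
#' each deterministic or phylogenetic filter is expected to remove.
#'
#' Planted classes (gene-level; every intron of a gene carries its gene's
#' class) and the stage expected to remove them:
#' \describe{
#'   \item{normal}{clock-like, adequate length: survives to `final`.}
#'   \item{conserved}{all branches scaled by `conserved_scale` (default
#'     0.3): removed by the `divergence` filter (scaling factor about 3.3).}
#'   \item{accelerated}{intron rate on the `accel_taxon` pendant branch
#'     multiplied by `accel_factor` (default 5): removed by the `k_score`
#'     filter.}
#'   \item{duplicated}{a second, about 90%-identical copy of the gene is
#'     inserted elsewhere in every genome: removed by `single_copy`.}
#'   \item{microsatellite}{an exact tandem tract is written into the intron
#'     (same position, all species): annotated, survives to `final`.}
#'   \item{short}{reference intron < 200 nt: removed by `ref_length`.}
#'   \item{long}{reference intron > 1600 nt: removed by `ref_length`.}
#'   \item{length_divergent}{an insertion of `divergent_frac` of the intron
#'     length in `divergent_taxon`: removed by `length_conservation`.}
#'   \item{small_flank}{one internal exon shorter than 40 nt: removed by
#'     `flank`.}
#' }
#'
#' @param species Five species names; the first is the reference, the first
#'   three form the "primate" subset used by the divergence filter.
#' @param tree_newick Rooted species tree over `species` with branch
#'   lengths in substitutions/site.
#' @param n_genes Number of orthologous genes to simulate.
#' @param introns_per_gene Introns per gene.
#' @param intron_len_range,exon_len_range Uniform length ranges (nt).
#' @param freqs,rates GTR parameters of the simulation
#'   (see [gtr_params()]).
#' @param rate_sdlog Lognormal sdlog of the per-gene intron rate
#'   multiplier (meanlog 0).
#' @param exon_rate_scale Exon rate relative to the intron rate.
#' @param class_props Named numeric vector of planted-class proportions
#'   (must sum to 1).
#' @param conserved_scale Rate multiplier of the conserved class.
#' @param accel_factor,accel_taxon Acceleration multiplier and the species
#'   whose pendant branch carries it.
#' @param divergent_taxon,divergent_frac Species and relative size of the
#'   insertion planted in the length-divergent class.
#' @param small_flank_len Length (nt) of the undersized exon.
#' @param microsat_len Approximate length (nt) of planted tandem tracts.
#' @param snp_mean_density Mean SNPs per nucleotide in reference-species
#'   introns (Poisson).
#' @param decoy_hit_prob Probability that a query additionally receives one
#'   insignificant decoy hit (e-value above the cutoff).
#' @param dup_divergence Per-site substitution probability applied to the
#'   planted gene duplicates (0.1 = about 90% identity).
#' @param gamma_shape Optional shape of 4-category discrete-gamma
#'   among-site rate variation; `NULL` (default) for rate homogeneity.
#' @param seed Integer seed; the simulation is a deterministic function of
#'   the configuration including this seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    species = c("human", "chimp", "macaque", "cow", "dog"),
    tree_newick = paste0("(((human:0.007,chimp:0.007):0.02,macaque:0.06)",
                         ":0.03,(cow:0.09,dog:0.08):0.03);"),
    n_genes = 500L, introns_per_gene = 2L,
    intron_len_range = c(500L, 1500L), exon_len_range = c(60L, 200L),
    freqs = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 4, 1, 1, 4, 1),
    rate_sdlog = 0.05, exon_rate_scale = 0.3,
    class_props = c(normal = 0.50, conserved = 0.10, accelerated = 0.05,
                    duplicated = 0.10, microsatellite = 0.05, short = 0.05,
                    long = 0.05, length_divergent = 0.05,
                    small_flank = 0.05),
    conserved_scale = 0.3, accel_factor = 5, accel_taxon = "cow",
    divergent_taxon = "chimp", divergent_frac = 0.25,
    small_flank_len = 25L, microsat_len = 30L,
    snp_mean_density = 0.0043, decoy_hit_prob = 0.1,
    dup_divergence = 0.1, gamma_shape = NULL, seed = 1L) {
  if (length(species) != 5L) abort("need exactly five species")
  if (abs(sum(class_props) - 1) > 1e-8) abort("class proportions must sum to 1")
  if (any(class_props < 0)) abort("class proportions must be >= 0")
  tree <- read_tree(text = tree_newick)
  if (!setequal(tree$tip.label, species)) {
    abort("tree leaves must match `species`")
  }
  if (!accel_taxon %in% species || !divergent_taxon %in% species) {
    abort("accel_taxon and divergent_taxon must be study species")
  }
  structure(list(
    species = species, tree_newick = tree_newick, tree = tree,
    n_genes = as.integer(n_genes),
    introns_per_gene = as.integer(introns_per_gene),
    intron_len_range = intron_len_range, exon_len_range = exon_len_range,
    freqs = freqs, rates = rates, rate_sdlog = rate_sdlog,
    exon_rate_scale = exon_rate_scale, class_props = class_props,
    conserved_scale = conserved_scale, accel_factor = accel_factor,
    accel_taxon = accel_taxon, divergent_taxon = divergent_taxon,
    divergent_frac = divergent_frac, small_flank_len = small_flank_len,
    microsat_len = microsat_len, snp_mean_density = snp_mean_density,
    decoy_hit_prob = decoy_hit_prob, dup_divergence = dup_divergence,
    gamma_shape = gamma_shape, seed = as.integer(seed)
  ), class = "simulation_config")
}

# stage each class is expected to terminate at
CLASS_STAGE <- c(normal = "final", conserved = "divergence",
                 accelerated = "k_score", duplicated = "single_copy",
                 microsatellite = "final", short = "ref_length",
                 long = "ref_length", length_divergent = "length_conservation",
                 small_flank = "flank")

random_codes <- function(n, freqs) {
  sample.int(4L, n, replace = TRUE, prob = freqs)
}

# uniform integer draw that is safe for degenerate lo == hi ranges
# (base sample(x, ...) would sample from 1:x for scalar x)
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

codes_to_string <- function(codes) {
  paste(BASES[codes], collapse = "")
}

# evolve integer-coded sequence along branch length t (vectorized by base)
evolve_codes <- function(codes, t, params) {
  if (t == 0 || length(codes) == 0L) return(codes)
  P <- gtr_transition_matrix(params, t)
  child <- codes
  for (b in 1:4) {
    idx <- which(codes == b)
    if (length(idx) > 0L) {
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  child
}

#' Evolve a sequence along a branch under the GTR model
#'
#' Per-site independent substitution by the transition-probability matrix
#' `P(t) = exp(Qt)` with Q normalized to one expected substitution per site
#' per unit branch length. Randomness comes from the R session RNG; seed it
#' for reproducibility.
#'
#' @param sequence Ancestor nucleotide string (A/C/G/T).
#' @param branch_length Branch length `t >= 0` in substitutions/site.
#' @param params A [gtr_params()] object.
#' @return The child sequence (same length).
#' @export
evolve_sequence <- function(sequence, branch_length, params = gtr_params()) {
  if (branch_length < 0) abort("branch_length must be >= 0")
  codes <- encode_dna(sequence)
  if (anyNA(codes)) abort("sequence must contain only A, C, G, T")
  codes_to_string(evolve_codes(codes, branch_length, params))
}

# 4-category discrete-gamma rates (category means), or NULL
gamma_category_rates <- function(shape, k = 4L) {
  q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  q / mean(q)
}

#' Simulate a fully labelled synthetic clade
#'
#' Generates, per species, a genome FASTA-equivalent tibble and exon-level
#' gene models, plus pairwise orthology tables, per-species hit tables,
#' reference-species SNPs, and a ground-truth label per orthologous intron
#' set naming the filter stage expected to remove it. The simulation is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: when given, all outputs are also written
#'   as plain-text files (FASTA, GFF3, TSV).
#' @return A list with elements `genomes` (named list of sequence tibbles),
#'   `gene_models` (exon tibble over all species), `orthology` (list of
#'   pairwise tables), `hits` (hit tibble with a `species` column), `snps`,
#'   `labels` (tibble `set_id`, `class`, `expected_stage`), `truth_introns`
#'   (the simulator's own intron records) and `config`.
#' @export
simulate_clade <- function(config, dir = NULL) {
  set.seed(config$seed)
  sp <- config$species
  ref <- sp[1]
  params <- gtr_params(config$freqs, config$rates)
  tree <- config$tree
  n_tip <- length(tree$tip.label)
  k_int <- config$introns_per_gene
  n_seg <- 2L * k_int + 1L          # exon,intron,...,exon
  seg_is_exon <- seq_len(n_seg) %% 2L == 1L
  site_rates <- if (is.null(config$gamma_shape)) NULL else
    gamma_category_rates(config$gamma_shape)

  # --- gene plan -----------------------------------------------------------
  classes <- names(config$class_props)
  n_per_class <- floor(config$class_props * config$n_genes)
  shortfall <- config$n_genes - sum(n_per_class)
  if (shortfall > 0L) {
    extra <- order(config$class_props, decreasing = TRUE)[seq_len(shortfall)]
    n_per_class[extra] <- n_per_class[extra] + 1L
  }
  gene_class <- sample(rep(classes, n_per_class))
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE,
                    prob = c(0.7, 0.3))
  chroms <- ifelse(seq_len(config$n_genes) <= ceiling(config$n_genes / 2),
                   "chr1", "chr2")
  gene_rate <- stats::rlnorm(config$n_genes, 0, config$rate_sdlog)

  plan <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    cls <- gene_class[g]
    exon_lens <- sample_range(config$exon_len_range[1],
                              config$exon_len_range[2], k_int + 1L)
    if (cls == "small_flank") exon_lens[2L] <- config$small_flank_len
    intron_lens <- switch(
      cls,
      short = sample_range(100L, 199L, k_int),
      long = sample_range(1601L, 2200L, k_int),
      sample_range(config$intron_len_range[1], config$intron_len_range[2],
                   k_int))
    seg_lens <- integer(n_seg)
    seg_lens[seg_is_exon] <- exon_lens
    seg_lens[!seg_is_exon] <- intron_lens
    plan[[g]] <- list(class = cls, strand = strands[g], chrom = chroms[g],
                      seg_lens = seg_lens, rate = gene_rate[g])
  }

  # --- evolve down the tree ------------------------------------------------
  root_node <- n_tip + 1L
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  accel_tip <- match(config$accel_taxon, tree$tip.label)

  tip_segs <- vector("list", config$n_genes)  # [[gene]][[species]][[segment]]
  for (g in seq_len(config$n_genes)) {
    p <- plan[[g]]
    root_segs <- map(p$seg_lens, random_codes, freqs = config$freqs)
    seg_rate_cats <- if (is.null(site_rates)) NULL else
      map(p$seg_lens, function(L) sample.int(4L, L, replace = TRUE))
    intron_mult <- p$rate *
      (if (p$class == "conserved") config$conserved_scale else 1)
    seg_mult <- ifelse(seg_is_exon, config$exon_rate_scale, intron_mult)
    per_species <- vector("list", n_tip)

    walk <- function(node, segs) {
      for (e in children_of[[as.character(node)]]) {
        child <- tree$edge[e, 2]
        t_edge <- tree$edge.length[e]
        accel <- p$class == "accelerated" && child == accel_tip
        child_segs <- vector("list", n_seg)
        for (s in seq_len(n_seg)) {
          t_seg <- t_edge * seg_mult[s] *
            (if (accel && !seg_is_exon[s]) config$accel_factor else 1)
          if (is.null(site_rates)) {
            child_segs[[s]] <- evolve_codes(segs[[s]], t_seg, params)
          } else {
            cs <- segs[[s]]
            for (cat in 1:4) {
              idx <- which(seg_rate_cats[[s]] == cat)
              if (length(idx) > 0L) {
                cs[idx] <- evolve_codes(segs[[s]][idx],
                                        t_seg * site_rates[cat], params)
              }
            }
            child_segs[[s]] <- cs
          }
        }
        if (child <= n_tip) {
          per_species[[child]] <<- child_segs
        } else {
          walk(child, child_segs)
        }
      }
    }
    walk(root_node, root_segs)
    names(per_species) <- tree$tip.label
    tip_segs[[g]] <- per_species[sp]
  }

  # --- post-evolution planted edits ---------------------------------------
  for (g in seq_len(config$n_genes)) {
    p <- plan[[g]]
    if (p$class == "microsatellite") {
      for (ii in seq_len(k_int)) {
        seg <- 2L * ii
        len <- p$seg_lens[seg]
        motif <- sample(c("A", "AC", "AG", "AAT", "ACT"), 1)
        copies <- max(3L, ceiling(config$microsat_len / nchar(motif)))
        tract <- encode_dna(strrep(motif, copies))
        at <- sample.int(len - length(tract) - 2L, 1) + 1L
        for (s in sp) {
          tip_segs[[g]][[s]][[seg]][at:(at + length(tract) - 1L)] <- tract
        }
      }
    }
    if (p$class == "length_divergent") {
      for (ii in seq_len(k_int)) {
        seg <- 2L * ii
        len <- p$seg_lens[seg]
        ins_len <- max(1L, round(config$divergent_frac * len))
        at <- sample.int(len - 1L, 1)
        ins <- random_codes(ins_len, config$freqs)
        old <- tip_segs[[g]][[config$divergent_taxon]][[seg]]
        tip_segs[[g]][[config$divergent_taxon]][[seg]] <-
          c(old[seq_len(at)], ins, old[seq(at + 1L, len)])
      }
    }
  }

  # --- assemble genomes, annotations, truth records -----------------------
  mutate_codes <- function(codes, pmut) {
    hit <- which(stats::runif(length(codes)) < pmut)
    if (length(hit) > 0L) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
    }
    codes
  }
  spacer <- function() random_codes(sample(250:350, 1), config$freqs)

  genomes <- list(); models <- list(); truth <- list()
  hits <- list(); snps <- list()
  dup_coords <- list()

  for (s in sp) {
    chrom_codes <- list(chr1 = integer(), chr2 = integer())
    exon_rows <- list(); intron_rows <- list()
    for (g in seq_len(config$n_genes)) {
      p <- plan[[g]]
      segs <- tip_segs[[g]][[s]]
      seg_lens <- lengths(segs)
      gene_seq <- unlist(segs, use.names = FALSE)
      L <- length(gene_seq)
      chrom_codes[[p$chrom]] <- c(chrom_codes[[p$chrom]], spacer())
      gstart <- length(chrom_codes[[p$chrom]])      # 0-based gene start
      placed <- if (p$strand == "+") gene_seq else rev(5L - gene_seq)
      chrom_codes[[p$chrom]] <- c(chrom_codes[[p$chrom]], placed)
      # transcript-coordinate segment spans
      ends <- cumsum(seg_lens); starts <- ends - seg_lens
      gcoord <- function(a, b) {                    # transcript -> genomic
        if (p$strand == "+") c(gstart + a, gstart + b)
        else c(gstart + L - b, gstart + L - a)
      }
      gid <- paste0(s, "_g", sprintf("%04d", g))
      for (x in seq_len(n_seg)) {
        cc <- gcoord(starts[x], ends[x])
        if (seg_is_exon[x]) {
          exon_rows[[length(exon_rows) + 1L]] <- tibble(
            species = s, gene_id = gid,
            transcript_id = paste0(gid, ".t1"), chromosome = p$chrom,
            strand = p$strand, exon_rank = (x + 1L) %/% 2L,
            start = cc[1], end = cc[2],
            description = paste0("simulated ", p$class, " gene"))
        } else {
          intron_rows[[length(intron_rows) + 1L]] <- tibble(
            species = s, gene_id = gid, intron_index = x %/% 2L,
            chromosome = p$chrom, strand = p$strand,
            start = cc[1], end = cc[2],
            length = cc[2] - cc[1],
            sequence = codes_to_string(segs[[x]]),
            class = p$class, gene_index = g)
        }
      }
      # planted duplicate: a diverged copy of the whole gene at the
      # chromosome end (appended after all genes; queued here)
      if (p$class == "duplicated") {
        dup_coords[[length(dup_coords) + 1L]] <- list(
          species = s, gene_index = g,
          codes = mutate_codes(gene_seq, config$dup_divergence),
          chrom = p$chrom, strand = p$strand, seg_lens = seg_lens)
      }
    }
    # append queued duplicates for this species
    for (d in dup_coords) {
      if (d$species != s) next
      chrom_codes[[d$chrom]] <- c(chrom_codes[[d$chrom]], spacer())
      dstart <- length(chrom_codes[[d$chrom]])
      chrom_codes[[d$chrom]] <- c(chrom_codes[[d$chrom]], d$codes)
      dup_coords[[which(map_lgl(dup_coords, function(x) {
        x$species == s && x$gene_index == d$gene_index
      }))]]$gstart <- dstart
    }
    genomes[[s]] <- tibble(
      id = names(chrom_codes),
      sequence = map_chr(chrom_codes, codes_to_string))
    models[[s]] <- list_rbind(exon_rows)
    truth[[s]] <- list_rbind(intron_rows)
  }
  gene_models <- list_rbind(models)
  truth_introns <- list_rbind(truth)

  # --- orthology tables ----------------------------------------------------
  gid_of <- function(s) paste0(s, "_g", sprintf("%04d", seq_len(config$n_genes)))
  orthology <- list(
    orthology_table(sp[1], sp[2], gid_of(sp[1]), gid_of(sp[2])),
    orthology_table(sp[1], sp[3], gid_of(sp[1]), gid_of(sp[3])),
    orthology_table(sp[1], sp[4], gid_of(sp[1]), gid_of(sp[4])),
    orthology_table(sp[4], sp[5], gid_of(sp[4]), gid_of(sp[5]))
  )

  # --- hit tables (the generator knows every copy) -------------------------
  dup_idx <- map_int(dup_coords, "gene_index")
  dup_sp <- map_chr(dup_coords, "species")
  for (s in sp) {
    ex <- models[[s]]
    for (g in seq_len(config$n_genes)) {
      p <- plan[[g]]
      gid_ref <- paste0(ref, "_g", sprintf("%04d", g))
      gid <- paste0(s, "_g", sprintf("%04d", g))
      gex <- ex[ex$gene_id == gid, ]
      gex <- gex[order(gex$exon_rank), ]
      for (ii in seq_len(k_int)) {
        for (side in c("up", "down")) {
          e_rank <- if (side == "up") ii else ii + 1L
          erow <- gex[gex$exon_rank == e_rank, ]
          qid <- paste0(gid_ref, ".intron", ii, "|", side)
          elen <- erow$end - erow$start
          mkhit <- function(sstart, send, pid, ev) tibble(
            species = s, query_id = qid, subject_id = erow$chromosome,
            percent_identity = pid, alignment_length = as.integer(elen),
            mismatches = as.integer(round(elen * (1 - pid / 100))),
            gap_opens = 0L, query_start = 1L, query_end = as.integer(elen),
            subject_start = as.integer(sstart), subject_end = as.integer(send),
            evalue = ev, bit_score = round(2 * elen * pid / 100, 1))
          self <- if (erow$strand == "+") {
            mkhit(erow$start + 1L, erow$end, 100, 1e-180)
          } else {
            mkhit(erow$end, erow$start + 1L, 100, 1e-180)
          }
          hits[[length(hits) + 1L]] <- self
          if (p$class == "duplicated") {
            d <- dup_coords[[which(dup_idx == g & dup_sp == s)]]
            ends <- cumsum(d$seg_lens); starts <- ends - d$seg_lens
            x <- 2L * e_rank - 1L       # segment index of this exon
            if (d$strand == "+") {
              ds <- d$gstart + starts[x]; de <- d$gstart + ends[x]
              hits[[length(hits) + 1L]] <- mkhit(ds + 1L, de, 90, 1e-50)
            } else {
              Ld <- sum(d$seg_lens)
              ds <- d$gstart + Ld - ends[x]; de <- d$gstart + Ld - starts[x]
              hits[[length(hits) + 1L]] <- mkhit(de, ds + 1L, 90, 1e-50)
            }
          }
          if (stats::runif(1) < config$decoy_hit_prob) {
            pos <- sample.int(1000L, 1)
            hits[[length(hits) + 1L]] <- mkhit(pos, pos + elen - 1L, 70, 5e-3)
          }
        }
      }
    }
  }
  hits <- list_rbind(hits)

  # --- reference-species SNPs ----------------------------------------------
  ref_introns <- truth[[ref]]
  for (i in seq_len(nrow(ref_introns))) {
    lam <- config$snp_mean_density * ref_introns$length[i]
    k <- stats::rpois(1, lam)
    if (k > 0L) {
      snps[[length(snps) + 1L]] <- tibble(
        chromosome = ref_introns$chromosome[i],
        position = ref_introns$start[i] +
          sort(sample.int(ref_introns$length[i], min(k, ref_introns$length[i]))) - 1L)
    }
  }
  snps <- if (length(snps) > 0L) list_rbind(snps) else
    tibble(chromosome = character(), position = integer())

  # --- ground-truth labels --------------------------------------------------
  labels <- tibble(
    set_id = paste0(rep(gid_of(ref), each = k_int), ".intron",
                    rep(seq_len(k_int), config$n_genes)),
    class = rep(gene_class, each = k_int)
  ) |>
    mutate(expected_stage = unname(CLASS_STAGE[.data$class]))

  sim <- list(genomes = genomes, gene_models = gene_models,
              orthology = orthology, hits = hits, snps = snps,
              labels = labels, truth_introns = truth_introns,
              config = config)
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- sim$config$species
  for (s in sp) {
    write_genome_fasta(sim$genomes[[s]], file.path(dir, paste0(s, ".fa")))
    write_gene_models_gff3(sim$gene_models[sim$gene_models$species == s, ],
                           file.path(dir, paste0(s, ".gff3")))
    h <- sim$hits[sim$hits$species == s, ]
    write_blast_hits(h, file.path(dir, paste0("hits_", s, ".tsv")))
  }
  for (ot in sim$orthology) {
    f <- file.path(dir, paste0("orthology_", ot$species_a[1], "_",
                               ot$species_b[1], ".tsv"))
    df <- setNames(data.frame(ot$gene_a, ot$gene_b),
                   c(ot$species_a[1], ot$species_b[1]))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_plain(sim$snps, file.path(dir, paste0("snps_", sp[1], ".tsv")))
  write_tsv_plain(sim$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}
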