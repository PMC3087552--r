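#' Count SNPs per intron and scale by length
#'
#' A SNP is counted when it lies on the intron's chromosome with
#' `start <= position < end` (0-based half-open, so a SNP exactly at `end`
#' is outside).
#'
#' @param introns Intron tibble (needs `chromosome`, `start`, `end`,
#'   `length`).
#' @param snps SNP tibble from [read_snp_table()].
#' @return `introns` with added columns `snp_count` and `snp_density`
#'   (count / length).
#' @export
snp_density <- function(introns, snps) {
  counts <- map_int(seq_len(nrow(introns)), function(i) {
    sum(snps$chromosome == introns$chromosome[i] &
          snps$position >= introns$start[i] &
          snps$position < introns$end[i])
  })
  introns |>
    mutate(snp_count = counts, snp_density = counts / .data$length)
}

# TRUE iff motif is primitive (not itself a repetition of a shorter motif)
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect exact tandem microsatellites
#'
#' Finds all maximal exact tandem tracts with a primitive motif of 1-6 nt,
#' at least `min_copies` full copies and a (full-copy) tract of at least
#' `min_tract` nt. Overlapping reports are collapsed to the tract with the
#' longest span, ties resolved in favour of the shortest motif. N positions
#' never participate in a tract.
#'
#' @param sequence A nucleotide string over A, C, G, T, N.
#' @param min_copies Minimum number of complete motif copies.
#' @param min_tract Minimum tract length in nt (counting complete copies).
#' @return A tibble with columns `motif`, `copies`, `start`, `end`
#'   (0-based half-open within the sequence; `end - start == copies *
#'   nchar(motif)`).
#' @export
find_microsatellites <- function(sequence, min_copies = 3L, min_tract = 8L) {
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(v)
  cand <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    eq <- v[seq_len(n - k)] == v[seq_len(n - k) + k] &
      v[seq_len(n - k)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      run_start <- starts[ri]           # first position with s[i] == s[i+k]
      run_len <- r$lengths[ri]
      tract_len <- run_len + k          # full periodic stretch
      copies <- tract_len %/% k
      if (copies < min_copies) next
      if (copies * k < min_tract) next
      motif <- paste(v[run_start:(run_start + k - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      cand[[length(cand) + 1L]] <- tibble(
        motif = motif, copies = copies,
        start = run_start - 1L,
        end = run_start - 1L + copies * k)
    }
  }
  if (length(cand) == 0L) {
    return(tibble(motif = character(), copies = integer(),
                  start = integer(), end = integer()))
  }
  hits <- list_rbind(cand) |>
    mutate(span = .data$end - .data$start) |>
    arrange(desc(.data$span), nchar(.data$motif), .data$start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(hits$start[i] < hits$end[prior] &
              hits$end[i] > hits$start[prior])) {
      keep[i] <- FALSE
    }
  }
  hits[keep, ] |>
    select(-"span") |>
    arrange(.data$start)
}

#' Repeat content of an intron
#'
#' @param intron One intron row (needs `chromosome`, `start`, `end`,
#'   `length`).
#' @param repeats Repeat tibble from [read_repeatmasker()].
#' @return A list with `fraction_masked` (union coverage of the intron by
#'   annotations, in \[0, 1\]) and `classes` (character vector of repeat
#'   classes overlapping the intron).
#' @export
repeat_content <- function(intron, repeats) {
  ov <- repeats |>
    filter(.data$chromosome == intron$chromosome,
           .data$end > intron$start, .data$start < intron$end)
  if (nrow(ov) == 0L) {
    return(list(fraction_masked = 0, classes = character()))
  }
  ir <- IRanges::IRanges(start = pmax(ov$start, intron$start) + 1L,
                         end = pmin(ov$end, intron$end))
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  list(fraction_masked = covered / (intron$end - intron$start),
       classes = sort(unique(ov$repeat_class)))
}

#' Genetic distance between one species pair for a single intron
#'
#' Aligns the two unaligned intron sequences globally (no column filtering,
#' matching how within-pair divergences are estimated from fresh pairwise
#' alignments) and returns the GTR ML distance.
#'
#' @param seq_a,seq_b Unaligned nucleotide strings.
#' @param params [gtr_params()] object.
#' @return Distance in substitutions per site; `NA` with a warning when the
#'   pair is saturated.
#' @export
species_pair_divergence <- function(seq_a, seq_b, params = gtr_params()) {
  aln <- pairwise_global_align(seq_a, seq_b)
  tryCatch(
    gtr_ml_distance(aln$sequence[1], aln$sequence[2], params),
    error = function(e) {
      warn(paste0("pair divergence unavailable: ", conditionMessage(e)))
      NA_real_
    })
}

IUPAC_FROM_BASES <- local({
  codes <- Biostrings::IUPAC_CODE_MAP
  inv <- names(codes)
  names(inv) <- vapply(codes, function(b) {
    paste(sort(strsplit(b, "")[[1]]), collapse = "")
  }, character(1))
  inv
})

iupac_consensus <- function(cols) {
  # cols: character matrix (rows = taxa) restricted to the window
  apply(cols, 2, function(col) {
    obs <- sort(unique(col[col %in% BASES]))
    if (length(obs) == 0L) return("N")
    IUPAC_FROM_BASES[[paste(obs, collapse = "")]]
  })
}

#' Suggest degenerate PCR primers from a flanking-exon alignment
#'
#' Slides windows of `window_min` to `window_max` columns over the exon
#' alignment (in transcription orientation), takes the per-column IUPAC
#' consensus of the observed bases, and keeps windows whose fold-degeneracy
#' (the product of per-position ambiguity counts) does not exceed
#' `max_degeneracy`. Windows containing alignment gaps are skipped.
#' Candidates are ranked by conservation of the 3'-terminal 5 nt (number of
#' unambiguous positions, descending), then degeneracy (ascending), then
#' proximity of the 3' end to the intron boundary. For the forward side the
#' intron lies to the right of the (upstream) exon; for the reverse side it
#' lies to the left of the (downstream) exon, and the returned primer is the
#' reverse complement of the window consensus.
#'
#' @param exon_aln Alignment tibble of the flanking exon.
#' @param side `"forward"` or `"reverse"`.
#' @param window_min,window_max Primer length bounds (nt).
#' @param max_degeneracy Maximum fold-degeneracy per primer.
#' @param n_best Number of top-ranked suggestions to return.
#' @return A tibble with columns `side`, `sequence`, `degeneracy`,
#'   `window_start`, `window_end` (0-based half-open alignment columns),
#'   `conservation_3p` (0-5) and `dist_to_intron` (nt between the 3' end
#'   and the intron boundary). Empty (with a warning) when no window meets
#'   the degeneracy cap.
#' @export
suggest_degenerate_primers <- function(exon_aln, side = c("forward", "reverse"),
                                       window_min = 20L, window_max = 27L,
                                       max_degeneracy = 48L, n_best = 5L) {
  side <- match.arg(side)
  m <- alignment_matrix(exon_aln)
  L <- ncol(m)
  cons <- iupac_consensus(m)
  has_gap <- apply(m, 2, function(col) any(col == "-"))
  deg <- vapply(cons, function(code) {
    nchar(Biostrings::IUPAC_CODE_MAP[[code]])
  }, numeric(1))
  out <- list()
  for (w in seq(window_min, min(window_max, L))) {
    for (s in seq_len(L - w + 1L)) {
      e <- s + w - 1L
      if (any(has_gap[s:e])) next
      d <- prod(deg[s:e])
      if (d > max_degeneracy) next
      if (side == "forward") {
        three_prime <- (e - 4L):e
        dist <- L - e
        primer <- paste(cons[s:e], collapse = "")
      } else {
        three_prime <- s:(s + 4L)
        dist <- s - 1L
        primer <- revcomp(paste(cons[s:e], collapse = ""))
      }
      out[[length(out) + 1L]] <- tibble(
        side = side, sequence = primer, degeneracy = d,
        window_start = s - 1L, window_end = e,
        conservation_3p = sum(deg[three_prime] == 1),
        dist_to_intron = dist)
    }
  }
  if (length(out) == 0L) {
    warn("no primer window satisfies the degeneracy cap")
    return(tibble(side = character(), sequence = character(),
                  degeneracy = numeric(), window_start = integer(),
                  window_end = integer(), conservation_3p = integer(),
                  dist_to_intron = integer()))
  }
  list_rbind(out) |>
    arrange(desc(.data$conservation_3p), .data$degeneracy,
            .data$dist_to_intron, .data$window_start) |>
    head(n_best)
}
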