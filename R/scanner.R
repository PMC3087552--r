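#' Naive seed-and-extend homology scanner
#'
#' A self-contained substitute for an external search engine when testing
#' the single-copy filter: exact k-mer seeds (both strands) are located with
#' [Biostrings::matchPattern()] and extended ungapped along the diagonal;
#' diagonals reaching at least `min_identity` over the full query are
#' reported as hits. E-values are nominal (a fixed small value for every
#' reported hit) and must not be interpreted as search-engine statistics.
#'
#' @param queries Tibble with columns `query_id` and `sequence`.
#' @param genome Genome tibble from [read_genome_fasta()].
#' @param word_size Exact seed length.
#' @param min_identity Minimum identity of the full-query diagonal
#'   alignment for a hit to be reported.
#' @param stride Distance between successive seed start positions.
#' @return A hit tibble in the layout of [read_blast_hits()].
#' @export
scan_genome_hits <- function(queries, genome, word_size = 16L,
                             min_identity = 0.8, stride = 8L) {
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qid <- queries$query_id[qi]
    qseq <- queries$sequence[qi]
    qlen <- nchar(qseq)
    if (qlen < word_size) next
    starts <- unique(c(seq(1L, qlen - word_size + 1L, by = stride),
                       qlen - word_size + 1L))
    for (gi in seq_len(nrow(genome))) {
      subj <- genome$sequence[gi]
      subj_dna <- Biostrings::DNAString(subj)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") qseq else revcomp(qseq)
        qvec <- strsplit(q, "", fixed = TRUE)[[1]]
        diags <- integer()
        for (s in starts) {
          seed <- substr(q, s, s + word_size - 1L)
          if (grepl("N", seed, fixed = TRUE)) next
          m <- Biostrings::matchPattern(seed, subj_dna)
          if (length(m) > 0L) {
            diags <- c(diags, Biostrings::start(m) - s)
          }
        }
        for (d in unique(diags)) {
          s_start <- d + 1L            # subject pos aligned to query pos 1
          s_end <- d + qlen
          q_from <- max(1L, 1L - d + 1L)
          if (s_start < 1L) { q_from <- 2L - s_start; s_start <- 1L }
          q_to <- qlen
          if (s_end > nchar(subj)) { q_to <- qlen - (s_end - nchar(subj)); s_end <- nchar(subj) }
          if (q_to <= q_from) next
          svec <- strsplit(substr(subj, s_start, s_end), "", fixed = TRUE)[[1]]
          matches <- sum(qvec[q_from:q_to] == svec)
          alen <- q_to - q_from + 1L
          ident <- matches / alen
          if (ident >= min_identity) {
            qs <- if (strand == "+") q_from else qlen - q_to + 1L
            qe <- if (strand == "+") q_to else qlen - q_from + 1L
            out[[length(out) + 1L]] <- tibble(
              query_id = qid, subject_id = genome$id[gi],
              percent_identity = 100 * ident, alignment_length = alen,
              mismatches = alen - matches, gap_opens = 0L,
              query_start = qs, query_end = qe,
              subject_start = if (strand == "+") s_start else s_end,
              subject_end = if (strand == "+") s_end else s_start,
              evalue = 1e-30, bit_score = 2 * matches)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(read_blast_hits(tempfile_empty()))
  }
  hits <- list_rbind(out)
  # collapse duplicate reports of the same locus (overlapping diagonals)
  hits |>
    mutate(lo = pmin(.data$subject_start, .data$subject_end),
           hi = pmax(.data$subject_start, .data$subject_end)) |>
    group_by(.data$query_id, .data$subject_id) |>
    arrange(desc(.data$percent_identity), .by_group = TRUE) |>
    group_modify(function(rows, key) {
      keep <- rep(TRUE, nrow(rows))
      for (i in seq_len(nrow(rows))[-1]) {
        prior <- which(keep[seq_len(i - 1L)])
        if (any(rows$lo[i] <= rows$hi[prior] & rows$hi[i] >= rows$lo[prior])) {
          keep[i] <- FALSE
        }
      }
      rows[keep, ]
    }) |>
    ungroup() |>
    select(-"lo", -"hi") |>
    arrange(.data$query_id, .data$subject_id, .data$subject_start)
}

tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
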