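#' Construct a multiple alignment object
#'
#' An alignment is a tibble with columns `taxon` and `sequence`; all rows
#' must have equal length and unique taxa. Characters are drawn from
#' A, C, G, T, N and `-`.
#'
#' @param taxa Character vector of taxon names.
#' @param sequences Character vector of aligned rows.
#' @return An alignment tibble.
#' @export
new_alignment <- function(taxa, sequences) {
  if (length(taxa) != length(sequences)) abort("taxa/sequences length mismatch")
  if (anyDuplicated(taxa)) abort("duplicated taxa in alignment")
  if (length(unique(nchar(sequences))) > 1L) {
    abort("alignment rows differ in length")
  }
  tibble(taxon = as.character(taxa), sequence = toupper(sequences))
}

alignment_length <- function(aln) {
  if (nrow(aln) == 0L) 0L else nchar(aln$sequence[1])
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
}

#' Remove poorly aligned alignment columns
#'
#' A two-parameter surrogate for block-based alignment cleaning: columns
#' whose gap fraction exceeds `max_gap_fraction` are removed, and remaining
#' runs of consecutive kept columns shorter than `min_block_len` are removed
#' too. Row order is preserved.
#'
#' @param aln Alignment tibble (at least 2 rows).
#' @param max_gap_fraction Columns with a gap fraction strictly above this
#'   are dropped.
#' @param min_block_len Minimum run length (in original column coordinates)
#'   of kept columns.
#' @return The filtered alignment; if every column is removed, a zero-length
#'   alignment with attribute `emptied = TRUE` (with a warning).
#' @export
filter_alignment_columns <- function(aln, max_gap_fraction = 0.5,
                                     min_block_len = 5L) {
  if (nrow(aln) < 2L) abort("alignment needs at least 2 rows")
  m <- alignment_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block_len] <- FALSE
  keep <- inverse.rle(r)
  out <- new_alignment(aln$taxon,
                       apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
  if (alignment_length(out) == 0L) {
    warn("alignment emptied entirely by column filtering")
    attr(out, "emptied") <- TRUE
  }
  out
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under a linear gap penalty, computed
#' with [Biostrings::pairwiseAlignment()].
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param match,mismatch,gap Scores (gap is the per-position penalty,
#'   negative).
#' @return A two-row alignment tibble with taxa `"a"` and `"b"` and a
#'   `score` attribute.
#' @export
pairwise_global_align <- function(seq_a, seq_b, match = 1, mismatch = -1,
                                  gap = -2) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    pad_a <- paste0(seq_a, strrep("-", nchar(seq_b)))
    pad_b <- paste0(strrep("-", nchar(seq_a)), seq_b)
    out <- new_alignment(c("a", "b"), c(pad_a, pad_b))
    attr(out, "score") <- gap * (nchar(seq_a) + nchar(seq_b))
    return(out)
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = -gap)
  out <- new_alignment(
    c("a", "b"),
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa))))
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Align the members of an orthologous intron set
#'
#' When all member sequences have equal length (the substitution-only case)
#' the rows are stacked directly. Otherwise a centre-star multiple alignment
#' is built from pairwise global alignments of every member against the
#' centre (the first taxon, by convention the reference species when the
#' caller orders taxa that way).
#'
#' @param taxa Character vector of taxon names.
#' @param sequences Character vector of unaligned nucleotide strings.
#' @return An alignment tibble.
#' @export
align_sequences <- function(taxa, sequences) {
  if (length(unique(nchar(sequences))) == 1L) {
    return(new_alignment(taxa, sequences))
  }
  centre <- sequences[1]
  n <- length(sequences)
  # per-pairwise gap patterns: insertions into the centre, keyed by the
  # number of gap columns after each centre position (index 0 = before)
  ins <- matrix(0L, nrow = n, ncol = nchar(centre) + 1L)
  rows_aln <- vector("list", n)
  rows_aln[[1]] <- centre
  for (i in seq_len(n)[-1]) {
    pa <- pairwise_global_align(centre, sequences[i])
    ca <- strsplit(pa$sequence[1], "", fixed = TRUE)[[1]]
    oa <- strsplit(pa$sequence[2], "", fixed = TRUE)[[1]]
    pos <- cumsum(ca != "-")      # centre position at/before each column
    gaps_after <- tabulate(pos[ca == "-"] + 1L, nbins = nchar(centre) + 1L)
    ins[i, ] <- gaps_after
    rows_aln[[i]] <- list(ca = ca, oa = oa, pos = pos)
  }
  master_ins <- apply(ins, 2, max)
  expand_centre <- function() {
    cvec <- strsplit(centre, "", fixed = TRUE)[[1]]
    parts <- character(0)
    for (p in 0:length(cvec)) {
      parts <- c(parts, strrep("-", master_ins[p + 1L]),
                 if (p < length(cvec)) cvec[p + 1L] else character(0))
    }
    paste(parts, collapse = "")
  }
  expand_other <- function(i) {
    ca <- rows_aln[[i]]$ca; oa <- rows_aln[[i]]$oa; pos <- rows_aln[[i]]$pos
    out <- character(0)
    col <- 1L
    for (p in 0:nchar(centre)) {
      have <- ins[i, p + 1L]
      chunk <- character(0)
      while (have > 0L && col <= length(ca) && ca[col] == "-") {
        chunk <- c(chunk, oa[col]); col <- col + 1L; have <- have - 1L
      }
      chunk <- c(chunk, rep("-", master_ins[p + 1L] - ins[i, p + 1L]))
      out <- c(out, chunk)
      if (p < nchar(centre)) {
        # the centre base column
        out <- c(out, oa[col]); col <- col + 1L
      }
    }
    paste(out, collapse = "")
  }
  aligned <- c(expand_centre(),
               vapply(seq_len(n)[-1], expand_other, character(1)))
  new_alignment(taxa, aligned)
}

#' Concatenate alignments row-wise over a shared taxon set
#'
#' @param alignments Non-empty list of alignment tibbles with identical
#'   taxon sets.
#' @return One alignment whose length is the sum of the input lengths.
#' @export
concat_alignments <- function(alignments) {
  if (length(alignments) == 0L) abort("no alignments to concatenate")
  taxa <- sort(alignments[[1]]$taxon)
  rows <- map(alignments, function(a) {
    if (!setequal(a$taxon, taxa)) {
      abort("taxon missing from one alignment block")
    }
    setNames(a$sequence, a$taxon)[taxa]
  })
  seqs <- do.call(paste0, rows)
  new_alignment(taxa, seqs)
}
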