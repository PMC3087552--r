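#' Read a genome (or any nucleotide) FASTA file
#'
#' Sequences are uppercased on input. Records must be non-empty and ids
#' (first whitespace-delimited token of the header) unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    abort(paste0("empty sequence for record '", ids[which(widths == 0L)[1]],
                 "' in ", path))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated FASTA id '", ids[anyDuplicated(ids)], "' in ", path))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in record '", ids[which(bad)[1]], "'"))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `sequence` (as from
#'   [read_genome_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "query_start", "query_end", "subject_start", "subject_end",
                 "evalue", "bit_score")

#' Read a homology-search hit table (BLAST tabular, outfmt 6)
#'
#' Twelve tab-separated columns in the standard `-outfmt 6` order. Rows are
#' returned in file order so hits stay grouped per query.
#'
#' @param path Path to the tabular hit file.
#' @return A tibble with columns `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `mismatches`, `gap_opens`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `evalue`, `bit_score`.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("hit table not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(as_tibble(setNames(
      c(list(character(), character()), replicate(10, numeric(), simplify = FALSE)),
      BLAST6_COLS)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    abort(sprintf("line %d of %s has %d fields; expected 12 (outfmt 6)",
                  which(nf != 12L)[1], path, nf[nf != 12L][1]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12])
  )
  if (anyNA(out$evalue) || any(out$evalue < 0)) {
    abort(paste0("invalid e-value in ", path))
  }
  out
}

#' Write a hit table in BLAST outfmt 6 layout
#'
#' @param hits A tibble as returned by [read_blast_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  df <- as.data.frame(hits[, BLAST6_COLS])
  df$evalue <- sprintf("%.3g", df$evalue)
  df$percent_identity <- sprintf("%.2f", df$percent_identity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read RepeatMasker annotations (.out format)
#'
#' Coordinates are converted from RepeatMasker's 1-based inclusive convention
#' to 0-based half-open. Repeat classes are collapsed to SINE, LINE, LTR,
#' DNA or other.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A tibble with columns `chromosome`, `start`, `end`, `repeat_class`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) abort(paste0("RepeatMasker file not found: ", path))
  lines <- readLines(path)
  # skip the two header lines + blank line if present
  body <- lines[!grepl("^\\s*$", lines)]
  body <- body[!grepl("^\\s*(SW|score)", body)]
  if (length(body) == 0L) {
    return(tibble(chromosome = character(), start = integer(),
                  end = integer(), repeat_class = character()))
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    abort(sprintf("truncated RepeatMasker line %d in %s",
                  which(nf < 11L)[1], path))
  }
  chrom <- map_chr(fields, 5)
  begin <- as.integer(map_chr(fields, 6))
  end <- as.integer(map_chr(fields, 7))
  if (anyNA(begin) || anyNA(end) || any(end < begin)) {
    abort(paste0("invalid repeat coordinates in ", path))
  }
  cls <- map_chr(fields, 11)
  cls <- sub("/.*$", "", cls)
  cls[!cls %in% c("SINE", "LINE", "LTR", "DNA")] <- "other"
  tibble(chromosome = chrom, start = begin - 1L, end = end,
         repeat_class = cls)
}

#' Read a SNP position table
#'
#' A two-column TSV (`chromosome`, `position`) with a header line; positions
#' are 0-based.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chromosome` and `position`.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chromosome", "position") %in% names(df))) {
    abort(paste0("SNP table ", path, " must have columns chromosome, position"))
  }
  tibble(chromosome = as.character(df$chromosome),
         position = as.integer(df$position))
}

#' Read Tandem Repeats Finder output (.dat format)
#'
#' Minimal reader for the per-repeat data lines of TRF's `.dat` output,
#' for users who prefer TRF's approximate-copy model over the exact-tandem
#' detector in [find_microsatellites()].
#'
#' @param path Path to a TRF `.dat` file.
#' @return A tibble with columns `sequence_id`, `start`, `end` (0-based
#'   half-open), `motif`, `copies`.
#' @export
read_trf_dat <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NA_character_
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      current <- sub("^Sequence:\\s*", "", ln)
      current <- sub("\\s.*$", "", current)
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) >= 14 && !is.na(suppressWarnings(as.integer(f[1])))) {
      out[[length(out) + 1L]] <- tibble(
        sequence_id = current,
        start = as.integer(f[1]) - 1L, end = as.integer(f[2]),
        motif = f[14], copies = as.numeric(f[4]))
    }
  }
  if (length(out) == 0L) {
    return(tibble(sequence_id = character(), start = integer(),
                  end = integer(), motif = character(), copies = numeric()))
  }
  list_rbind(out)
}
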