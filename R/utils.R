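# Internal sequence and coordinate helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Reverse complement of a character vector of DNA strings (A,C,G,T,N + IUPAC).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer encoding A=1, C=2, G=3, T=4; anything else (N, gap) -> NA.
encode_dna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES)
  m
}

# 4x4 site-pattern count matrix for two aligned rows; columns where either
# row is a gap/N are excluded.
pair_count_matrix <- function(seq_a, seq_b) {
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  if (length(a) != length(b)) {
    abort("aligned rows differ in length")
  }
  ok <- !is.na(a) & !is.na(b)
  n <- tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L)
  matrix(n, nrow = 4, byrow = TRUE, dimnames = list(BASES, BASES))
}

# Fraction of N characters in a sequence.
n_fraction <- function(seq) {
  nc <- nchar(seq)
  ifelse(nc == 0L, 0, stringr::str_count(seq, "N") / nc)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %g", name, min))
  }
}

# Deterministic formatting used by all table writers so that reruns are
# byte-identical: plain %.10g, no scientific notation surprises from locale.
format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
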