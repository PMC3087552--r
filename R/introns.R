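#' Extract introns and flanking exons from an annotated genome
#'
#' For a gene with k exons, the k-1 introns are returned with `intron_index`
#' 1..k-1 in transcription order. Intron (and flanking-exon) sequences are
#' stored in transcription orientation, i.e. reverse-complemented for genes
#' on the minus strand. Introns longer than `max_len` are omitted; their
#' number is recorded in the `n_over_cap` attribute of the result.
#'
#' Introns whose sequence is more than half N are flagged (`high_n = TRUE`)
#' so that alignment stages can skip them.
#'
#' @param genome Genome tibble from [read_genome_fasta()].
#' @param genes Exon-level gene-model tibble from [read_gene_models()].
#' @param max_len Extraction cap in nucleotides (default 50000): introns
#'   longer than this are discarded outright.
#' @return A tibble with one row per intron: `gene_id`, `species`,
#'   `intron_index`, `chromosome`, `strand`, `start`, `end` (0-based
#'   half-open genomic), `length`, `sequence`, `upstream_exon_len`,
#'   `downstream_exon_len`, `upstream_exon_seq`, `downstream_exon_seq`,
#'   `high_n`.
#' @export
extract_introns <- function(genome, genes, max_len = 50000L) {
  stopifnot_scalar_number(max_len, "max_len", min = 1)
  missing_chr <- setdiff(unique(genes$chromosome), genome$id)
  if (length(missing_chr) > 0L) {
    abort(paste0("chromosome '", missing_chr[1], "' not present in genome"))
  }
  chrom_seq <- setNames(genome$sequence, genome$id)
  chrom_len <- setNames(nchar(genome$sequence), genome$id)
  bad <- genes$end > chrom_len[genes$chromosome]
  if (any(bad)) {
    abort(paste0("exon of gene ", genes$gene_id[bad][1],
                 " extends beyond the end of ", genes$chromosome[bad][1]))
  }

  # introns between consecutive exons in transcription order
  g <- genes |>
    arrange(.data$gene_id, .data$exon_rank) |>
    group_by(.data$gene_id) |>
    filter(n() >= 2L) |>
    mutate(
      next_start = lead(.data$start), next_end = lead(.data$end)
    ) |>
    ungroup() |>
    filter(!is.na(.data$next_start)) |>
    mutate(
      intron_index = .data$exon_rank,
      istart = ifelse(.data$strand == "+", .data$end, .data$next_end),
      iend = ifelse(.data$strand == "+", .data$next_start, .data$start),
      up_start = .data$start, up_end = .data$end,
      down_start = .data$next_start, down_end = .data$next_end
    )
  if (any(g$iend <= g$istart)) {
    abort(paste0("zero- or negative-length intron in gene ",
                 g$gene_id[g$iend <= g$istart][1],
                 " (abutting or mis-sorted exons)"))
  }
  n_over <- sum(g$iend - g$istart > max_len)
  g <- g[g$iend - g$istart <= max_len, , drop = FALSE]

  fetch <- function(chrom, s, e) {
    substring(chrom_seq[chrom], s + 1L, e)
  }
  iseq <- fetch(g$chromosome, g$istart, g$iend)
  upseq <- fetch(g$chromosome, g$up_start, g$up_end)
  downseq <- fetch(g$chromosome, g$down_start, g$down_end)
  minus <- g$strand == "-"
  if (any(minus)) {
    iseq[minus] <- revcomp(iseq[minus])
    upseq[minus] <- revcomp(upseq[minus])
    downseq[minus] <- revcomp(downseq[minus])
  }

  out <- tibble(
    gene_id = g$gene_id,
    species = g$species,
    intron_index = g$intron_index,
    chromosome = g$chromosome,
    strand = g$strand,
    start = as.integer(g$istart),
    end = as.integer(g$iend),
    length = as.integer(g$iend - g$istart),
    sequence = unname(iseq),
    upstream_exon_len = as.integer(g$up_end - g$up_start),
    downstream_exon_len = as.integer(g$down_end - g$down_start),
    upstream_exon_seq = unname(upseq),
    downstream_exon_seq = unname(downseq),
    high_n = n_fraction(iseq) > 0.5
  )
  attr(out, "n_over_cap") <- n_over
  out
}
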