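#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`/`mRNA`/`exon` (and `CDS`) features and returns one gene
#' model per gene, using a single canonical transcript: the transcript with
#' the longest total CDS (ties broken by the lexicographically smallest
#' transcript id). GFF3 1-based inclusive coordinates are converted to
#' 0-based half-open. Exons are returned in transcription order, i.e. in
#' descending chromosome coordinate for minus-strand genes.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label attached to every returned row.
#' @return A tibble with one row per exon: `species`, `gene_id`,
#'   `transcript_id`, `chromosome`, `strand`, `exon_rank` (1-based, in
#'   transcription order), `start`, `end` (0-based half-open) and
#'   `description`.
#' @export
read_gene_models <- function(path, species) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("malformed GFF3 in ", path, ": ",
                                     conditionMessage(e)))
  )
  df <- tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start1 = GenomicRanges::start(gr),
    end1 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = map_chr(as.list(gr$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[[1]])
    })
  )
  if (!is.null(gr$description)) {
    df$description <- as.character(gr$description)
  } else {
    df$description <- NA_character_
  }

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]
  if (nrow(exons) == 0L) abort(paste0("no exon features in ", path))
  if (anyNA(exons$parent)) {
    abort(paste0("exon without Parent attribute in ", path))
  }
  orphan <- setdiff(exons$parent, mrnas$id)
  if (length(orphan) > 0L) {
    abort(paste0("exon parented to unknown transcript '", orphan[1],
                 "' in ", path))
  }

  # canonical transcript per gene: longest total CDS, ties -> smallest id
  cds_len <- cds |>
    group_by(transcript_id = .data$parent) |>
    summarise(cds_total = sum(.data$end1 - .data$start1 + 1L), .groups = "drop")
  canon <- mrnas |>
    transmute(transcript_id = .data$id, gene_id = .data$parent) |>
    left_join(cds_len, by = "transcript_id") |>
    mutate(cds_total = ifelse(is.na(.data$cds_total), 0L, .data$cds_total)) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$cds_total), .data$transcript_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()

  gene_desc <- genes |>
    transmute(gene_id = .data$id,
              description = ifelse(is.na(.data$description), "",
                                   .data$description))

  out <- exons |>
    transmute(transcript_id = .data$parent, chromosome = .data$chromosome,
              strand = .data$strand,
              start = .data$start1 - 1L, end = .data$end1) |>
    inner_join(canon, by = "transcript_id") |>
    left_join(gene_desc, by = "gene_id") |>
    mutate(species = species,
           description = ifelse(is.na(.data$description), "",
                                .data$description))

  if (any(!out$strand %in% c("+", "-"))) {
    abort("exons must be on + or - strand")
  }

  out <- out |>
    group_by(.data$gene_id) |>
    arrange(ifelse(.data$strand == "+", 1L, -1L) * .data$start,
            .by_group = TRUE) |>
    mutate(exon_rank = row_number()) |>
    ungroup()

  # exons within a gene must not overlap
  overlap_bad <- out |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start[-1] < head(.data$end, -1)),
              .groups = "drop")
  if (any(overlap_bad$bad)) {
    abort(paste0("overlapping exons in gene ",
                 overlap_bad$gene_id[overlap_bad$bad][1]))
  }

  out |>
    select("species", "gene_id", "transcript_id", "chromosome", "strand",
           "exon_rank", "start", "end", "description") |>
    arrange(.data$gene_id, .data$exon_rank)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()] for round-tripping synthetic annotations:
#' emits gene, mRNA, exon and CDS features (CDS identical to exons) with
#' 1-based inclusive coordinates.
#'
#' @param models Exon-level tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- models |>
    group_by(.data$gene_id) |>
    summarise(chromosome = .data$chromosome[1], strand = .data$strand[1],
              transcript_id = .data$transcript_id[1],
              start = min(.data$start), end = max(.data$end),
              description = .data$description[1], .groups = "drop") |>
    arrange(.data$chromosome, .data$start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- models[models$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    desc <- if (nzchar(g$description)) paste0(";description=", g$description) else ""
    writeLines(sprintf("%s\tintronmine\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       g$chromosome, g$start + 1L, g$end, g$strand,
                       g$gene_id, desc), con)
    writeLines(sprintf("%s\tintronmine\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chromosome, g$start + 1L, g$end, g$strand,
                       g$transcript_id, g$gene_id), con)
    for (j in seq_len(nrow(ex))) {
      e <- ex[j, ]
      writeLines(sprintf(
        "%s\tintronmine\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        e$chromosome, e$start + 1L, e$end, e$strand, g$transcript_id,
        j, g$transcript_id), con)
      writeLines(sprintf(
        "%s\tintronmine\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        e$chromosome, e$start + 1L, e$end, e$strand, g$transcript_id,
        j, g$transcript_id), con)
    }
  }
  invisible(path)
}
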