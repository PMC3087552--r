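#' Read a pairwise one-to-one gene-orthology table
#'
#' A two-column TSV whose header names the two species; each row pairs one
#' gene id from each species. One-to-one means each gene id may appear at
#' most once in its column.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `species_a`, `species_b`, `gene_a`,
#'   `gene_b`.
#' @export
read_orthology_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) != 2L) {
    abort(paste0("orthology table ", path, " must have exactly 2 columns"))
  }
  orthology_table(names(df)[1], names(df)[2], df[[1]], df[[2]])
}

#' Construct an orthology table from vectors
#'
#' @param species_a,species_b Species names for the two columns.
#' @param genes_a,genes_b Equal-length character vectors of paired gene ids.
#' @return A tibble with columns `species_a`, `species_b`, `gene_a`,
#'   `gene_b`.
#' @export
orthology_table <- function(species_a, species_b, genes_a, genes_b) {
  if (length(genes_a) != length(genes_b)) {
    abort("gene id vectors must have equal length")
  }
  if (anyDuplicated(genes_a) || anyDuplicated(genes_b)) {
    abort(paste0("orthology table ", species_a, "-", species_b,
                 " is not one-to-one (duplicated gene id)"))
  }
  tibble(species_a = species_a, species_b = species_b,
         gene_a = as.character(genes_a), gene_b = as.character(genes_b))
}

#' Cross pairwise orthology tables into multi-species ortholog groups
#'
#' Joins the pairwise tables over a connected species graph, anchored on one
#' reference species, so that only genes with a one-to-one partner in every
#' species survive. The classic two-stage use is to cross the
#' anchor-vs-each-primate tables, the laurasiatherian pair, and finally the
#' two halves; any connected set of tables gives the same result here.
#'
#' @param tables A list of tibbles from [read_orthology_table()] or
#'   [orthology_table()].
#' @param species Character vector of all study species.
#' @param anchor Anchor (reference) species used to seed the join and to
#'   sort the output.
#' @return A tibble with one row per ortholog group and one column per
#'   species holding that species' gene id, sorted by the anchor gene id.
#' @export
cross_orthology_tables <- function(tables, species, anchor = species[1]) {
  if (!anchor %in% species) abort("`anchor` must be one of `species`")
  pair_species <- map(tables, function(t) c(t$species_a[1], t$species_b[1]))
  known <- unique(unlist(pair_species))
  if (!all(species %in% known)) {
    abort(paste0("species without any orthology table: ",
                 paste(setdiff(species, known), collapse = ", ")))
  }

  # breadth-first join starting from the anchor
  joined <- tibble(.anchor = unique_genes_of(tables, anchor))
  names(joined) <- anchor
  covered <- anchor
  remaining <- seq_along(tables)
  while (length(remaining) > 0L) {
    usable <- remaining[map_lgl(remaining, function(i) {
      any(pair_species[[i]] %in% covered)
    })]
    if (length(usable) == 0L) {
      abort(paste0("orthology tables do not connect species: ",
                   paste(setdiff(species, covered), collapse = ", "),
                   " unreachable from ", anchor))
    }
    i <- usable[1]
    t <- tables[[i]]
    sa <- t$species_a[1]; sb <- t$species_b[1]
    pair <- setNames(tibble(t$gene_a, t$gene_b), c(sa, sb))
    if (sa %in% covered && sb %in% covered) {
      # consistency join: keeps only groups whose pair is listed
      joined <- inner_join(joined, pair, by = c(sa, sb))
    } else if (sa %in% covered) {
      joined <- inner_join(joined, pair, by = sa)
      covered <- c(covered, sb)
    } else {
      joined <- inner_join(joined, pair, by = sb)
      covered <- c(covered, sa)
    }
    remaining <- setdiff(remaining, i)
  }
  missing_cols <- setdiff(species, names(joined))
  if (length(missing_cols) > 0L) {
    abort(paste0("species never joined: ", paste(missing_cols, collapse = ", ")))
  }
  joined |>
    select(all_of(species)) |>
    arrange(.data[[anchor]])
}

unique_genes_of <- function(tables, sp) {
  g <- unlist(map(tables, function(t) {
    if (t$species_a[1] == sp) t$gene_a
    else if (t$species_b[1] == sp) t$gene_b
    else character()
  }))
  sort(unique(g))
}

#' Match introns across an ortholog group into one-to-one intron sets
#'
#' A gene group contributes intron sets only when the (extracted) intron
#' count of the gene is identical in every species; intron i of one species
#' is then matched to intron i of every other, since conserved relative
#' position within the gene is the orthology criterion. Groups whose gene
#' has no extracted intron in some species contribute nothing.
#'
#' @param gene_sets Ortholog-group tibble from [cross_orthology_tables()].
#' @param introns Intron tibble from [extract_introns()], covering all
#'   species (rows bound together).
#' @param anchor Anchor species used to name the sets.
#' @return A tibble in long form: `set_id` (`"<anchor gene>.intron<i>"`),
#'   `intron_index`, `species`, plus all columns of `introns`.
#' @export
match_introns <- function(gene_sets, introns, anchor) {
  species <- names(gene_sets)
  counts <- introns |>
    group_by(.data$species, .data$gene_id) |>
    summarise(n_introns = max(.data$intron_index), n_rows = n(),
              .groups = "drop")

  long <- gene_sets |>
    mutate(.group = row_number()) |>
    pivot_longer(cols = all_of(species), names_to = "species",
                 values_to = "gene_id") |>
    left_join(counts, by = c("species", "gene_id"))

  ok_groups <- long |>
    group_by(.data$.group) |>
    summarise(
      keep = !anyNA(.data$n_introns) &&
        length(unique(.data$n_introns)) == 1L &&
        all(.data$n_rows == .data$n_introns),
      .groups = "drop")
  # n_rows == n_introns guards against gaps left by the extraction cap:
  # a gene whose intron i was discarded in one species cannot be matched.

  kept <- long |>
    inner_join(ok_groups |> filter(.data$keep) |> select(".group"),
               by = ".group")
  if (nrow(kept) == 0L) {
    out <- introns[0, ]
    out$set_id <- character()
    return(out |> select("set_id", everything()))
  }

  anchor_gene <- kept |>
    filter(.data$species == anchor) |>
    select(".group", anchor_gene = "gene_id")

  kept |>
    select(".group", "species", "gene_id") |>
    inner_join(introns, by = c("species", "gene_id"),
               relationship = "one-to-many") |>
    inner_join(anchor_gene, by = ".group") |>
    mutate(set_id = paste0(.data$anchor_gene, ".intron", .data$intron_index)) |>
    select("set_id", "intron_index", "species", everything(),
           -".group", -"anchor_gene") |>
    arrange(.data$set_id, .data$species)
}
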