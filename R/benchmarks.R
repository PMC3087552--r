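#' Published divergence benchmarks for the mammalian intron marker set
#'
#' Human-chimpanzee divergence summaries reported for the original
#' 224-marker screen, used to put new marker sets in context: the mean
#' intron patristic distance of the final marker set, the same quantity for
#' the pre-divergence-filter sets, the cytochrome-b distance measured on the
#' same three-primate tree, the mean flanking-exon divergence, and the mean
#' SNP counts and densities of the final versus the size-constrained intron
#' sets.
#'
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @export
published_benchmarks <- function() {
  tribble(
    ~quantity, ~value, ~unit,
    "mean_intron_hc_distance_final", 0.014, "subs/position",
    "mean_intron_hc_distance_initial", 0.011, "subs/position",
    "cytb_hc_distance", 0.169, "subs/position",
    "mean_exon_hc_distance", 0.006, "subs/position",
    "mean_snp_count_final", 4.35, "SNPs/intron",
    "mean_snp_count_initial", 3.19, "SNPs/intron",
    "snp_density_final", 0.0055, "SNPs/nt",
    "snp_density_initial", 0.0043, "SNPs/nt"
  )
}
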