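#' Bar chart of survivors per pipeline stage
#'
#' Regenerates the filtering-cascade box diagram from the stage counts.
#'
#' @param stage_counts Tibble of `stage`, `survivors` (from a
#'   `marker_pipeline` object).
#' @return A ggplot object.
#' @export
plot_stage_counts <- function(stage_counts) {
  sc <- stage_counts |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot(sc, aes(x = .data$stage, y = .data$survivors)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "surviving intron sets",
         title = "Filter cascade") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of reference-sister divergences of a marker set
#'
#' @param reports Marker report tibble.
#' @param value Column to plot.
#' @param bin_width Bin width (substitutions/position).
#' @return A ggplot object.
#' @export
plot_divergence_histogram <- function(reports, value = "hc_distance",
                                      bin_width = 0.002) {
  ggplot(reports, aes(x = .data[[value]])) +
    geom_histogram(binwidth = bin_width, fill = "grey30",
                   boundary = 0, closed = "left") +
    labs(x = "distance (substitutions/position)", y = "introns") +
    theme_minimal()
}

#' Heatmap of per-marker, per-species-pair divergences
#'
#' @param pair_table Output of [pair_divergence_table()].
#' @return A ggplot object.
#' @export
plot_pair_divergence <- function(pair_table) {
  long <- pair_table |>
    pivot_longer(-"set_id", names_to = "pair", values_to = "distance")
  ggplot(long, aes(x = .data$pair, y = .data$set_id,
                   fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey80") +
    labs(x = "species pair", y = NULL,
         fill = "subs/position") +
    theme_minimal()
}

#' @export
autoplot.marker_pipeline <- function(object, ...) {
  plot_stage_counts(object$stage_counts)
}
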