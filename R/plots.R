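# ggplot2 views of the main result types.

#' Plot a per-species barcoding-gap table
#'
#' Maximum intraspecific against minimum interspecific divergence, one point
#' per species. Points below the identity line have a local barcoding gap;
#' points on or above it overlap.
#'
#' @param object A [gap_table()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gap_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      max_intra = dplyr::coalesce(.data$max_intra, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_intra, y = .data$min_inter,
                                   label = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "maximum intraspecific K2P distance (%)",
      y = "minimum interspecific K2P distance (%)",
      title = "Barcoding gap per species"
    )
}

#' Plot a threshold sweep
#'
#' Number of molecular units against candidate threshold; point size shows
#' the gap score of each candidate partition.
#'
#' @param object A `partition_sweep` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partition_sweep <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$threshold, y = .data$n_units,
                               size = .data$gap_score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::labs(x = "distance threshold (K2P fraction)",
                  y = "molecular taxonomic units", size = "gap score",
                  title = "Single-linkage threshold sweep")
}

#' Histogram of pairwise divergences by rank
#'
#' Overlaid distributions of intraspecific and interspecific (and, when
#' taxonomy is supplied, per-rank) K2P distances — the visual form of the
#' barcoding gap.
#'
#' @param x A `k2p_dist` object.
#' @param taxonomy A tibble with `specimen_id`, `species`, `genus`,
#'   `family`.
#' @param binwidth Histogram bin width in percent (default 0.5).
#' @return A ggplot object.
#' @export
plot_divergence <- function(x, taxonomy, binwidth = 0.5) {
  pairs <- pair_rank_table(x, taxonomy) |>
    dplyr::filter(!is.na(.data$distance), !is.na(.data$rank))
  ggplot2::ggplot(pairs, ggplot2::aes(x = 100 * .data$distance,
                                      fill = .data$rank)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "K2P distance (%)", y = "pairs", fill = NULL,
                  title = "Pairwise divergence by taxonomic rank")
}
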