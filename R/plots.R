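#' Histogram of pairwise distances with the clustering cut-off
#'
#' The distance distribution is what the molecular-group cut-off is judged
#' against: within-cultivar pairs pile up near 0, between-cultivar pairs
#' far above the cut-off.
#'
#' @param object an `ssr_dist`.
#' @param cutoff cut-off to draw (default 0.2).
#' @param binwidth histogram bin width.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ssr_dist
#' @export
autoplot.ssr_dist <- function(object, cutoff = 0.2, binwidth = 0.02, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "pairwise Dice–Sørensen distance",
                  y = "sample pairs",
                  title = "Pairwise distance distribution") +
    ggplot2::theme_minimal()
}

#' Group-size and frequency overview of a curation run
#'
#' @param object an `ssr_curation`.
#' @param ... unused.
#' @return A ggplot: molecular-group sizes, coloured by retraceability.
#' @method autoplot ssr_curation
#' @export
autoplot.ssr_curation <- function(object, ...) {
  tt <- tidy(object)
  tt$group_id <- stats::reorder(tt$group_id, -tt$n_members)
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$group_id, y = .data$n_members,
                                   fill = .data$retraceable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "molecular group", y = "members",
                  fill = "retraceable",
                  title = "Molecular group sizes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Per-position representative-variant frequencies
#'
#' Low frequencies mark markers or groups with high within-group
#' variability, worth manual review.
#'
#' @param frequencies tibble from [frequency_report()].
#' @return A ggplot of per-marker frequency distributions.
#' @export
plot_variant_frequencies <- function(frequencies) {
  ggplot2::ggplot(frequencies,
                  ggplot2::aes(x = .data$marker, y = .data$frequency)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "representative-variant frequency",
                  title = "Within-group frequency of representative alleles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
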