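# ggplot2 views of the main result types. These are thin presentation
# layers over the tidy tables; all numbers come from the tables themselves.

#' Plot niche-split richness or abundance over the time course
#'
#' @param series Output of [niche_series()].
#' @param what `"richness"` or `"rel_abundance"`.
#' @return A ggplot object: one panel per compartment, lines per niche.
#' @export
plot_niche_series <- function(series, what = c("richness", "rel_abundance")) {
  what <- match.arg(what)
  df <- series[!is.na(series$day), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$day, y = .data[[what]], colour = .data$niche
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(donor ~ sample_type) +
    ggplot2::labs(x = "day", y = gsub("_", " ", what), colour = "niche") +
    ggplot2::theme_minimal()
}

#' Heat map of oral invader abundances across bioreactor samples
#'
#' @param x An `oralgut_invasion_report`.
#' @param ... Unused.
#' @return A ggplot tile plot, invader MSPs x samples, log10 abundance
#'   fill, zeros blank.
#' @method autoplot oralgut_invasion_report
#' @export
autoplot.oralgut_invasion_report <- function(x, ...) {
  im <- x$invader_matrix
  if (nrow(im) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no oral invaders detected") +
             ggplot2::theme_void())
  }
  im$label <- paste0(im$sample_type, "_d", sprintf("%02d", im$day))
  im$ab <- ifelse(im$abundance > 0, log10(im$abundance), NA)
  ggplot2::ggplot(im, ggplot2::aes(.data$label, .data$msp_id, fill = .data$ab)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~donor, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 rel. ab.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Heat map of the Bray-Curtis dissimilarity matrix
#'
#' @param bc Output of [bray_curtis_matrix()].
#' @return A ggplot tile plot of the sample x sample dissimilarities.
#' @export
plot_bray_curtis <- function(bc) {
  long <- tidyr::pivot_longer(bc, -"sample_id", names_to = "other",
                              values_to = "bc")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$other,
                                     fill = .data$bc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Bray-Curtis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Stacked composition bars at a taxonomic rank
#'
#' @param comp Output of [aggregate_by_rank()].
#' @return A ggplot stacked bar chart, one bar per sample.
#' @export
plot_rank_composition <- function(comp) {
  rank <- names(comp)[1]
  long <- tidyr::pivot_longer(comp, -all_of(rank), names_to = "sample_id",
                              values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$abundance,
                                     fill = .data[[rank]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = rank) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
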