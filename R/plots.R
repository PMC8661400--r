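#' Plot telomeric repeat density along chromosomes
#'
#' One panel per sequence showing the windowed combined motif density, with
#' the call threshold as a dashed line. Windows at telomeric ends stand out
#' as density spikes near 1.
#'
#' @param object A `telomere_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot telomere_scan
#' @export
autoplot.telomere_scan <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$win_start + .data$win_end) / 2,
                                  y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$params$min_density,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~seq_id, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "telomeric motif density") +
    ggplot2::theme_minimal()
}

#' Plot a curation result
#'
#' Closed versus open gaps per chromosome, sized by gap length and coloured
#' by outcome.
#'
#' @param object A `curation` object (full run).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curation
#' @export
autoplot.curation <- function(object, ...) {
  if (is.null(object$report)) abort("autoplot needs a full curation run")
  g <- mutate(object$gaps,
              outcome = if_else(.data$gap_id %in% object$report$closures$gap_id,
                                "closed", "open"))
  ggplot2::ggplot(g, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$seq_id,
                                  size = .data$length, colour = .data$outcome)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::scale_colour_manual(values = c(closed = "#2c7fb8", open = "#d95f0e")) +
    ggplot2::labs(x = "position (bp)", y = NULL, size = "gap bp",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
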