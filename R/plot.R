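#' Plot an observed-vs-expected distance distribution
#'
#' Observed inter-copy distance frequencies (points) against the geometric
#' expectation (line), on a log10 frequency scale. The crossing of the two
#' curves is the data-driven maximum-distance threshold of the intersection
#' models; an optional vertical line marks a resolved threshold.
#'
#' @param object A `wordclust_dist` distribution from
#'   [distance_distribution()].
#' @param d_max Optional threshold to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wordclust_dist
#' @export
autoplot.wordclust_dist <- function(object, d_max = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$exp_freq,
                                    colour = "expected")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_freq,
                                     colour = "observed"), size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inter-copy distance", y = "relative frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(d_max)) {
    p <- p + ggplot2::geom_vline(xintercept = d_max, linetype = "dashed")
  }
  p
}

#' Plot the distance distribution behind a cluster analysis
#'
#' @param x A `wordclust` result.
#' @param seq_id Sequence to plot; defaults to the first. Ignored under the
#'   genome-intersection model, where the merged distribution is shown.
#' @return A ggplot object with the resolved threshold marked.
#' @export
plot_distance_distribution <- function(x, seq_id = NULL) {
  stopifnot(inherits(x, "wordclust"))
  thr <- x$thresholds
  if (x$model == "genome_intersection") {
    d <- x$distances$d
    row <- thr[1, ]
  } else {
    if (is.null(seq_id)) seq_id <- thr$seq_id[[1]]
    d <- x$distances$d[x$distances$seq_id == seq_id]
    row <- thr[thr$seq_id == seq_id, ]
  }
  unit <- if ("L_mean" %in% names(row)) row$L_mean else 1
  dd <- distance_distribution(d, row$p, unit = unit)
  autoplot(dd, d_max = row$d_max / unit)
}

#' Map the significant clusters of an analysis
#'
#' Draws each significant cluster as a horizontal segment along its
#' sequence, coloured by -log10 p-value.
#'
#' @param object A `wordclust` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wordclust
#' @export
autoplot.wordclust <- function(object, ...) {
  cl <- object$significant
  ggplot2::ggplot(cl,
    ggplot2::aes(x = .data$start, xend = .data$end,
                 y = .data$seq_id, yend = .data$seq_id,
                 colour = -log10(.data$p_value))) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  colour = expression(-log[10] * " p")) +
    ggplot2::theme_minimal()
}
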