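## ggplot2 views of call sets and diversity tracks.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a TE call set
#'
#' Events along each chromosome, support on the y axis, coloured by
#' new/old status and shaped by orientation.
#'
#' @param object A `te_call_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_call_set
#' @export
autoplot.te_call_set <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$loc / 1e3,
                                   y = .data$read_pair_support,
                                   colour = .data$novelty,
                                   shape = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (kb)", y = "supporting read pairs",
                  colour = "status", shape = "orientation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.te_call_set
#' @param x A `te_call_set`.
#' @param y Ignored.
#' @export
plot.te_call_set <- function(x, y, ...) print(autoplot(x, ...))

#' Plot a diversity track
#'
#' Per-window mean pairwise difference per bp along each chromosome.
#'
#' @param object A `diversity_track` from [pairwise_diversity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diversity_track
#' @export
autoplot.diversity_track <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$window_start / 1e3,
                               y = .data$value)) +
    ggplot2::geom_col(width = attr(object, "window_size") / 1e3,
                      fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "window start (kb)",
                  y = "pairwise difference per bp") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.diversity_track
#' @param x A `diversity_track`.
#' @param y Ignored.
#' @export
plot.diversity_track <- function(x, y, ...) print(autoplot(x, ...))
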