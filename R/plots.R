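# ggplot2 views of the result types.

#' Plot split count against distance ratio
#'
#' The batch-level view: one point per tree, split count `s` on the x axis
#' (log scale optional) against `D_bar`. Trees in the lower-left corner
#' (single split, low `D_bar`) separate the domains by a single long
#' branch -- the signature expected of families already present in the
#' last universal common ancestor.
#'
#' @param object A `batch_result`.
#' @param log_s Use a log10 x axis for `s`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot batch_result
#' @export
autoplot.batch_result <- function(object, log_s = FALSE, ...) {
  pairs <- scatter_table(object)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$s, y = .data$D_bar)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "interdomain splits (s)",
                  y = expression(bar(D)),
                  title = "Domain separation: splits vs distance ratio") +
    ggplot2::theme_minimal()
  if (log_s) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot null distributions of the split count
#'
#' Histograms of `s` over label shuffles, one facet per proportion.
#'
#' @param object A `null_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_result
#' @export
autoplot.null_result <- function(object, ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~proportion, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "interdomain splits (s)", y = "replicates",
                  title = "Split counts under label shuffling") +
    ggplot2::theme_minimal()
}

#' Plot D_bar null distributions by proportion
#'
#' Violin plot of `D_bar` across shuffle replicates, stratified by the
#' A-fraction used, with single-split replicates overlaid as points.
#'
#' @param result A `null_result`.
#' @return A ggplot object.
#' @export
plot_null_dbar <- function(result) {
  stopifnot(inherits(result, "null_result"))
  rec <- result$records[!is.na(result$records$D_bar), , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(x = factor(.data$proportion),
                                    y = .data$D_bar)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_point(data = rec[rec$s == 1, , drop = FALSE],
                        color = "firebrick", alpha = 0.7, size = 1) +
    ggplot2::labs(x = "A-fraction of shuffle",
                  y = expression(bar(D)),
                  title = "Distance ratios under label shuffling",
                  subtitle = "single-split replicates in red") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
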