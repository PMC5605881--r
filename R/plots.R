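#' Plot an OD-delta trajectory with its credible band
#'
#' @param object An `odelta_trajectory`.
#' @param ... Unused.
#' @return A ggplot: posterior mean line, 95% ribbon, zero reference.
#' @method autoplot odelta_trajectory
#' @export
autoplot.odelta_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(
      x = "time (h)", y = expression(OD[Delta]),
      title = sprintf("%s vs %s (%s)", attr(object, "strain"),
                      attr(object, "parent"), attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' Heat-map style plot of a trajectory matrix in dendrogram order
#'
#' @param m A [trajectory_matrix()].
#' @param clustering Optional [cluster_trajectories()] result; rows are
#'   ordered by its dendrogram.
#' @return A ggplot tile plot of posterior-mean OD-delta values.
#' @export
plot_trajectory_heatmap <- function(m, clustering = NULL) {
  ord <- if (!is.null(clustering))
    rownames(m)[clustering$tree$order] else rownames(m)
  df <- tibble::as_tibble(m, rownames = "strain") |>
    tidyr::pivot_longer(-strain, names_to = "time", values_to = "value") |>
    dplyr::mutate(time = as.numeric(time),
                  strain = factor(strain, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = time, y = strain, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0,
                                  name = expression(OD[Delta])) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ranked phenotype magnitudes for one condition
#'
#' @param norms A tibble of per-strain magnitudes (columns `strain`,
#'   `norm_median`, optionally `norm_q1`/`norm_q3`), e.g. from
#'   [phenotype_summaries()] filtered to one condition.
#' @param cutoff Optional magnitude cutoff drawn as a vertical line.
#' @return A ggplot bar chart in rank order.
#' @export
plot_phenotype_ranking <- function(norms, cutoff = NULL) {
  ranked <- rank_mutants(norms)
  ranked$strain <- factor(ranked$strain, levels = rev(ranked$strain))
  p <- ggplot2::ggplot(ranked,
                       ggplot2::aes(x = norm_median, y = strain)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression("||" * OD[Delta] * "||" ~ "(posterior median)"),
                  y = NULL) +
    ggplot2::theme_minimal()
  if ("norm_q1" %in% names(ranked) && "norm_q3" %in% names(ranked)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$norm_q1, xmax = .data$norm_q3),
      height = 0.3, colour = "grey30")
  }
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
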