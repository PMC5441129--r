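#' Tidy a cluster-inference result
#'
#' @param x a `cluster_fwe_result` from [cluster_fwe()].
#' @param ... unused.
#' @return One row per cluster: regressor, extent (voxels and resels), peak
#'   statistics, corrected p-value and significance flag.
#' @export
tidy.cluster_fwe_result <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' @rdname tidy.cluster_fwe_result
#' @return `glance()`: a one-row model summary.
#' @export
glance.cluster_fwe_result <- function(x, ...) {
  tibble::tibble(n_regressors = length(x$regressors), dof = x$dof,
                 t_threshold = x$t_threshold, n_perm = x$n_perm,
                 voxel_p = x$voxel_p, cluster_alpha = x$cluster_alpha,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant))
}

#' Tidy a learned Bayesian network
#'
#' @param x a `bn_graph` from [tpda_learn()].
#' @param ... unused.
#' @return The edge tibble (`from`, `to`, `direction`, `r2`, `p_marginal`).
#' @export
tidy.bn_graph <- function(x, ...) x$edges

#' @rdname tidy.bn_graph
#' @export
glance.bn_graph <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_directed = sum(x$edges$direction == "forward"),
                 n_bidirected = sum(x$edges$direction == "bidirected"),
                 alpha = x$alpha)
}

#' Plot the null distribution of maximum cluster extent
#'
#' Histogram of the permutation null of the maximum resel-normalized cluster
#' extent, with the observed clusters overlaid, one panel per regressor.
#'
#' @param object a `cluster_fwe_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_fwe_result <- function(object, ...) {
  null_df <- tidyr::pivot_longer(
    tibble::as_tibble(object$null_max), dplyr::everything(),
    names_to = "regressor", values_to = "max_extent")
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$max_extent)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~regressor) +
    ggplot2::labs(x = "maximum cluster extent (resels), permutation null",
                  y = "permutations")
  if (nrow(object$clusters) > 0L) {
    p <- p + ggplot2::geom_vline(
      data = dplyr::select(object$clusters, "regressor", "extent_resels",
                           "significant"),
      ggplot2::aes(xintercept = .data$extent_resels,
                   linetype = .data$significant), colour = "firebrick")
  }
  p
}

#' Plot a learned Bayesian network as a simple diagram
#'
#' Nodes on a circle, directed edges as arrows, bidirected edges as
#' double-headed arrows, labelled by determination coefficient.
#'
#' @param object a `bn_graph`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bn_graph <- function(object, ...) {
  nodes <- tibble::tibble(
    name = object$nodes,
    angle = 2 * pi * (seq_along(object$nodes) - 1) / length(object$nodes))
  nodes$x <- cos(nodes$angle); nodes$y <- sin(nodes$angle)
  g <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name)) +
    ggplot2::coord_equal() + ggplot2::theme_void()
  if (nrow(object$edges) > 0L) {
    ed <- dplyr::left_join(object$edges,
                           dplyr::rename(nodes, from_x = "x", from_y = "y"),
                           by = c(from = "name"))
    ed <- dplyr::left_join(ed, dplyr::rename(nodes, to_x = "x", to_y = "y"),
                           by = c(to = "name"))
    shrink <- 0.12
    ed$x0 <- ed$from_x + shrink * (ed$to_x - ed$from_x)
    ed$y0 <- ed$from_y + shrink * (ed$to_y - ed$from_y)
    ed$x1 <- ed$to_x - shrink * (ed$to_x - ed$from_x)
    ed$y1 <- ed$to_y - shrink * (ed$to_y - ed$from_y)
    g <- g + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches"),
                             ends = ifelse(ed$direction == "bidirected",
                                           "both", "last")),
      colour = "steelblue") +
      ggplot2::geom_label(
        data = ed,
        ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                     y = (.data$y0 + .data$y1) / 2,
                     label = sprintf("%.2f", .data$r2)), size = 3)
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
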