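# ggplot2 visualisations for the main result types.

#' @describeIn build_common_network Plot the common network with edge width
#'   proportional to the common weight and node size to the activation
#'   presence count.
#' @param object Result object to plot.
#' @export
autoplot.common_network <- function(object, ...) {
  if (nrow(object$edges) == 0L) {
    abort_langcore("Common network is empty; nothing to plot.", "invalid_input")
  }
  g <- igraph::graph_from_data_frame(
    object$edges, directed = FALSE,
    vertices = as.data.frame(object$nodes)
  )
  lay <- igraph::layout_in_circle(g)
  nodes <- object$nodes %>%
    mutate(x = lay[, 1L], y = lay[, 2L])
  pos <- setNames(seq_len(nrow(nodes)), nodes$froi)
  edges <- object$edges %>%
    mutate(
      x = nodes$x[pos[.data$froi_i]], y = nodes$y[pos[.data$froi_i]],
      xend = nodes$x[pos[.data$froi_j]], yend = nodes$y[pos[.data$froi_j]]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$W_C),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_active),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x * 1.15, y = .data$y * 1.15, label = .data$froi)
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 3), name = "W^C") +
    ggplot2::scale_size(range = c(3, 8), name = "subjects active") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Common network (presence ≥ %d/%d subjects)",
                                  ceiling(object$presence_fraction * object$n_subjects),
                                  object$n_subjects))
}

#' @describeIn occupancy_by_froi Stacked k-shell occupancy histogram, one
#'   fill colour per fROI.
#' @param object Result object to plot.
#' @export
autoplot.occupancy_histogram <- function(object, ...) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count,
                 fill = .data$froi)
  ) +
    ggplot2::geom_col(width = 1 / object$n_bins * 0.95) +
    ggplot2::labs(x = "normalized k-shell", y = "voxel count", fill = "fROI",
                  title = "k-shell occupancy by fROI") +
    ggplot2::theme_minimal()
}

#' @describeIn normalized_rich_club Normalized rich-club ratio against k with
#'   the null 2-SD band.
#' @param object Result object to plot.
#' @export
autoplot.rich_club_curve <- function(object, ...) {
  d <- tidy(object) %>% filter(is.finite(.data$ratio))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = ifelse(.data$phi_rand_mean > 0,
                      1 - 2 * .data$phi_rand_sd / .data$phi_rand_mean, NA),
        ymax = ifelse(.data$phi_rand_mean > 0,
                      1 + 2 * .data$phi_rand_sd / .data$phi_rand_mean, NA)
      ),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ratio), colour = "firebrick") +
    ggplot2::labs(x = "k", y = expression(phi(k) / phi[rand](k)),
                  title = "Normalized rich-club coefficient") +
    ggplot2::theme_minimal()
}

#' @describeIn pooled_weight_distribution Histogram of pooled normalized link
#'   weights.
#' @param object Result object to plot.
#' @export
autoplot.weight_distribution <- function(object, ...) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count)
  ) +
    ggplot2::geom_col(width = diff(object$histogram$bin_lo[1:2]) * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(
      x = "normalized link weight", y = "count",
      title = sprintf("Pooled link weights (skewness %.2f)", object$skewness)
    ) +
    ggplot2::theme_minimal()
}
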