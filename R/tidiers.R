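# broom-style tidy()/glance() methods: every result type flattens to a tibble.

#' @describeIn threshold_network Edge list of a voxel network as a tibble.
#' @param x,... Tidier arguments.
#' @export
tidy.voxel_network <- function(x, ...) as_tibble(x$edges)

#' @describeIn aggregate_froi Edge list of an fROI network as a tibble.
#' @param x,... Tidier arguments.
#' @export
tidy.froi_network <- function(x, ...) as_tibble(x$edges)

#' @describeIn build_common_network Edge list of the common network.
#' @param x,... Tidier arguments.
#' @export
tidy.common_network <- function(x, ...) as_tibble(x$edges)

#' @describeIn build_common_network One-row summary of the common network.
#' @export
glance.common_network <- function(x, ...) {
  tibble(
    n_frois = nrow(x$nodes),
    n_links = nrow(x$edges),
    n_subjects = x$n_subjects,
    presence_fraction = x$presence_fraction,
    min_presence = ceiling(x$presence_fraction * x$n_subjects),
    w_c_max = if (nrow(x$edges)) max(x$edges$W_C) else NA_real_
  )
}

#' @describeIn occupancy_by_froi Long-format occupancy histogram.
#' @param x,... Tidier arguments.
#' @export
tidy.occupancy_histogram <- function(x, ...) as_tibble(x$histogram)

#' @describeIn occupancy_by_froi Per-fROI max-shell summary.
#' @export
glance.occupancy_histogram <- function(x, ...) as_tibble(x$max_shell)

#' @describeIn normalized_rich_club The curve as a plain tibble.
#' @param x,... Tidier arguments.
#' @export
tidy.rich_club_curve <- function(x, ...) {
  tibble(k = x$k, phi = x$phi, phi_rand_mean = x$phi_rand_mean,
         phi_rand_sd = x$phi_rand_sd, ratio = x$ratio)
}

#' @describeIn normalized_rich_club One-row summary of the curve.
#' @export
glance.rich_club_curve <- function(x, ...) {
  ok <- is.finite(x$ratio)
  tibble(
    k_max = max(x$k),
    n_null = attr(x, "n_null"),
    ratio_slope = ratio_slope(x),
    max_ratio = if (any(ok)) max(x$ratio[ok]) else NA_real_
  )
}

#' @describeIn pooled_weight_distribution Histogram of pooled weights.
#' @param x,... Tidier arguments.
#' @export
tidy.weight_distribution <- function(x, ...) as_tibble(x$histogram)

#' @describeIn pooled_weight_distribution One-row summary (skewness, n).
#' @export
glance.weight_distribution <- function(x, ...) {
  tibble(n_weights = x$n_weights, skewness = x$skewness,
         mean = mean(x$weights), median = stats::median(x$weights))
}
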