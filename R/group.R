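#' Extract the cross-subject common network
#'
#' The common network retains an fROI pair and the link between them only if
#' both areas and the link are present in at least
#' `ceiling(presence_fraction * N)` of the N contributing subjects. The
#' common weight of a retained link is the average of the per-subject
#' normalized weights,
#' \deqn{W^C_{ij} = \frac{1}{N}\sum_{l=1}^{N} \tilde W^{(l)}_{ij},}
#' where by default the sum and the denominator run over the subjects that
#' possess the link (the behaviour matching reported group weights);
#' `denominator = "all"` divides by the full cohort size instead. An fROI is
#' retained only if it is active in enough subjects *and* keeps at least one
#' retained incident link, so the common network has no isolated areas.
#'
#' @param fnets List of normalized `froi_network`s (one per subject).
#'   Edgeless networks are dropped with a warning.
#' @param presence_fraction Fraction of subjects required, in (0, 1]
#'   (default 0.85, i.e. 17 of 20).
#' @param denominator `"possessors"` (default) or `"all"`.
#' @return An object of class `common_network`: list with `nodes` (tibble
#'   `froi`, `n_active`), `edges` (tibble `froi_i`, `froi_j`, `W_C`, `sd`,
#'   `n_present`), `presence_fraction`, `n_subjects`, `denominator`.
#' @export
build_common_network <- function(fnets, presence_fraction = 0.85,
                                 denominator = c("possessors", "all")) {
  denominator <- match.arg(denominator)
  fnets <- purrr::compact(fnets)
  if (length(fnets) == 0L) {
    abort_langcore("No subject networks supplied.", "invalid_input")
  }
  empty <- purrr::map_lgl(fnets, ~ nrow(.x$edges) == 0L)
  if (any(empty)) {
    warning(sprintf("%d edgeless subject network(s) excluded from the group stage.",
                    sum(empty)), call. = FALSE)
    fnets <- fnets[!empty]
  }
  if (length(fnets) < 2L) {
    abort_langcore("At least 2 subjects with edges are required.", "invalid_input")
  }
  if (presence_fraction <= 0 || presence_fraction > 1) {
    abort_langcore("`presence_fraction` must lie in (0, 1].", "invalid_input")
  }
  n_subj <- length(fnets)
  need <- as.integer(ceiling(presence_fraction * n_subj))

  node_presence <- purrr::map_dfr(fnets, ~ .x$nodes["froi"]) %>%
    count(.data$froi, name = "n_active")
  all_edges <- purrr::map_dfr(fnets, ~ .x$edges)

  stats <- all_edges %>%
    group_by(.data$froi_i, .data$froi_j) %>%
    summarise(
      n_present = dplyr::n(),
      W_sum = sum(.data$W_norm),
      sd = if (dplyr::n() > 1L) sd(.data$W_norm) else 0,
      .groups = "drop"
    ) %>%
    mutate(W_C = .data$W_sum /
             if (denominator == "possessors") .data$n_present else n_subj)

  active_enough <- node_presence$froi[node_presence$n_active >= need]
  edges <- stats %>%
    filter(.data$n_present >= need,
           .data$froi_i %in% active_enough,
           .data$froi_j %in% active_enough) %>%
    select("froi_i", "froi_j", "W_C", "sd", "n_present") %>%
    arrange(.data$froi_i, .data$froi_j)

  if (nrow(edges) == 0L) {
    warning("No link meets the persistence criterion; common network is empty.",
            call. = FALSE)
  }
  nodes <- node_presence %>%
    filter(.data$froi %in% c(edges$froi_i, edges$froi_j)) %>%
    arrange(.data$froi)

  structure(
    list(nodes = nodes, edges = edges,
         presence_fraction = presence_fraction,
         n_subjects = n_subj, denominator = denominator),
    class = "common_network"
  )
}

#' @export
print.common_network <- function(x, ...) {
  cat(sprintf(
    "<common_network> %d fROIs, %d links (presence >= %d/%d subjects)\n",
    nrow(x$nodes), nrow(x$edges),
    ceiling(x$presence_fraction * x$n_subjects), x$n_subjects
  ))
  if (nrow(x$edges) > 0L) print(as_tibble(x$edges))
  invisible(x)
}

#' Cross-subject statistics of one fROI link
#'
#' Sample mean and SD of the normalized weight of a given link over the
#' subjects that possess it.
#'
#' @param fnets List of normalized `froi_network`s.
#' @param froi_i,froi_j The two fROI names (order irrelevant).
#' @return A list with `mean`, `sd`, `n_present`, and `degenerate` (`TRUE`
#'   when only one subject possesses the link, in which case `sd = 0`).
#' @export
link_statistics <- function(fnets, froi_i, froi_j) {
  a <- min(froi_i, froi_j); b <- max(froi_i, froi_j)
  w <- purrr::compact(fnets) %>%
    purrr::map_dfr(~ .x$edges) %>%
    filter(.data$froi_i == a, .data$froi_j == b) %>%
    pull("W_norm")
  if (length(w) == 0L) {
    abort_langcore(sprintf("Link %s--%s is present in no subject.", a, b),
                   "absent_edge")
  }
  list(
    mean = mean(w),
    sd = if (length(w) > 1L) sd(w) else 0,
    n_present = length(w),
    degenerate = length(w) == 1L
  )
}

#' Rank fROIs by connectivity strength within a subject
#'
#' Strength is the sum of the normalized weights of a region's incident
#' links; regions are ranked descending (rank 1 = most connected). Ties are
#' broken alphabetically so rankings are deterministic.
#'
#' @param fnet A normalized `froi_network`.
#' @param frois Optional subset of fROIs to rank (e.g. the common-network
#'   areas); defaults to all fROIs with at least one link.
#' @return A tibble `froi`, `strength`, `rank`.
#' @export
rank_froi_strength <- function(fnet, frois = NULL) {
  stopifnot(inherits(fnet, "froi_network"))
  if (nrow(fnet$edges) == 0L) {
    abort_langcore("fROI network has no edges.", "invalid_input")
  }
  incid <- bind_rows(
    fnet$edges %>% select(froi = "froi_i", w = "W_norm"),
    fnet$edges %>% select(froi = "froi_j", w = "W_norm")
  )
  if (!is.null(frois)) incid <- filter(incid, .data$froi %in% frois)
  incid %>%
    group_by(.data$froi) %>%
    summarise(strength = sum(.data$w), .groups = "drop") %>%
    arrange(desc(.data$strength), .data$froi) %>%
    mutate(rank = row_number())
}

#' Pooled distribution of normalized link weights
#'
#' Pools every subject's normalized fROI link weights, bins them, and
#' reports the sample skewness; strongly right-skewed (long-tailed) pooled
#' weights indicate large intersubject variability of individual links.
#'
#' @param fnets List of normalized `froi_network`s.
#' @param n_bins Number of equal-width bins on `[0, 1]` (default 20).
#' @return An object of class `weight_distribution`: list with `histogram`
#'   (tibble `bin_lo`, `bin_hi`, `count`), `skewness`, `n_weights`, and the
#'   pooled `weights`.
#' @export
pooled_weight_distribution <- function(fnets, n_bins = 20L) {
  w <- purrr::compact(fnets) %>% purrr::map_dfr(~ .x$edges) %>% pull("W_norm")
  if (length(w) == 0L) {
    abort_langcore("No link weights to pool.", "invalid_input")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bins <- cut(w, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bins))
  structure(
    list(
      histogram = tibble(
        bin_lo = breaks[-length(breaks)],
        bin_hi = breaks[-1L],
        count = counts
      ),
      skewness = skewness_(w),
      n_weights = length(w),
      weights = w
    ),
    class = "weight_distribution"
  )
}
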