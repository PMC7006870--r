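#' Pairwise Pearson correlation matrix of voxel time series
#'
#' The functional coupling between voxels i and j is the Pearson correlation
#' of their BOLD series,
#' \deqn{C_{ij} = \frac{\langle x_i x_j\rangle - \langle x_i\rangle\langle x_j\rangle}
#'   {\sigma_i \sigma_j},}
#' with temporal averages over the full run.
#'
#' @param bold Numeric matrix, voxels x volumes, restricted to the voxels of
#'   interest (typically the active set).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(bold) {
  if (!is.matrix(bold) || nrow(bold) < 2L || ncol(bold) < 4L) {
    abort_langcore("`bold` must be a matrix with >= 2 voxels and >= 4 volumes.",
                   "invalid_input")
  }
  sds <- apply(bold, 1L, sd)
  if (any(sds == 0)) {
    abort_langcore(
      "Constant voxel series: correlation undefined. Exclude such voxels upstream.",
      "undefined_correlation"
    )
  }
  cor(t(bold))
}

#' Threshold a correlation matrix into a voxel-level network
#'
#' Connects voxel pairs whose correlation meets or exceeds the absolute
#' threshold `theta` (signed correlations: negative couplings never form
#' edges). Edge weight is the correlation itself. Isolated voxels are kept as
#' nodes so that fROI sizes count all analyzed voxels.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param labels Character vector of fROI labels, one per row of `corr`.
#' @param theta Correlation threshold in (0, 1).
#' @param voxel_ids Optional voxel identifiers (defaults to 0-based indices).
#' @return An object of class `voxel_network`: list with `nodes`
#'   (tibble `voxel_id`, `froi`), `edges` (tibble `from`, `to`, `weight`,
#'   endpoints ordered), and `theta`.
#' @export
threshold_network <- function(corr, labels, theta,
                              voxel_ids = seq_len(nrow(corr)) - 1L) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    abort_langcore("`theta` must lie strictly between 0 and 1.", "invalid_threshold")
  }
  n <- nrow(corr)
  stopifnot(length(labels) == n, length(voxel_ids) == n)
  idx <- which(upper.tri(corr) & corr >= theta, arr.ind = TRUE)
  edges <- tibble(
    from = voxel_ids[idx[, 1L]],
    to = voxel_ids[idx[, 2L]],
    weight = corr[idx]
  )
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  structure(
    list(
      nodes = tibble(voxel_id = voxel_ids, froi = labels),
      edges = arrange(edges, .data$from, .data$to),
      theta = theta
    ),
    class = "voxel_network"
  )
}

#' @export
print.voxel_network <- function(x, ...) {
  cat(sprintf("<voxel_network> %d voxels, %d edges, theta = %g\n",
              nrow(x$nodes), nrow(x$edges), x$theta))
  invisible(x)
}

#' Build the voxel network for one subject
#'
#' Convenience wrapper: restricts the BOLD matrix to active voxels (optionally
#' minus excluded fROIs, the analogue of dropping visual/auditory activation),
#' computes the correlation matrix and thresholds it.
#'
#' @param subject A `subject_data` object.
#' @param activation An [activation_map()] for the subject.
#' @param theta Correlation threshold (default 0.7).
#' @param exclude_frois Character vector of fROI names to drop after
#'   activation selection.
#' @return A `voxel_network`, or `NULL` with a warning if fewer than 2 active
#'   voxels remain.
#' @export
build_voxel_network <- function(subject, activation, theta = 0.7,
                                exclude_frois = character(0)) {
  keep <- activation$active & !(activation$froi %in% exclude_frois)
  if (sum(keep) < 2L) {
    warning(sprintf("Subject %s has < 2 analyzable active voxels; skipped.",
                    subject$subject_id %||% "?"), call. = FALSE)
    return(NULL)
  }
  rows <- match(activation$voxel_id[keep], subject$voxels$voxel_id)
  corr <- correlation_matrix(subject$bold[rows, , drop = FALSE])
  vnet <- threshold_network(corr, activation$froi[keep], theta,
                            voxel_ids = activation$voxel_id[keep])
  vnet$subject_id <- subject$subject_id
  vnet
}

#' Aggregate a voxel network into an fROI network (raw weights)
#'
#' Two fROIs are linked if and only if at least one voxel-level edge crosses
#' between them. The raw link weight is the cross edge count normalized by
#' the sum of the two fROI sizes,
#' \deqn{W_{ij} = \frac{\#\text{links } i \leftrightarrow j}
#'   {\mathrm{size}(i) + \mathrm{size}(j)}.}
#' Within-fROI edges contribute to sizes only, never to a weight.
#'
#' @param vnet A [threshold_network()] result.
#' @return An object of class `froi_network`: list with `nodes` (tibble
#'   `froi`, `size`) and `edges` (tibble `froi_i`, `froi_j`, `W`), plus the
#'   originating `theta` and `subject_id` if known.
#' @export
aggregate_froi <- function(vnet) {
  stopifnot(inherits(vnet, "voxel_network"))
  nodes <- vnet$nodes %>% count(.data$froi, name = "size")
  lab <- setNames(vnet$nodes$froi, as.character(vnet$nodes$voxel_id))
  e <- vnet$edges %>%
    mutate(fi = unname(lab[as.character(.data$from)]),
           fj = unname(lab[as.character(.data$to)])) %>%
    filter(.data$fi != .data$fj) %>%
    mutate(
      froi_i = pmin(.data$fi, .data$fj),
      froi_j = pmax(.data$fi, .data$fj)
    ) %>%
    count(.data$froi_i, .data$froi_j, name = "n_links")
  sizes <- setNames(nodes$size, nodes$froi)
  edges <- e %>%
    mutate(W = .data$n_links /
             unname(sizes[.data$froi_i] + sizes[.data$froi_j])) %>%
    select("froi_i", "froi_j", "n_links", "W") %>%
    arrange(.data$froi_i, .data$froi_j)
  structure(
    list(nodes = nodes, edges = edges, theta = vnet$theta,
         subject_id = vnet$subject_id),
    class = "froi_network"
  )
}

#' @export
print.froi_network <- function(x, ...) {
  cat(sprintf("<froi_network> %d fROIs, %d links%s\n",
              nrow(x$nodes), nrow(x$edges),
              if ("W_norm" %in% names(x$edges)) " (normalized)" else ""))
  invisible(x)
}

#' Normalize fROI link weights to the subject's maximum
#'
#' Divides every raw weight by the subject's largest raw weight,
#' \eqn{\tilde W_{ij} = W_{ij} / W^{max}}, so that every individual network
#' shares the same weight scale and its maximum normalized weight is exactly
#' 1.
#'
#' @param fnet An [aggregate_froi()] result.
#' @return The same `froi_network` with a `W_norm` column and `w_max` field.
#'   An edgeless network yields an empty result with a warning (such subjects
#'   are excluded from the group stage).
#' @export
normalize_weights <- function(fnet) {
  stopifnot(inherits(fnet, "froi_network"))
  if (nrow(fnet$edges) == 0L) {
    warning("fROI network has no edges; nothing to normalize (subject excluded from group stage).",
            call. = FALSE)
    fnet$edges$W_norm <- numeric(0)
    fnet$w_max <- NA_real_
    return(fnet)
  }
  fnet$w_max <- max(fnet$edges$W)
  fnet$edges$W_norm <- fnet$edges$W / fnet$w_max
  fnet
}

#' Per-subject fROI network in one call
#'
#' @param subject,activation,theta,exclude_frois Passed to
#'   [build_voxel_network()].
#' @return A normalized `froi_network`, or `NULL` if the subject was skipped.
#' @export
build_froi_network <- function(subject, activation, theta = 0.7,
                               exclude_frois = character(0)) {
  vnet <- build_voxel_network(subject, activation, theta, exclude_frois)
  if (is.null(vnet)) return(NULL)
  normalize_weights(aggregate_froi(vnet))
}
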