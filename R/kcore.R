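#' k-core decomposition of a voxel network
#'
#' The k-core of a graph is the maximal subgraph in which every node has
#' degree at least k; it is obtained by iteratively pruning nodes of degree
#' < k until none remain. A node's core number is the largest k for which it
#' survives, and the k-shell is the set of nodes with core number exactly k.
#' The maximum k-shell always coincides with the maximum k-core. Edge
#' weights are ignored: the decomposition depends on topology only.
#'
#' @param x A `voxel_network`, or a data frame of edges with columns
#'   `from`/`to`.
#' @param nodes Optional node tibble (`voxel_id`, `froi`) when `x` is an edge
#'   table; isolated nodes listed here receive core number 0.
#' @return An object of class `kshell_assignment`: a tibble `voxel_id`,
#'   `froi`, `core_number`, with attributes `kcore_max` and `subject_id`.
#' @examples
#' vn <- threshold_network(diag(3) * 0 + 0.9, c("A", "A", "B"), 0.5)
#' core_decompose(vn)
#' @export
core_decompose <- function(x, nodes = NULL) {
  if (inherits(x, "voxel_network")) {
    nodes <- x$nodes
    edges <- x$edges
    subject_id <- x$subject_id
  } else {
    edges <- as_tibble(x)
    subject_id <- NULL
    if (is.null(nodes)) {
      ids <- sort(unique(c(edges$from, edges$to)))
      nodes <- tibble(voxel_id = ids, froi = NA_character_)
    }
  }
  if (nrow(nodes) == 0L) {
    out <- tibble(voxel_id = integer(0), froi = character(0),
                  core_number = integer(0))
    return(structure(out, class = c("kshell_assignment", class(out)),
                     kcore_max = 0L, subject_id = subject_id))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$voxel_id))
  )
  core <- igraph::coreness(g)
  out <- tibble(
    voxel_id = nodes$voxel_id,
    froi = nodes$froi,
    core_number = as.integer(core[as.character(nodes$voxel_id)])
  )
  structure(out, class = c("kshell_assignment", class(out)),
            kcore_max = max(out$core_number, 0L), subject_id = subject_id)
}

#' Normalize k-shell values by the subject's maximum k-core
#'
#' Divides every core number by the subject's `kcore_max`, mapping each
#' individual's shell range onto (0, 1] so that occupancy can be pooled and
#' compared across subjects with different maximum cores: the top shell of
#' every subject maps to exactly 1.
#'
#' @param assignment A [core_decompose()] result with `kcore_max >= 1`.
#' @return The assignment tibble with a `normalized_shell` column.
#' @export
normalized_shells <- function(assignment) {
  stopifnot(inherits(assignment, "kshell_assignment"))
  kmax <- attr(assignment, "kcore_max")
  if (is.null(kmax) || kmax < 1L) {
    abort_langcore(
      "Edgeless network: kcore_max = 0, normalization undefined (subject skipped).",
      "undefined_normalization"
    )
  }
  assignment$normalized_shell <- assignment$core_number / kmax
  assignment
}

# breaks for the occupancy bins: n equal-width bins on (0, 1]; values of 0
# (isolated voxels) are counted into the bottom bin.
occupancy_breaks <- function(n_bins) seq(0, 1, length.out = n_bins + 1L)

#' Pooled k-shell occupancy by fROI
#'
#' Pools the normalized shell values of all subjects and histograms them per
#' fROI on equal-width bins over (0, 1] (default 10 bins, top bin
#' (0.9, 1]). Also reports, per fROI, the fraction of its voxels lying in
#' their subject's maximum k-shell.
#'
#' @param assignments List of [normalized_shells()] results (one per
#'   subject).
#' @param froi_filter fROIs to analyse (e.g. the common-network areas).
#'   Unknown names raise an error. `NULL` analyses all fROIs.
#' @param n_bins Number of occupancy bins (default 10).
#' @return An object of class `occupancy_histogram`: list with `histogram`
#'   (tibble `froi`, `bin_lo`, `bin_hi`, `count`), `max_shell` (tibble
#'   `froi`, `n_voxels`, `n_max_shell`, `fraction_max_shell`), `n_bins`,
#'   `froi_filter`.
#' @export
occupancy_by_froi <- function(assignments, froi_filter = NULL, n_bins = 10L) {
  if (inherits(assignments, "kshell_assignment")) assignments <- list(assignments)
  pooled <- purrr::map_dfr(assignments, function(a) {
    stopifnot(inherits(a, "kshell_assignment"))
    if (!"normalized_shell" %in% names(a)) a <- normalized_shells(a)
    tibble(
      froi = a$froi,
      normalized_shell = a$normalized_shell,
      in_max_shell = a$core_number == attr(a, "kcore_max")
    )
  })
  if (!is.null(froi_filter)) {
    unknown <- setdiff(froi_filter, unique(pooled$froi))
    if (length(unknown) > 0L) {
      abort_langcore(sprintf("Unknown fROI(s) in filter: %s",
                             paste(unknown, collapse = ", ")),
                     "unknown_froi")
    }
    pooled <- filter(pooled, .data$froi %in% froi_filter)
  }
  breaks <- occupancy_breaks(n_bins)
  pooled$bin <- cut(pooled$normalized_shell, breaks = breaks,
                    include.lowest = TRUE, right = TRUE)
  histogram <- pooled %>%
    count(.data$froi, .data$bin, .drop = FALSE, name = "count") %>%
    mutate(
      bin_lo = breaks[as.integer(.data$bin)],
      bin_hi = breaks[as.integer(.data$bin) + 1L]
    ) %>%
    select("froi", "bin_lo", "bin_hi", "count")
  max_shell <- pooled %>%
    group_by(.data$froi) %>%
    summarise(
      n_voxels = dplyr::n(),
      n_max_shell = sum(.data$in_max_shell),
      fraction_max_shell = mean(.data$in_max_shell),
      .groups = "drop"
    )
  structure(
    list(histogram = histogram, max_shell = max_shell,
         n_bins = n_bins, froi_filter = froi_filter),
    class = "occupancy_histogram"
  )
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("<occupancy_histogram> %d fROIs, %d bins\n",
              dplyr::n_distinct(x$histogram$froi), x$n_bins))
  print(x$max_shell)
  invisible(x)
}

#' Label-permutation null for k-shell occupancy
#'
#' Randomizes the voxel-to-fROI assignment within each subject (preserving
#' per-subject topology, core numbers and fROI sizes), re-pools occupancy
#' across subjects, and compares each fROI's observed maximum-shell fraction
#' with its null distribution. The permutation p-value uses the add-one
#' estimator `(b + 1) / (n_perm + 1)` and is two-sided (doubled smaller
#' tail, capped at 1).
#'
#' @param assignments List of [normalized_shells()] results.
#' @param n_perm Number of label permutations (default 199).
#' @param seed Integer seed.
#' @param froi_filter,n_bins As in [occupancy_by_froi()].
#' @return A tibble `froi`, `observed` (max-shell fraction), `null_mean`,
#'   `null_sd`, `p_value`, with attribute `n_perm`.
#' @export
null_occupancy <- function(assignments, n_perm = 199L, seed = 1L,
                           froi_filter = NULL, n_bins = 10L) {
  if (inherits(assignments, "kshell_assignment")) assignments <- list(assignments)
  if (n_perm < 1L) {
    abort_langcore("`n_perm` must be at least 1.", "invalid_input")
  }
  per_subject <- purrr::map(assignments, function(a) {
    if (!"normalized_shell" %in% names(a)) a <- normalized_shells(a)
    tibble(
      froi = a$froi,
      in_max_shell = a$core_number == attr(a, "kcore_max")
    )
  })
  observed <- max_shell_fraction(per_subject, froi_filter)

  null_mat <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(i) {
      permuted <- purrr::map(per_subject, function(d) {
        d$froi <- sample(d$froi)
        d
      })
      max_shell_fraction(permuted, froi_filter)$fraction
    }, numeric(nrow(observed)))
  })
  null_mat <- matrix(null_mat, nrow = nrow(observed))

  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1L, sd)
  b_hi <- rowSums(null_mat >= observed$fraction)
  b_lo <- rowSums(null_mat <= observed$fraction)
  p <- pmin(1, 2 * (pmin(b_hi, b_lo) + 1) / (n_perm + 1))

  structure(
    tibble(
      froi = observed$froi,
      observed = observed$fraction,
      null_mean = null_mean,
      null_sd = null_sd,
      p_value = p
    ),
    n_perm = n_perm
  )
}

max_shell_fraction <- function(per_subject, froi_filter) {
  pooled <- bind_rows(per_subject)
  if (!is.null(froi_filter)) {
    unknown <- setdiff(froi_filter, unique(pooled$froi))
    if (length(unknown) > 0L) {
      abort_langcore(sprintf("Unknown fROI(s) in filter: %s",
                             paste(unknown, collapse = ", ")),
                     "unknown_froi")
    }
    pooled <- filter(pooled, .data$froi %in% froi_filter)
  }
  pooled %>%
    group_by(.data$froi) %>%
    summarise(fraction = mean(.data$in_max_shell), .groups = "drop") %>%
    arrange(.data$froi)
}
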