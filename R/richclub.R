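# --- internal: igraph from a voxel_network or edge table ------------------
as_graph_ <- function(x, nodes = NULL) {
  if (inherits(x, "voxel_network")) {
    igraph::graph_from_data_frame(
      x$edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = as.character(x$nodes$voxel_id))
    )
  } else if (igraph::is_igraph(x)) {
    x
  } else {
    edges <- as_tibble(x)
    verts <- if (is.null(nodes)) NULL else data.frame(name = as.character(nodes))
    igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                  vertices = verts)
  }
}

#' Rich-club coefficient
#'
#' For each degree k, restrict the graph to the nodes whose degree in the
#' original graph exceeds k and measure the density of the surviving
#' subgraph,
#' \deqn{\phi(k) = \frac{2 E_{>k}}{N_{>k}(N_{>k} - 1)},}
#' where `E_>k` and `N_>k` count the edges and nodes remaining after all
#' nodes with degree <= k are removed. Values are reported for k from 0 to
#' the maximum degree minus 1; k with fewer than 2 surviving nodes are
#' omitted (the density is undefined). The computation is unweighted.
#'
#' @param graph An igraph object, a `voxel_network`, or an edge data frame.
#' @return A tibble `k`, `n_nodes`, `n_edges`, `phi`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' rich_club_coefficient(g) # phi(k) = 1 everywhere
#' @export
rich_club_coefficient <- function(graph) {
  g <- as_graph_(graph)
  deg <- igraph::degree(g)
  if (length(deg) == 0L || max(deg) == 0L) {
    return(tibble(k = integer(0), n_nodes = integer(0),
                  n_edges = integer(0), phi = numeric(0)))
  }
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  # an edge survives the > k filter iff the smaller endpoint degree exceeds k
  edge_min_deg <- pmin(deg[ends[, 1L]], deg[ends[, 2L]])
  ks <- 0:(max(deg) - 1L)
  purrr::map_dfr(ks, function(k) {
    n_k <- sum(deg > k)
    if (n_k < 2L) return(NULL)
    e_k <- sum(edge_min_deg > k)
    tibble(k = k, n_nodes = n_k, n_edges = e_k,
           phi = 2 * e_k / (n_k * (n_k - 1)))
  })
}

#' Degree-preserving rewiring
#'
#' Randomizes a graph by repeated double-edge swaps that preserve every
#' node's degree; swaps that would create self-loops or parallel edges are
#' rejected. Reproducible under `seed`.
#'
#' @param graph An igraph object, `voxel_network`, or edge data frame.
#' @param n_swaps Number of attempted swaps (default 10 x edge count).
#' @param seed Integer seed.
#' @return A rewired igraph object with the same degree sequence. Graphs
#'   admitting no valid swap (e.g. complete graphs) are returned unchanged
#'   with a warning.
#' @export
degree_preserving_rewire <- function(graph, n_swaps = NULL, seed = 1L) {
  g <- as_graph_(graph)
  m <- igraph::ecount(g)
  if (m < 2L) {
    abort_langcore("At least 2 edges are required to rewire.", "invalid_input")
  }
  n <- igraph::vcount(g)
  if (m == n * (n - 1) / 2) {
    warning("Complete graph: no admissible degree-preserving swap; returned unchanged.",
            call. = FALSE)
    return(g)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * m
  with_seed_(seed, igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
}

#' Normalized rich-club curve
#'
#' Computes phi(k) for the observed graph and for `n_null` degree-preserving
#' rewired graphs, and reports the normalized coefficient
#' `phi(k) / phi_rand(k)`, where `phi_rand(k)` is the null mean. A ratio
#' rising above 1 with k is the rich-club signature: hubs are more densely
#' interconnected than their degrees alone require.
#'
#' @param graph An igraph object, `voxel_network`, or edge data frame.
#' @param n_null Number of rewired null graphs (default 100).
#' @param n_swaps Swap attempts per null (default 10 x edge count).
#' @param seed Integer seed.
#' @return An object of class `rich_club_curve`: a tibble `k`, `phi`,
#'   `phi_rand_mean`, `phi_rand_sd`, `ratio` (NA where the null mean is 0 or
#'   undefined), with attributes `n_null`, `n_swaps`, `seed`.
#' @export
normalized_rich_club <- function(graph, n_null = 100L, n_swaps = NULL, seed = 1L) {
  if (n_null < 1L) {
    abort_langcore("`n_null` must be at least 1.", "invalid_input")
  }
  g <- as_graph_(graph)
  obs <- rich_club_coefficient(g)
  if (nrow(obs) == 0L) {
    abort_langcore("Graph has no edges; rich-club curve undefined.", "invalid_input")
  }
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  seeds <- derive_seeds(seed, "rich_club_null", n_null)
  null_phi <- purrr::map(seeds, function(s) {
    gr <- suppressWarnings(degree_preserving_rewire(g, n_swaps = n_swaps, seed = s))
    phi <- rich_club_coefficient(gr)
    setNames(phi$phi, phi$k)[as.character(obs$k)]
  })
  null_mat <- do.call(cbind, null_phi)
  out <- obs %>%
    mutate(
      phi_rand_mean = rowMeans(null_mat, na.rm = TRUE),
      phi_rand_sd = apply(null_mat, 1L, sd, na.rm = TRUE),
      ratio = ifelse(.data$phi_rand_mean > 0,
                     .data$phi / .data$phi_rand_mean, NA_real_)
    )
  structure(out, class = c("rich_club_curve", class(out)),
            n_null = n_null, n_swaps = n_swaps, seed = seed)
}

#' Rich-club sensitivity to the correlation threshold
#'
#' Rebuilds a subject's voxel network at the base threshold and at relative
#' perturbations of it (default +/- 5%), computes the normalized rich-club
#' curve for each, and summarizes the qualitative behaviour by the sign of
#' the slope of `ratio` against k over each curve's defined range. A planted
#' or real rich club should keep a positive slope at every perturbed
#' threshold.
#'
#' @param subject A `subject_data` object.
#' @param activation An [activation_map()] for the subject.
#' @param theta0 Base correlation threshold.
#' @param deltas Relative threshold perturbations (default `c(-0.05, 0, 0.05)`).
#' @param n_null,n_swaps,seed Passed to [normalized_rich_club()].
#' @param exclude_frois Passed to [build_voxel_network()].
#' @return An object of class `rich_club_sweep`: list with `curves` (named
#'   list of `rich_club_curve`s, one per delta), and `summary` (tibble
#'   `delta`, `theta`, `n_edges`, `slope`, `increasing`).
#' @export
threshold_sensitivity <- function(subject, activation, theta0 = 0.7,
                                  deltas = c(-0.05, 0, 0.05),
                                  n_null = 100L, n_swaps = NULL, seed = 1L,
                                  exclude_frois = character(0)) {
  thetas <- theta0 * (1 + deltas)
  if (any(thetas <= 0 | thetas >= 1)) {
    abort_langcore("All perturbed thresholds must lie in (0, 1).",
                   "invalid_threshold")
  }
  seeds <- derive_seeds(seed, "threshold_sensitivity", length(deltas))
  curves <- list()
  rows <- list()
  for (i in seq_along(deltas)) {
    vnet <- build_voxel_network(subject, activation, theta = thetas[i],
                                exclude_frois = exclude_frois)
    if (is.null(vnet) || nrow(vnet$edges) < 2L) {
      warning(sprintf("Threshold %.3f leaves too small a network; curve omitted.",
                      thetas[i]), call. = FALSE)
      next
    }
    curve <- normalized_rich_club(vnet, n_null = n_null, n_swaps = n_swaps,
                                  seed = seeds[i])
    slope <- ratio_slope(curve)
    key <- sprintf("delta=%+.0f%%", 100 * deltas[i])
    curves[[key]] <- curve
    rows[[key]] <- tibble(
      delta = deltas[i], theta = thetas[i],
      n_edges = nrow(vnet$edges),
      slope = slope, increasing = slope > 0
    )
  }
  structure(
    list(curves = curves, summary = bind_rows(rows)),
    class = "rich_club_sweep"
  )
}

# least-squares slope of the normalized ratio against k over defined points
ratio_slope <- function(curve) {
  ok <- is.finite(curve$ratio)
  if (sum(ok) < 2L) return(NA_real_)
  stats::coef(stats::lm(curve$ratio[ok] ~ curve$k[ok]))[[2L]]
}

#' @export
print.rich_club_sweep <- function(x, ...) {
  cat("<rich_club_sweep>\n")
  print(x$summary)
  invisible(x)
}
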