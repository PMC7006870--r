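# Independent brute-force oracles. Each one re-derives a quantity from its
# definition by explicit enumeration, sharing no code with the implementation.

# O(n^2) linear convolution, truncated to length(x).
oracle_convolve <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (l in seq_along(kernel)) {
      if (t - l + 1 >= 1) out[t] <- out[t] + x[t - l + 1] * kernel[l]
    }
  }
  out
}

# Pearson correlation matrix from raw temporal moments, double loop.
oracle_corr <- function(bold) {
  n <- nrow(bold)
  C <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      xi <- bold[i, ]; xj <- bold[j, ]
      num <- mean(xi * xj) - mean(xi) * mean(xj)
      C[i, j] <- num / sqrt((mean(xi^2) - mean(xi)^2) * (mean(xj^2) - mean(xj)^2))
    }
  }
  C
}

# Benjamini-Hochberg step-up q-values straight from the definition:
# q(i) = min_{j >= i} m * p_(j) / j, in the sorted order, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# fROI link weights by exhaustive voxel-pair enumeration over a voxel network.
oracle_froi_weights <- function(vnet) {
  lab <- setNames(vnet$nodes$froi, as.character(vnet$nodes$voxel_id))
  sizes <- table(vnet$nodes$froi)
  counts <- list()
  if (nrow(vnet$edges) > 0) {
    for (e in seq_len(nrow(vnet$edges))) {
      fi <- lab[[as.character(vnet$edges$from[e])]]
      fj <- lab[[as.character(vnet$edges$to[e])]]
      if (fi == fj) next
      key <- paste(sort(c(fi, fj)), collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(counts) == 0L) {
    return(tibble::tibble(froi_i = character(0), froi_j = character(0),
                          W = numeric(0)))
  }
  out <- purrr::imap_dfr(counts, function(cnt, key) {
    fr <- strsplit(key, "|", fixed = TRUE)[[1]]
    tibble::tibble(froi_i = fr[1], froi_j = fr[2],
                   W = cnt / (as.integer(sizes[[fr[1]]]) + as.integer(sizes[[fr[2]]])))
  })
  dplyr::arrange(out, froi_i, froi_j)
}

# Core numbers by literal iterative pruning (independent of igraph).
oracle_coreness <- function(edges, node_ids) {
  adj <- lapply(setNames(vector("list", length(node_ids)), as.character(node_ids)),
                function(x) character(0))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges$from[e]); b <- as.character(edges$to[e])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  core <- setNames(rep(0L, length(node_ids)), as.character(node_ids))
  alive <- setNames(rep(TRUE, length(node_ids)), as.character(node_ids))
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- vapply(names(alive)[alive],
                    function(v) sum(alive[adj[[v]]]), integer(1))
      drop <- names(deg)[deg < k]
      if (length(drop) == 0L) break
      core[drop] <- k - 1L
      alive[drop] <- FALSE
    }
    if (any(alive)) k <- k + 1L
  }
  core[names(alive)[!alive]] <- pmax(core[names(alive)[!alive]], 0L)
  core
}

# Definitional k-core check: for every k up to the max core number, the nodes
# with core >= k induce a subgraph of min degree >= k, and re-adding any
# excluded node gives it degree < k within the augmented node set.
oracle_core_check <- function(edges, node_ids, core) {
  core <- core[as.character(node_ids)]
  kmax <- max(core, 0L)
  adj_deg <- function(v, S) {
    sum((edges$from == v & edges$to %in% S) | (edges$to == v & edges$from %in% S))
  }
  for (k in seq_len(kmax)) {
    S <- node_ids[core >= k]
    for (v in S) {
      if (adj_deg(v, setdiff(S, v)) < k) return(FALSE)
    }
    for (u in setdiff(node_ids, S)) {
      if (adj_deg(u, S) >= k) return(FALSE)
    }
  }
  TRUE
}

# Rich-club phi(k) by explicitly building each degree-filtered subgraph.
oracle_rich_club <- function(g) {
  deg <- igraph::degree(g)
  if (length(deg) == 0 || max(deg) == 0) {
    return(tibble::tibble(k = integer(0), phi = numeric(0)))
  }
  rows <- list()
  for (k in 0:(max(deg) - 1)) {
    keep <- which(deg > k)
    if (length(keep) < 2) next
    sub <- igraph::induced_subgraph(g, keep)
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = k,
      phi = 2 * igraph::ecount(sub) /
        (igraph::vcount(sub) * (igraph::vcount(sub) - 1))
    )
  }
  dplyr::bind_rows(rows)
}

random_gnp <- function(n, p) igraph::sample_gnp(n, p)

`%||%` <- function(a, b) if (is.null(a)) b else a
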