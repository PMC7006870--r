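graph_as_edges <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  tibble::tibble(from = e[, 1], to = e[, 2])
}

test_that("core numbers match cliques, trees and the pruning definition", {
  k4 <- graph_as_edges(igraph::make_full_graph(4))
  a <- core_decompose(k4)
  expect_equal(a$core_number, rep(3L, 4))
  expect_equal(attr(a, "kcore_max"), 3L)

  path <- tibble::tibble(from = 1:4, to = 2:5)
  expect_equal(core_decompose(path)$core_number, rep(1L, 5))

  empty <- core_decompose(tibble::tibble(from = integer(0), to = integer(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "kcore_max"), 0L)
})

test_that("core numbers satisfy the definitional check and pruning oracle on random graphs", {
  withr::with_seed(37, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      g <- random_gnp(n, runif(1, 0.2, 0.7))
      edges <- graph_as_edges(g)
      nodes <- tibble::tibble(voxel_id = seq_len(n), froi = "X")
      a <- core_decompose(edges, nodes = nodes)
      core <- setNames(a$core_number, as.character(a$voxel_id))
      expect_equal(unname(core),
                   unname(oracle_coreness(edges, seq_len(n))[as.character(seq_len(n))]))
      expect_true(oracle_core_check(edges, seq_len(n), core))
      # nestedness: the (k+1)-core is a subset of the k-core
      for (k in seq_len(max(core))) {
        expect_true(all(a$voxel_id[core >= k + 1] %in% a$voxel_id[core >= k]))
      }
    }
  })
})

test_that("adding an edge never decreases a core number", {
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(5:10, 1)
      g <- random_gnp(n, 0.3)
      edges <- graph_as_edges(g)
      nodes <- tibble::tibble(voxel_id = seq_len(n), froi = "X")
      base <- core_decompose(edges, nodes = nodes)$core_number
      absent <- t(combn(seq_len(n), 2))
      have <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
      absent <- absent[!(paste(absent[, 1], absent[, 2]) %in% have), , drop = FALSE]
      if (nrow(absent) == 0) next
      pick <- absent[sample(nrow(absent), 1), ]
      grown <- dplyr::bind_rows(edges, tibble::tibble(from = pick[1], to = pick[2]))
      expect_true(all(core_decompose(grown, nodes = nodes)$core_number >= base))
    }
  })
})

test_that("shell normalization maps every subject's top core to 1", {
  k4 <- graph_as_edges(igraph::make_full_graph(4))
  a <- normalized_shells(core_decompose(k4))
  expect_equal(a$normalized_shell, rep(1, 4))

  a2 <- structure(
    tibble::tibble(voxel_id = 1:2, froi = "X", core_number = c(2L, 4L)),
    class = c("kshell_assignment", "tbl_df", "tbl", "data.frame"),
    kcore_max = 4L
  )
  expect_equal(normalized_shells(a2)$normalized_shell, c(0.5, 1))

  edgeless <- core_decompose(tibble::tibble(from = integer(0), to = integer(0)),
                             nodes = tibble::tibble(voxel_id = 1:3, froi = "X"))
  expect_error(normalized_shells(edgeless), class = "undefined_normalization")
})

test_that("occupancy pools counts and conserves voxel totals per fROI", {
  k4 <- graph_as_edges(igraph::make_full_graph(4))
  a <- core_decompose(k4, nodes = tibble::tibble(voxel_id = 1:4,
                                                 froi = c("A", "A", "B", "B")))
  occ <- occupancy_by_froi(list(normalized_shells(a)))
  expect_equal(sum(occ$histogram$count), 4)
  top <- occ$histogram[occ$histogram$bin_hi == 1, ]
  expect_equal(sum(top$count), 4)
  expect_equal(occ$max_shell$fraction_max_shell, c(1, 1))

  expect_error(occupancy_by_froi(list(normalized_shells(a)), froi_filter = "Z"),
               class = "unknown_froi")

  # counts conserve per-fROI voxel numbers on a random graph
  withr::with_seed(23, {
    g <- random_gnp(30, 0.2)
    nodes <- tibble::tibble(voxel_id = 1:30,
                            froi = sample(c("A", "B", "C"), 30, replace = TRUE))
    a2 <- normalized_shells(core_decompose(graph_as_edges(g), nodes = nodes))
    occ2 <- occupancy_by_froi(list(a2))
    by_froi <- tapply(occ2$histogram$count, occ2$histogram$froi, sum)
    expect_equal(as.integer(by_froi[sort(unique(nodes$froi))]),
                 as.integer(table(nodes$froi)))
  })
})

test_that("label permutation null matches the hypergeometric expectation", {
  withr::with_seed(29, {
    g <- random_gnp(40, 0.25)
    nodes <- tibble::tibble(voxel_id = 1:40,
                            froi = rep(c("A", "B"), times = c(10, 30)))
    a <- normalized_shells(core_decompose(graph_as_edges(g), nodes = nodes))
  })
  n_perm <- 1000
  nul <- null_occupancy(list(a), n_perm = n_perm, seed = 17)
  N <- nrow(a)
  total_max <- sum(a$core_number == attr(a, "kcore_max"))
  expected <- total_max / N                # per-voxel max-shell probability
  for (i in seq_len(nrow(nul))) {
    size_f <- sum(a$froi == nul$froi[i])
    # hypergeometric SD of the per-permutation fraction, / sqrt(n_perm)
    se_mean <- sqrt(expected * (1 - expected) / size_f *
                      (N - size_f) / (N - 1)) / sqrt(n_perm)
    expect_lt(abs(nul$null_mean[i] - expected), 3 * se_mean)
  }
})

test_that("single-fROI permutation null is vacuous", {
  k4 <- graph_as_edges(igraph::make_full_graph(4))
  a <- normalized_shells(core_decompose(k4, nodes = tibble::tibble(
    voxel_id = 1:4, froi = "only"
  )))
  nul <- null_occupancy(list(a), n_perm = 25, seed = 2)
  expect_equal(nul$null_mean, nul$observed)
  expect_equal(nul$null_sd, 0)
  expect_equal(nul$p_value, 1)
})

test_that("core numbers ignore edge weights and node relabeling", {
  withr::with_seed(53, {
    g <- random_gnp(15, 0.3)
    edges <- graph_as_edges(g)
    nodes <- tibble::tibble(voxel_id = 1:15, froi = "X")
    base <- core_decompose(edges, nodes = nodes)$core_number
    perm <- sample(15)
    relabeled <- tibble::tibble(from = perm[edges$from], to = perm[edges$to])
    got <- core_decompose(relabeled, nodes = tibble::tibble(voxel_id = perm[nodes$voxel_id],
                                                            froi = "X"))
    expect_equal(got$core_number, base)
  })
})
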