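test_that("correlation matrix matches the temporal-moment definition", {
  withr::with_seed(21, {
    bold <- matrix(rnorm(6 * 20), nrow = 6)
    C <- correlation_matrix(bold)
    expect_true(isSymmetric(C))
    expect_equal(diag(C), rep(1, 6))
    expect_lt(max(abs(C - oracle_corr(bold))), 1e-12)
  })

  two <- rbind(1:10, 1:10) + 0
  expect_equal(correlation_matrix(two)[1, 2], 1)
  opp <- rbind(1:10, -(1:10)) + 0
  expect_equal(correlation_matrix(opp)[1, 2], -1)

  const <- rbind(1:10, rep(2, 10))
  expect_error(correlation_matrix(const), class = "undefined_correlation")
  expect_error(correlation_matrix(matrix(1:3, 1)), class = "invalid_input")
})

test_that("thresholding keeps supra-threshold pairs and isolated nodes", {
  withr::with_seed(8, {
    bold <- matrix(rnorm(8 * 30), nrow = 8)
    C <- correlation_matrix(bold)
    labels <- rep(c("A", "B"), each = 4)

    expect_error(threshold_network(C, labels, 0), class = "invalid_threshold")
    expect_error(threshold_network(C, labels, 1), class = "invalid_threshold")

    pos_min <- min(C[upper.tri(C)][C[upper.tri(C)] > 0])
    vn <- threshold_network(C, labels, pos_min * 0.999)
    expect_equal(nrow(vn$edges), sum(C[upper.tri(C)] >= pos_min * 0.999))
    expect_equal(nrow(vn$nodes), 8)
    expect_true(all(vn$edges$weight >= vn$theta))
    expect_true(all(vn$edges$from < vn$edges$to))

    # raising theta never adds an edge
    thetas <- sort(runif(5, 0.05, 0.95))
    edge_sets <- lapply(thetas, function(th) {
      e <- threshold_network(C, labels, th)$edges
      paste(e$from, e$to)
    })
    for (i in seq_len(length(thetas) - 1)) {
      expect_true(all(edge_sets[[i + 1]] %in% edge_sets[[i]]))
    }
  })
})

test_that("fROI aggregation implements the size-normalized cross-link count", {
  fn <- aggregate_froi(toy_voxel_network())
  expect_equal(fn$nodes$size[fn$nodes$froi == "A"], 3L)
  expect_equal(fn$nodes$size[fn$nodes$froi == "B"], 2L)
  expect_equal(nrow(fn$edges), 1)           # within-A edge makes no A-A link
  expect_equal(fn$edges$W, 4 / 5)           # 4 cross links / (3 + 2)

  # zero cross edges: link absent, not weight zero
  vn <- toy_voxel_network()
  vn$edges <- vn$edges[5, ]                 # only the within-fROI edge
  expect_equal(nrow(aggregate_froi(vn)$edges), 0)
})

test_that("fROI weights agree with exhaustive pair enumeration on random networks", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(6:14, 1)
      nodes <- tibble::tibble(
        voxel_id = seq_len(n) - 1L,
        froi = sample(LETTERS[1:3], n, replace = TRUE)
      )
      pairs <- t(combn(nodes$voxel_id, 2))
      keep <- runif(nrow(pairs)) < 0.4
      vn <- structure(
        list(nodes = nodes,
             edges = tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                                    weight = runif(sum(keep), 0.7, 1)),
             theta = 0.7, subject_id = "rnd"),
        class = "voxel_network"
      )
      got <- aggregate_froi(vn)$edges[, c("froi_i", "froi_j", "W")]
      expect_equal(as.data.frame(got), as.data.frame(oracle_froi_weights(vn)),
                   tolerance = 1e-12)
    }
  })
})

test_that("weight normalization fixes the per-subject maximum at 1", {
  single <- toy_fnet(tibble::tibble(froi_i = "A", froi_j = "B", W = 0.3))
  expect_equal(normalize_weights(single)$edges$W_norm, 1)

  two <- toy_fnet(tibble::tibble(froi_i = c("A", "A"), froi_j = c("B", "C"),
                                 W = c(0.8, 0.4)))
  expect_equal(normalize_weights(two)$edges$W_norm, c(1, 0.5))

  # scale equivariance: rescaling raw W leaves W_norm unchanged
  scaled <- two
  scaled$edges$W <- scaled$edges$W * 37
  expect_equal(normalize_weights(scaled)$edges$W_norm,
               normalize_weights(two)$edges$W_norm)

  empty <- toy_fnet(tibble::tibble(froi_i = character(0), froi_j = character(0),
                                   W = numeric(0)))
  expect_warning(res <- normalize_weights(empty), "no edges")
  expect_equal(nrow(res$edges), 0)
})

test_that("every synthetic subject's maximum normalized weight is exactly 1", {
  d <- task_design()
  r <- make_regressor(d)
  cohort <- simulate_cohort(small_spec(n_subjects = 4L, seed = 55L), d)
  for (s in cohort) {
    fn <- build_froi_network(s, activation_map(s, regressor = r), theta = 0.7)
    expect_identical(max(fn$edges$W_norm), 1)
  }
})

test_that("fROI exclusion drops areas before network construction", {
  d <- task_design()
  s <- simulate_subject(small_spec(), d, subject_seed = 9)
  act <- activation_map(s, design = d)
  vn <- build_voxel_network(s, act, theta = 0.7, exclude_frois = c("AG", "SMG"))
  expect_false(any(c("AG", "SMG") %in% vn$nodes$froi))
})
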