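three_toy_subjects <- function() {
  list(
    toy_fnet(tibble::tibble(froi_i = "A", froi_j = "B", W = 1, W_norm = 1.0)),
    toy_fnet(tibble::tibble(froi_i = "A", froi_j = "B", W = 1, W_norm = 0.5)),
    toy_fnet(tibble::tibble(froi_i = "A", froi_j = "C", W = 1, W_norm = 1.0))
  )
}

test_that("persistence rule retains links by presence count", {
  fnets <- three_toy_subjects()
  expect_warning(full <- build_common_network(fnets, presence_fraction = 1.0),
                 "No link meets")
  expect_equal(nrow(full$edges), 0)

  partial <- suppressWarnings(build_common_network(fnets, presence_fraction = 0.6))
  ab <- partial$edges[partial$edges$froi_i == "A" & partial$edges$froi_j == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$W_C, 0.75)      # mean over the two possessors
  expect_equal(ab$n_present, 2L)

  # literal total-N denominator on request
  all_n <- suppressWarnings(
    build_common_network(fnets, presence_fraction = 0.6, denominator = "all")
  )
  expect_equal(all_n$edges$W_C[all_n$edges$froi_i == "A" &
                                 all_n$edges$froi_j == "B"], 1.5 / 3)

  expect_error(build_common_network(list()), class = "invalid_input")
  expect_error(build_common_network(fnets, presence_fraction = 0),
               class = "invalid_input")
})

test_that("common network is monotone in presence_fraction and subject order invariant", {
  d <- task_design()
  r <- make_regressor(d)
  cohort <- simulate_cohort(small_spec(n_subjects = 6L, seed = 21L), d)
  fnets <- purrr::map(cohort, ~ build_froi_network(.x, activation_map(.x, regressor = r)))

  cn1 <- build_common_network(fnets, 0.5)
  cn2 <- build_common_network(fnets, 0.85)
  expect_true(all(cn2$nodes$froi %in% cn1$nodes$froi))
  key <- function(cn) paste(cn$edges$froi_i, cn$edges$froi_j)
  expect_true(all(key(cn2) %in% key(cn1)))

  perm <- build_common_network(rev(fnets), 0.85)
  expect_equal(cn2$edges, perm$edges)
  expect_equal(cn2$nodes, perm$nodes)

  # retained weights lie within the contributing subjects' range
  all_edges <- purrr::map_dfr(fnets, ~ .x$edges)
  for (i in seq_len(nrow(cn2$edges))) {
    w <- all_edges$W_norm[all_edges$froi_i == cn2$edges$froi_i[i] &
                            all_edges$froi_j == cn2$edges$froi_j[i]]
    expect_gte(cn2$edges$W_C[i], min(w))
    expect_lte(cn2$edges$W_C[i], max(w))
  }
})

test_that("link statistics average over possessing subjects", {
  fnets <- list(
    toy_fnet(tibble::tibble(froi_i = "A", froi_j = "B", W = 1, W_norm = 0.5)),
    toy_fnet(tibble::tibble(froi_i = "A", froi_j = "B", W = 1, W_norm = 0.5))
  )
  ls1 <- link_statistics(fnets, "A", "B")
  expect_equal(ls1$mean, 0.5)
  expect_equal(ls1$sd, 0)

  fnets[[2]]$edges$W_norm <- 0
  fnets[[1]]$edges$W_norm <- 1
  ls2 <- link_statistics(fnets, "B", "A")   # order irrelevant
  expect_equal(ls2$mean, 0.5)
  expect_equal(ls2$sd, sqrt(0.5), tolerance = 1e-12)

  ls3 <- link_statistics(fnets[1], "A", "B")
  expect_equal(ls3$sd, 0)
  expect_true(ls3$degenerate)

  expect_error(link_statistics(fnets, "A", "Z"), class = "absent_edge")
})

test_that("strength ranking sums incident weights with deterministic ties", {
  star <- toy_fnet(tibble::tibble(
    froi_i = c("hub", "hub", "hub"),
    froi_j = c("a", "b", "c"),
    W = 1, W_norm = c(0.9, 0.8, 1.0)
  ))
  rk <- rank_froi_strength(star)
  expect_equal(rk$froi[rk$rank == 1], "hub")
  expect_equal(rk$strength[rk$rank == 1], 2.7)

  # brute-force incidence summation oracle on a random fROI network
  withr::with_seed(3, {
    frois <- LETTERS[1:5]
    pairs <- t(combn(frois, 2))
    keep <- runif(nrow(pairs)) < 0.6
    fn <- toy_fnet(tibble::tibble(
      froi_i = pairs[keep, 1], froi_j = pairs[keep, 2],
      W = 1, W_norm = runif(sum(keep))
    ))
    rk <- rank_froi_strength(fn)
    for (f in rk$froi) {
      manual <- sum(fn$edges$W_norm[fn$edges$froi_i == f]) +
        sum(fn$edges$W_norm[fn$edges$froi_j == f])
      expect_equal(rk$strength[rk$froi == f], manual)
    }
    expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  })
})

test_that("the planted hub area dominates the subject-level rankings", {
  d <- task_design()
  r <- make_regressor(d)
  cohort <- simulate_cohort(small_spec(n_subjects = 10L, seed = 63L), d)
  top2 <- purrr::map_lgl(cohort, function(s) {
    fn <- build_froi_network(s, activation_map(s, regressor = r))
    rk <- rank_froi_strength(fn, frois = core_frois())
    # the non-peripheral core areas are mutually strongly coupled; WA is not
    rk$rank[rk$froi == "WA"] > 2
  })
  expect_gt(mean(top2), 0.9)
})

test_that("pooled weight distribution conserves counts and detects skew", {
  equal <- list(
    toy_fnet(tibble::tibble(froi_i = c("A", "B"), froi_j = c("B", "C"),
                            W = 1, W_norm = c(0.5, 0.5)))
  )
  wd <- pooled_weight_distribution(equal)
  expect_equal(wd$skewness, 0)
  expect_equal(sum(wd$histogram$count), 2)

  withr::with_seed(19, {
    w <- exp(rnorm(500, -2, 1))
    w <- w / max(w)
    fnets <- list(toy_fnet(tibble::tibble(
      froi_i = paste0("A", seq_along(w)), froi_j = paste0("B", seq_along(w)),
      W = w, W_norm = w
    )))
    wd2 <- pooled_weight_distribution(fnets)
    expect_gt(wd2$skewness, 0)
    expect_equal(sum(wd2$histogram$count), 500)
  })
})
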