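# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go through
# this, so no function leaks or depends on hidden global RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from a master seed and a stage label, so each
# pipeline stage consumes an independent, reproducible stream. Kept < 2^31.
derive_seeds <- function(seed, label, n = 1L) {
  lab <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 10000L
  with_seed_((as.integer(seed) %% 1000000L) * 1009L + lab, {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Canonical undirected edge orientation: endpoint ids sorted per edge.
orient_edges <- function(from, to) {
  swap <- from > to
  tibble(
    from = ifelse(swap, to, from),
    to   = ifelse(swap, from, to)
  )
}

# Sample skewness (method-of-moments, g1).
skewness_ <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

abort_langcore <- function(msg, class) {
  rlang::abort(msg, class = c(class, "langcore_error"))
}
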