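#' Per-voxel activation statistic
#'
#' Pearson correlation of one voxel's BOLD series with the task regressor,
#' with a p-value from the exact null distribution of the correlation under
#' Gaussian noise: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees
#' of freedom. For a single regressor plus intercept this is equivalent to
#' the GLM t-test on the regressor coefficient. The default alternative is
#' one-sided ("greater"): activation means a positive task association.
#'
#' @param bold_row Numeric BOLD series of one voxel.
#' @param regressor Task regressor from [make_regressor()]; same length.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A list with elements `r` and `p_value`. A constant (zero-variance)
#'   input yields `r = NA`, `p_value = 1` with a warning: such voxels are
#'   reported inactive rather than propagating NaN.
#' @examples
#' r <- make_regressor(task_design())
#' voxel_statistic(r + rnorm(length(r), 0, 0.1), r)
#' @export
voxel_statistic <- function(bold_row, regressor,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(bold_row)
  if (n != length(regressor)) {
    abort_langcore("`bold_row` and `regressor` must have equal length.",
                   "invalid_input")
  }
  if (n < 4L) {
    abort_langcore("At least 4 volumes are required.", "invalid_input")
  }
  if (sd(regressor) == 0) {
    abort_langcore("The regressor is constant; correlation is undefined.",
                   "undefined_correlation")
  }
  if (sd(bold_row) == 0) {
    warning("Constant voxel series: correlation undefined, reported inactive (p = 1).",
            call. = FALSE)
    return(list(r = NA_real_, p_value = 1))
  }
  r <- cor(bold_row, regressor)
  list(r = r, p_value = r_to_p(r, n, alternative))
}

# p-value of a Pearson correlation via the t-transform.
r_to_p <- function(r, n, alternative) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  t[r == 1] <- Inf
  t[r == -1] <- -Inf
  p_upper <- pt(t, df = n - 2, lower.tail = FALSE)
  switch(alternative,
         greater = p_upper,
         two.sided = 2 * pmin(p_upper, 1 - p_upper))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values: `q(i) = min over j >= i of
#' m * p(j) / j` over the p-values sorted ascending, mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_qvalues <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort_langcore("All p-values must lie in [0, 1].", "invalid_input")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Activation map for one subject
#'
#' Applies [voxel_statistic()] to every voxel, attaches BH q-values, and
#' flags voxels active when `p < p_thresh` (the conventional uncorrected
#' threshold in clinical presurgical mapping is `p < 1e-4`). The q-value
#' threshold is a diagnostic: `fdr_ok` in the attributes reports whether the
#' largest q among selected voxels is below `q_thresh`.
#'
#' @param subject A `subject_data` object (or a list with a `bold` matrix and
#'   a `voxels` tibble with `voxel_id` and `froi`).
#' @param regressor Task regressor; defaults need `design`.
#' @param design A [task_design()], used if `regressor` is missing.
#' @param p_thresh Uncorrected p-value threshold (default `1e-4`).
#' @param q_thresh FDR diagnostic threshold (default `1e-3`).
#' @param alternative Sidedness of the test; see [voxel_statistic()].
#' @return A tibble of class `activation_map` with columns `voxel_id`,
#'   `froi`, `r`, `p_value`, `q_value`, `active`, and attributes `p_thresh`,
#'   `q_thresh`, `fdr_ok`, `subject_id`.
#' @examples
#' subj <- simulate_subject(cohort_spec(seed = 3), task_design(), subject_seed = 5)
#' act <- activation_map(subj, design = task_design())
#' table(act$active)
#' @export
activation_map <- function(subject, regressor = NULL, design = NULL,
                           p_thresh = 1e-4, q_thresh = 1e-3,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(regressor)) {
    if (is.null(design)) {
      abort_langcore("Provide `regressor` or `design`.", "invalid_input")
    }
    regressor <- make_regressor(design)
  }
  bold <- subject$bold
  if (ncol(bold) != length(regressor)) {
    abort_langcore("Regressor length must equal the number of volumes.",
                   "invalid_input")
  }
  n <- length(regressor)
  sds <- apply(bold, 1L, sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sprintf("%d constant voxel series reported inactive (p = 1).",
                    sum(constant)), call. = FALSE)
  }
  r <- rep(NA_real_, nrow(bold))
  r[!constant] <- as.vector(cor(t(bold[!constant, , drop = FALSE]), regressor))
  p <- rep(1, nrow(bold))
  p[!constant] <- r_to_p(r[!constant], n, alternative)
  q <- bh_qvalues(p)

  out <- subject$voxels %>%
    select(dplyr::any_of(c("voxel_id", "froi"))) %>%
    mutate(r = r, p_value = p, q_value = q, active = p < p_thresh & !constant)
  structure(out,
            class = c("activation_map", class(out)),
            p_thresh = p_thresh, q_thresh = q_thresh,
            fdr_ok = if (any(out$active)) max(q[out$active]) < q_thresh else NA,
            subject_id = subject$subject_id)
}

#' Select active voxels
#'
#' Voxel ids with `p_value` strictly below the threshold, together with the
#' FDR diagnostic (whether the maximum q-value among selected voxels is below
#' the map's `q_thresh`).
#'
#' @param map An [activation_map()].
#' @param p_thresh Threshold; defaults to the map's own.
#' @return A list with `voxel_ids` and `fdr_ok`.
#' @export
select_active <- function(map, p_thresh = attr(map, "p_thresh")) {
  stopifnot(inherits(map, "activation_map"))
  sel <- map$p_value < p_thresh & !is.na(map$r)
  list(
    voxel_ids = map$voxel_id[sel],
    fdr_ok = if (any(sel)) max(map$q_value[sel]) < attr(map, "q_thresh") else NA
  )
}
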