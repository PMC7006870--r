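#' Define a block task design
#'
#' A block (boxcar) design alternates rest and task periods. Each epoch is a
#' `(rest_volumes, task_volumes)` pair; volumes are acquired every
#' `tr_seconds`. The default mirrors a clinical verb-generation run: six
#' 20-second epochs of 10 s rest followed by 10 s task, sampled at TR = 2 s,
#' i.e. 60 volumes.
#'
#' @param epochs A data frame (or tibble) with integer columns `rest_volumes`
#'   and `task_volumes`, one row per epoch, in presentation order.
#' @param tr_seconds Repetition time in seconds (> 0).
#'
#' @return An object of class `task_design`: a list with `epochs`,
#'   `tr_seconds`, `n_volumes` and the binary `boxcar` vector.
#' @examples
#' design <- task_design()
#' design$n_volumes
#' @export
task_design <- function(epochs = default_epochs(), tr_seconds = 2) {
  epochs <- as_tibble(epochs)
  if (nrow(epochs) == 0L) {
    abort_langcore("`epochs` must contain at least one epoch.", "invalid_design")
  }
  if (!all(c("rest_volumes", "task_volumes") %in% names(epochs))) {
    abort_langcore(
      "`epochs` needs columns `rest_volumes` and `task_volumes`.",
      "invalid_design"
    )
  }
  if (any(epochs$rest_volumes < 0) || any(epochs$task_volumes < 0) ||
      any((epochs$rest_volumes + epochs$task_volumes) <= 0)) {
    abort_langcore("Epoch volume counts must be non-negative and each epoch non-empty.",
                   "invalid_design")
  }
  if (tr_seconds <= 0) {
    abort_langcore("`tr_seconds` must be positive.", "invalid_design")
  }
  design <- structure(
    list(
      epochs = epochs,
      tr_seconds = tr_seconds,
      n_volumes = sum(epochs$rest_volumes) + sum(epochs$task_volumes)
    ),
    class = "task_design"
  )
  design$boxcar <- make_boxcar(design)
  design
}

default_epochs <- function(n_epochs = 6L, rest_volumes = 5L, task_volumes = 5L) {
  tibble(
    rest_volumes = rep(as.integer(rest_volumes), n_epochs),
    task_volumes = rep(as.integer(task_volumes), n_epochs)
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "<task_design> %d epochs, %d volumes, TR = %g s (%d task volumes)\n",
    nrow(x$epochs), x$n_volumes, x$tr_seconds, sum(x$boxcar)
  ))
  invisible(x)
}

#' Binary boxcar vector for a block design
#'
#' Returns the on/off stimulus train: 0 during rest sub-blocks, 1 during task
#' sub-blocks, in epoch order.
#'
#' @param design A [task_design()].
#' @return Integer vector of length `design$n_volumes` with entries in {0, 1}.
#' @examples
#' sum(make_boxcar(task_design())) # task volumes
#' @export
make_boxcar <- function(design) {
  stopifnot(inherits(design, "task_design"))
  unlist(purrr::map2(
    design$epochs$rest_volumes, design$epochs$task_volumes,
    function(r, t) c(rep(0L, r), rep(1L, t))
  ), use.names = FALSE)
}

#' Specify a double-gamma haemodynamic response function
#'
#' Parameters of the conventional double-gamma HRF kernel: a gamma-shaped
#' positive response peaking around `peak_delay_s`, minus a later undershoot
#' scaled by `undershoot_ratio`. Defaults are the common convention (peak 6 s,
#' undershoot 16 s, unit dispersions, ratio 1/6, 32 s support).
#'
#' @param peak_delay_s Delay of the response peak, seconds.
#' @param undershoot_delay_s Delay of the undershoot, seconds.
#' @param peak_dispersion_s Dispersion (gamma scale) of the peak, seconds.
#' @param undershoot_dispersion_s Dispersion of the undershoot, seconds.
#' @param undershoot_ratio Relative undershoot amplitude.
#' @param kernel_length_s Truncation length of the kernel, seconds.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                     undershoot_ratio = 1 / 6, kernel_length_s = 32) {
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 ||
      peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0 ||
      kernel_length_s <= 0) {
    abort_langcore("All HRF delays, dispersions and lengths must be positive.",
                   "invalid_spec")
  }
  structure(
    list(
      peak_delay_s = peak_delay_s,
      undershoot_delay_s = undershoot_delay_s,
      peak_dispersion_s = peak_dispersion_s,
      undershoot_dispersion_s = undershoot_dispersion_s,
      undershoot_ratio = undershoot_ratio,
      kernel_length_s = kernel_length_s
    ),
    class = "hrf_spec"
  )
}

#' Sample the canonical HRF kernel at the acquisition TR
#'
#' Evaluates the double-gamma kernel at lags `0, tr, 2 tr, ...` up to
#' `kernel_length_s` and peak-normalizes it to 1. The kernel is identically
#' zero at negative lags (causality), so convolution with the boxcar delays
#' the response.
#'
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param spec An [hrf_spec()].
#' @return Numeric kernel vector with `max(kernel) == 1`.
#' @examples
#' k <- canonical_hrf(2)
#' which.max(k) # peak near 6 s / TR
#' @export
canonical_hrf <- function(tr_seconds, spec = hrf_spec()) {
  if (tr_seconds <= 0) {
    abort_langcore("`tr_seconds` must be positive.", "invalid_spec")
  }
  stopifnot(inherits(spec, "hrf_spec"))
  lags <- seq(0, spec$kernel_length_s, by = tr_seconds)
  k <- double_gamma(lags, spec)
  k / max(k)
}

# Double-gamma evaluated on arbitrary (non-negative) lag grid; unnormalized.
double_gamma <- function(lags, spec) {
  stopifnot(all(lags >= 0))
  dgamma(lags,
         shape = spec$peak_delay_s / spec$peak_dispersion_s,
         scale = spec$peak_dispersion_s) -
    spec$undershoot_ratio *
      dgamma(lags,
             shape = spec$undershoot_delay_s / spec$undershoot_dispersion_s,
             scale = spec$undershoot_dispersion_s)
}

#' Build the task regressor by convolving the boxcar with the HRF
#'
#' Linear (causal) convolution of the design's boxcar with the sampled HRF
#' kernel, truncated to the number of acquired volumes. This is the model
#' time course a task-responsive voxel is expected to follow, and the single
#' regressor used by [activation_map()].
#'
#' @param design A [task_design()].
#' @param hrf Kernel vector from [canonical_hrf()].
#' @return Numeric vector of length `design$n_volumes`.
#' @examples
#' r <- make_regressor(task_design(), canonical_hrf(2))
#' length(r)
#' @export
make_regressor <- function(design, hrf = canonical_hrf(design$tr_seconds)) {
  stopifnot(inherits(design, "task_design"))
  if (length(hrf) > design$n_volumes) {
    abort_langcore("HRF kernel is longer than the acquisition.", "invalid_design")
  }
  box <- design$boxcar
  n <- length(box)
  full <- stats::convolve(box, rev(hrf), type = "open")
  out <- full[seq_len(n)]
  # numerical dust from FFT-based convolution of non-negative inputs
  out[abs(out) < 1e-12] <- 0
  out
}
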