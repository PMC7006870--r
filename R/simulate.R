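#' Default fROI catalog for the synthetic cohort
#'
#' Left-dominant language areas modelled on a clinical verb-generation study:
#' the planted core is Broca's area (pars opercularis `op-BA`, pars
#' triangularis `tri-BA`), Wernicke's area (`WA`), the ventral premotor area
#' (`preMA`) and the pre-supplementary motor area (`pre-SMA`); the remaining
#' areas (middle frontal gyrus, supramarginal and angular gyri, precentral
#' gyrus, deep opercular cortex, caudate and right-hemisphere homologues) are
#' task-responsive but only weakly coupled to each other. Core areas are
#' obligatory (always activated); non-obligatory areas drop out per subject
#' with the cohort's `p_dropout`, so subjects activate roughly 10-14 areas.
#'
#' @return A tibble with columns `froi`, `min_voxels`, `max_voxels`, `core`,
#'   `obligatory`.
#' @export
default_froi_catalog <- function() {
  tibble(
    froi = c("op-BA", "tri-BA", "WA", "preMA", "pre-SMA",
             "aMFG", "SMG", "AG", "PCG", "DOC", "caudate",
             "d-preMA", "BA-R", "WA-R"),
    min_voxels = c(rep(18L, 5), rep(12L, 9)),
    max_voxels = c(rep(32L, 5), rep(28L, 9)),
    core = c(rep(TRUE, 5), rep(FALSE, 9)),
    obligatory = c(rep(TRUE, 5), rep(FALSE, 9))
  )
}

#' Specify a synthetic task-fMRI cohort
#'
#' Parameters of the generative model used by [simulate_subject()]. For a
#' voxel v in fROI f the BOLD series is
#' \deqn{x_v(t) = \beta_v r(t) + \rho_w g_f(t) + \rho_{c,f} h(t) + \epsilon_v(t),}
#' where `r` is the HRF-convolved task regressor, `g_f = r + N(0, latent_sd^2)`
#' is a per-fROI latent series, `h = r + N(0, latent_sd^2)` is one latent
#' shared by all core fROIs, and `eps` is i.i.d. Gaussian noise. `beta_v` is
#' `beta_active` for active voxels and 0 otherwise; `rho_cf` is `rho_core` for
#' core fROIs, `rho_peripheral` for the designated peripheral core fROI, and 0
#' elsewhere. The shared latents make all planted couplings positive, as
#' observed for task-driven activation.
#'
#' Defaults are calibrated so that (i) active voxels correlate with the
#' regressor at roughly r = 0.63 (a strong, clinical-task-like effect of
#' Cohen's d about 1.5), (ii) voxel pairs within and between core fROIs
#' correlate around 0.77-0.87, above the default network threshold of 0.7,
#' (iii) the peripheral core fROI couples to the rest of the core around 0.65
#' (links persist at the fROI level but its voxels accumulate fewer
#' supra-threshold edges), and (iv) background cross-fROI correlation stays
#' near 0.41, well below threshold.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param froi_catalog Catalog tibble as in [default_froi_catalog()].
#' @param core_frois Names of the planted strongly coupled core fROIs.
#' @param peripheral_froi One core fROI given the attenuated
#'   `rho_peripheral` loading (the Wernicke's-area analogue); `NULL` for none.
#' @param beta_active Task amplitude of active voxels (signal units).
#' @param sigma_noise SD of the i.i.d. voxel noise.
#' @param rho_within Loading on the per-fROI latent.
#' @param rho_core Loading of core fROIs on the shared core latent.
#' @param rho_peripheral Loading of the peripheral core fROI on that latent.
#' @param latent_sd SD of the white noise inside each latent series.
#' @param p_dropout Per-subject probability that a non-obligatory fROI is
#'   absent (no activation at all).
#' @param fraction_inactive Fraction of voxels with `beta = 0` inside an
#'   activated fROI.
#' @param seed Integer master seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L,
                        froi_catalog = default_froi_catalog(),
                        core_frois = froi_catalog$froi[froi_catalog$core],
                        peripheral_froi = if ("WA" %in% core_frois) "WA" else NULL,
                        beta_active = 0.5,
                        sigma_noise = 0.75,
                        rho_within = 0.2,
                        rho_core = 0.4,
                        rho_peripheral = 0.18,
                        latent_sd = 3.3,
                        p_dropout = 0.1,
                        fraction_inactive = 0.15,
                        seed = 1L) {
  froi_catalog <- as_tibble(froi_catalog)
  if (nrow(froi_catalog) == 0L) {
    abort_langcore("`froi_catalog` must contain at least one fROI.", "invalid_spec")
  }
  if (anyDuplicated(froi_catalog$froi)) {
    abort_langcore("fROI names in the catalog must be unique.", "invalid_spec")
  }
  if (!all(core_frois %in% froi_catalog$froi)) {
    abort_langcore("`core_frois` must be a subset of the catalog fROIs.", "invalid_spec")
  }
  if (!is.null(peripheral_froi) && !(peripheral_froi %in% core_frois)) {
    abort_langcore("`peripheral_froi` must be one of `core_frois`.", "invalid_spec")
  }
  if (n_subjects < 1L) {
    abort_langcore("`n_subjects` must be at least 1.", "invalid_spec")
  }
  if (p_dropout < 0 || p_dropout > 1 || fraction_inactive < 0 || fraction_inactive > 1) {
    abort_langcore("`p_dropout` and `fraction_inactive` must lie in [0, 1].",
                   "invalid_spec")
  }
  if (sigma_noise <= 0) {
    abort_langcore("`sigma_noise` must be positive.", "invalid_spec")
  }
  if (beta_active < 0 || rho_within < 0 || rho_core < 0 || rho_peripheral < 0 ||
      latent_sd < 0) {
    abort_langcore("Amplitudes and loadings must be non-negative.", "invalid_spec")
  }
  if (!"obligatory" %in% names(froi_catalog)) {
    froi_catalog$obligatory <- froi_catalog$froi %in% core_frois
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      froi_catalog = froi_catalog,
      core_frois = core_frois,
      peripheral_froi = peripheral_froi,
      beta_active = beta_active,
      sigma_noise = sigma_noise,
      rho_within = rho_within,
      rho_core = rho_core,
      rho_peripheral = rho_peripheral,
      latent_sd = latent_sd,
      p_dropout = p_dropout,
      fraction_inactive = fraction_inactive,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects, %d fROIs (%d core), seed %d\n",
    x$n_subjects, nrow(x$froi_catalog), length(x$core_frois), x$seed
  ))
  invisible(x)
}

#' Simulate one subject's BOLD data
#'
#' Draws one subject from the generative model described in [cohort_spec()]:
#' activated fROIs are chosen (obligatory fROIs always, others dropped with
#' probability `p_dropout`), per-fROI voxel counts are drawn uniformly from
#' the catalog ranges, and each voxel's time series combines the task
#' regressor, the fROI latent, the shared core latent (core fROIs only) and
#' i.i.d. Gaussian noise. Ground-truth activity and amplitude are recorded
#' per voxel.
#'
#' @param spec A [cohort_spec()].
#' @param design A [task_design()].
#' @param hrf HRF kernel from [canonical_hrf()].
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Subject identifier string.
#' @return An object of class `subject_data`: list with `subject_id`, the
#'   `bold` matrix (voxels x volumes), and a `voxels` tibble
#'   (`voxel_id`, `froi`, `truth_active`, `truth_beta`).
#' @examples
#' subj <- simulate_subject(cohort_spec(seed = 7), task_design(), subject_seed = 1)
#' dim(subj$bold)
#' @export
simulate_subject <- function(spec, design, hrf = canonical_hrf(design$tr_seconds),
                             subject_seed, subject_id = sprintf("sub-%03d", subject_seed)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "task_design"))
  r <- make_regressor(design, hrf)
  n_vol <- design$n_volumes
  cat <- spec$froi_catalog

  with_seed_(subject_seed, {
    present <- cat$obligatory | (stats::runif(nrow(cat)) >= spec$p_dropout)
    cat <- cat[present, , drop = FALSE]
    sizes <- purrr::map2_int(cat$min_voxels, cat$max_voxels,
                             function(a, b) a + sample.int(b - a + 1L, 1L) - 1L)
    n_vox <- sum(sizes)
    froi <- rep(cat$froi, sizes)
    is_core <- rep(cat$froi %in% spec$core_frois, sizes)

    core_loading <- ifelse(is_core, spec$rho_core, 0)
    if (!is.null(spec$peripheral_froi)) {
      core_loading[froi == spec$peripheral_froi] <- spec$rho_peripheral
    }

    truth_active <- stats::runif(n_vox) >= spec$fraction_inactive
    truth_beta <- ifelse(truth_active, spec$beta_active, 0)

    # latent series: per-fROI factor and one shared core factor, each the
    # regressor plus white noise
    g <- sapply(cat$froi, function(f) r + rnorm(n_vol, 0, spec$latent_sd))
    h <- r + rnorm(n_vol, 0, spec$latent_sd)

    signal <- outer(truth_beta, r) +
      spec$rho_within * t(g)[match(froi, cat$froi), , drop = FALSE] +
      outer(core_loading, h)
    bold <- signal + matrix(rnorm(n_vox * n_vol, 0, spec$sigma_noise),
                            nrow = n_vox)
    dimnames(bold) <- NULL

    structure(
      list(
        subject_id = subject_id,
        bold = bold,
        voxels = tibble(
          voxel_id = seq_len(n_vox) - 1L,
          froi = froi,
          truth_active = truth_active,
          truth_beta = truth_beta
        )
      ),
      class = "subject_data"
    )
  })
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf(
    "<subject_data> %s: %d voxels x %d volumes, %d fROIs\n",
    x$subject_id, nrow(x$bold), ncol(x$bold), dplyr::n_distinct(x$voxels$froi)
  ))
  invisible(x)
}

#' Simulate a whole cohort
#'
#' Draws `spec$n_subjects` subjects with per-subject seeds derived
#' deterministically from `spec$seed`, so the same spec always yields a
#' bit-identical cohort.
#'
#' @inheritParams simulate_subject
#' @return A named list of [simulate_subject()] results.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 3, seed = 2), task_design())
#' names(cohort)
#' @export
simulate_cohort <- function(spec, design, hrf = canonical_hrf(design$tr_seconds)) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, "simulate_cohort", spec$n_subjects)
  subjects <- purrr::imap(
    seeds,
    function(s, i) simulate_subject(spec, design, hrf,
                                    subject_seed = s,
                                    subject_id = sprintf("sub-%03d", i))
  )
  setNames(subjects, purrr::map_chr(subjects, "subject_id"))
}
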