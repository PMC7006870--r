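#' Configure the end-to-end pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' All randomness downstream is derived from `seed` plus a stage label, so a
#' config determines the full run.
#'
#' @param cohort A [cohort_spec()] (used when simulating), or `NULL` when
#'   reading subjects from `input_dir`.
#' @param design A [task_design()].
#' @param input_dir Directory of `*_bold.tsv` / `*_labels.tsv` pairs, or
#'   `NULL` to simulate the cohort.
#' @param output_dir Directory for TSV/GraphML/JSON outputs, or `NULL` to
#'   keep results in memory only.
#' @param theta Correlation threshold for the voxel network.
#' @param deltas Relative threshold perturbations for the rich-club sweep.
#' @param p_thresh,q_thresh Activation thresholds.
#' @param presence_fraction Common-network persistence rule parameter.
#' @param denominator Common-weight denominator mode; see
#'   [build_common_network()].
#' @param exclude_frois fROIs dropped after activation (the visual/auditory
#'   exclusion analogue).
#' @param occupancy_frois fROIs analysed in the k-shell occupancy stage;
#'   `NULL` means the common-network fROIs found in the run.
#' @param n_bins Occupancy bins.
#' @param n_perm Label permutations for the occupancy null.
#' @param n_null,n_swaps Rich-club null replication controls.
#' @param richclub_subject Subject id (or index) for the rich-club sweep;
#'   defaults to the first subject.
#' @param seed Master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            design = task_design(),
                            input_dir = NULL,
                            output_dir = NULL,
                            theta = 0.7,
                            deltas = c(-0.05, 0, 0.05),
                            p_thresh = 1e-4,
                            q_thresh = 1e-3,
                            presence_fraction = 0.85,
                            denominator = "possessors",
                            exclude_frois = character(0),
                            occupancy_frois = NULL,
                            n_bins = 10L,
                            n_perm = 199L,
                            n_null = 100L,
                            n_swaps = NULL,
                            richclub_subject = 1L,
                            seed = 1L) {
  if (theta <= 0 || theta >= 1) {
    abort_langcore("`theta` must lie in (0, 1).", "invalid_config")
  }
  if (p_thresh <= 0 || p_thresh >= 1 || q_thresh <= 0 || q_thresh >= 1) {
    abort_langcore("`p_thresh` and `q_thresh` must lie in (0, 1).", "invalid_config")
  }
  if (presence_fraction <= 0 || presence_fraction > 1) {
    abort_langcore("`presence_fraction` must lie in (0, 1].", "invalid_config")
  }
  if (n_bins < 1L || n_perm < 1L || n_null < 1L) {
    abort_langcore("Counts must be at least 1.", "invalid_config")
  }
  structure(
    list(cohort = cohort, design = design, input_dir = input_dir,
         output_dir = output_dir, theta = theta, deltas = deltas,
         p_thresh = p_thresh, q_thresh = q_thresh,
         presence_fraction = presence_fraction, denominator = denominator,
         exclude_frois = exclude_frois, occupancy_frois = occupancy_frois,
         n_bins = as.integer(n_bins), n_perm = as.integer(n_perm),
         n_null = as.integer(n_null), n_swaps = n_swaps,
         richclub_subject = richclub_subject, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> activation -> per-subject networks ->
#' common network -> strength rankings -> k-shell occupancy with its
#' permutation null -> rich-club sweep, and returns everything in one report
#' object. With `output_dir` set, per-subject networks, the common network,
#' rankings, the occupancy summary and a JSON report are written as
#' TSV/GraphML/JSON.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`: list with `subjects`
#'   (ids analysed), `activations`, `fnets`, `common`, `rankings`,
#'   `occupancy`, `occupancy_null`, `richclub`, `weight_distribution`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  regressor <- make_regressor(design)

  subjects <- if (is.null(config$input_dir)) {
    spec <- config$cohort
    spec$seed <- derive_seeds(config$seed, "simulate")[1L]
    simulate_cohort(spec, design)
  } else {
    bolds <- sort(list.files(config$input_dir, pattern = "_bold\\.tsv$",
                             full.names = TRUE))
    if (length(bolds) == 0L) {
      abort_langcore("No *_bold.tsv files found in `input_dir`.", "invalid_config")
    }
    subs <- purrr::map(bolds, function(b) {
      read_subject(b, sub("_bold\\.tsv$", "_labels.tsv", b))
    })
    setNames(subs, purrr::map_chr(subs, "subject_id"))
  }

  activations <- purrr::map(subjects, function(s) {
    activation_map(s, regressor = regressor,
                   p_thresh = config$p_thresh, q_thresh = config$q_thresh)
  })

  vnets <- purrr::map2(subjects, activations, function(s, a) {
    build_voxel_network(s, a, theta = config$theta,
                        exclude_frois = config$exclude_frois)
  })
  fnets <- purrr::map(vnets, function(v) {
    if (is.null(v)) NULL else normalize_weights(aggregate_froi(v))
  })

  common <- build_common_network(fnets,
                                 presence_fraction = config$presence_fraction,
                                 denominator = config$denominator)

  rankings <- purrr::imap_dfr(purrr::compact(fnets), function(f, id) {
    rank_froi_strength(f, frois = common$nodes$froi) %>%
      mutate(subject = id, .before = 1L)
  })

  assignments <- purrr::map(purrr::compact(vnets), function(v) {
    normalized_shells(core_decompose(v))
  })
  occ_frois <- config$occupancy_frois %||% common$nodes$froi
  occupancy <- occupancy_by_froi(assignments, froi_filter = occ_frois,
                                 n_bins = config$n_bins)
  occupancy_null <- null_occupancy(
    assignments, n_perm = config$n_perm,
    seed = derive_seeds(config$seed, "occupancy_null")[1L],
    froi_filter = occ_frois, n_bins = config$n_bins
  )

  rc_id <- if (is.numeric(config$richclub_subject)) {
    names(subjects)[config$richclub_subject]
  } else {
    config$richclub_subject
  }
  richclub <- threshold_sensitivity(
    subjects[[rc_id]], activations[[rc_id]],
    theta0 = config$theta, deltas = config$deltas,
    n_null = config$n_null, n_swaps = config$n_swaps,
    seed = derive_seeds(config$seed, "rich_club")[1L],
    exclude_frois = config$exclude_frois
  )

  report <- structure(
    list(
      subjects = names(subjects),
      activations = activations,
      fnets = fnets,
      common = common,
      rankings = rankings,
      occupancy = occupancy,
      occupancy_null = occupancy_null,
      richclub = richclub,
      weight_distribution = pooled_weight_distribution(fnets),
      config = config
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, theta = %g\n",
              length(x$subjects), x$config$theta))
  print(x$common)
  invisible(x)
}

# Write the report's tabular pieces under `dir`.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(report$common, file.path(dir, "common_network"))
  readr::write_tsv(report$rankings, file.path(dir, "froi_strength_rankings.tsv"))
  readr::write_tsv(report$occupancy$histogram, file.path(dir, "kshell_occupancy.tsv"))
  readr::write_tsv(as_tibble(report$occupancy_null),
                   file.path(dir, "kshell_occupancy_null.tsv"))
  purrr::iwalk(report$richclub$curves, function(curve, key) {
    readr::write_tsv(as_tibble(curve),
                     file.path(dir, sprintf("richclub_%s.tsv",
                                            gsub("[^0-9a-zA-Z+-]", "", key))))
  })
  jsonlite::write_json(
    list(
      n_subjects = length(report$subjects),
      theta = report$config$theta,
      seed = report$config$seed,
      presence_fraction = report$config$presence_fraction,
      common_network = report$common$edges,
      max_shell = report$occupancy$max_shell,
      occupancy_null = as_tibble(report$occupancy_null),
      richclub_increasing = report$richclub$summary$increasing,
      weight_skewness = report$weight_distribution$skewness
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
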