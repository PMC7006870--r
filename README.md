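# langcore

Reconstructing the **core language network** from task-based fMRI functional
connectivity, in R.

## The problem

Clinical language tasks (covert verb generation and its relatives) are used
before neurosurgery to map the language-sensitive cortex. Beyond the
activation map, the *functional links* between language areas matter: a
network built from a patient's BOLD correlations can be compared against the
network that healthy subjects consistently exhibit for the same task, and
missing areas or links indicate functional damage. `langcore` implements the
healthy-benchmark side of that comparison:

- **Activation mapping.** Per-voxel Pearson correlation with the
  HRF-convolved block regressor, p-values from the exact t-transform
  (one-sided, uncorrected p < 10⁻⁴ by default), Benjamini–Hochberg
  q-values as the FDR diagnostic.
- **Individual networks.** Voxel-level graphs from thresholded pairwise
  correlations, `C_ij ≥ θ` (absolute threshold, default θ = 0.7), aggregated
  to fROI level with weights `W_ij = #links / (size_i + size_j)` and the
  per-subject normalization `W̃_ij = W_ij / W_max` (so every subject's
  maximum weight is exactly 1).
- **Common network.** The group-level graph of fROIs and links present in at
  least `⌈0.85 N⌉` subjects, with weights `W^C = mean of W̃` across the
  subjects possessing each link, ± SD.
- **k-core occupancy.** Iterative-pruning core numbers per voxel, normalized
  per subject by `kcore_max`, pooled per-fROI shell occupancy, and a
  voxel-label permutation null for max-shell enrichment.
- **Rich club.** `φ(k) = 2E_{>k} / [N_{>k}(N_{>k}−1)]` with
  degree-preserving rewiring nulls and a ±5% threshold-sensitivity sweep.

A synthetic cohort generator (`cohort_spec()`, `simulate_cohort()`) plants a
known five-area core — op-BA, tri-BA, WA (peripheral), preMA, pre-SMA —
inside a realistic block-design cohort, so the full pipeline is testable
end-to-end without scanner data. See the methods vignette
(`vignettes/language-network-methods.Rmd`) for the generative model and all
parameter choices.

## Worked example

```r
library(langcore)

design <- task_design()                       # 6 epochs, 10 s rest / 10 s task, TR 2 s
cohort <- simulate_cohort(cohort_spec(n_subjects = 20, seed = 1), design)
regressor <- make_regressor(design)

fnets <- lapply(cohort, function(s) {
  build_froi_network(s, activation_map(s, regressor = regressor), theta = 0.7)
})
common <- build_common_network(fnets, presence_fraction = 0.85)
common
#> <common_network> 5 fROIs, 10 links (presence >= 17/20 subjects)
#> # A tibble: 10 × 5
#>    froi_i  froi_j    W_C    sd n_present
#>    <chr>   <chr>   <dbl> <dbl>     <int>
#>  1 op-BA   WA      0.191 0.177        20
#>  2 op-BA   pre-SMA 0.806 0.171        20
#>  3 op-BA   preMA   0.766 0.146        20
#>  4 op-BA   tri-BA  0.813 0.155        20
#>  5 pre-SMA WA      0.221 0.212        20
#>  ...
```

The recovered common network is exactly the planted five-area core. Links
among the strongly coupled areas carry high mean weights (`W^C ≈ 0.77–0.87`)
with subject-to-subject SDs of comparable order — the long-tailed
intersubject variability the pooled weight distribution
(`pooled_weight_distribution()`) makes explicit — while the peripheral WA
attaches through much weaker links (`W^C ≈ 0.19–0.24`).

```r
vnets   <- lapply(cohort, function(s)
  build_voxel_network(s, activation_map(s, regressor = regressor), theta = 0.7))
assigns <- lapply(vnets, function(v) normalized_shells(core_decompose(v)))
occupancy_by_froi(assigns, froi_filter = common$nodes$froi)
#> <occupancy_histogram> 5 fROIs, 10 bins
#> # A tibble: 5 × 4
#>   froi    n_voxels n_max_shell fraction_max_shell
#>   <chr>      <int>       <int>              <dbl>
#> 1 WA           443          23             0.0519
#> 2 op-BA        440         352             0.8
#> 3 pre-SMA      465         410             0.882
#> 4 preMA        424         367             0.866
#> 5 tri-BA       457         392             0.858
```

80–88% of op-BA, tri-BA, preMA and pre-SMA voxels sit in their subject's
maximum k-shell (the most resilient substructure of the network), versus 5%
for WA, which populates lower shells — and the label-permutation null
(`null_occupancy()`, null mean ≈ 0.30 for every area) confirms the contrast
is not a size artifact (permutation p = 0.01 at 199 permutations).

`run_pipeline(pipeline_config(...))` chains all stages, writes TSV/GraphML
outputs plus a JSON report, and is fully reproducible from one master seed.
Every result type has `tidy()`, `glance()` and `autoplot()` methods.

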