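---
title: "Methods: from task BOLD series to the core language network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from task BOLD series to the core language network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langcore)
library(dplyr)
```

## The problem

Task-based fMRI of clinical language paradigms (e.g. covert verb generation)
produces, per subject, a BOLD time series for every voxel and an activation
map locating the voxels driven by the task. Presurgical planning cares about
more than the map: it needs to know which functional *links* between language
areas persist across healthy individuals, because a patient network missing
one of those links signals damage. `langcore` implements that analysis as a
pipeline:

1. **Activation mapping** — per-voxel association with the task regressor,
   thresholded at uncorrected p, with FDR diagnostics.
2. **Individual networks** — thresholded Pearson correlation among active
   voxels (voxel level), aggregated into weighted fROI networks.
3. **Group analysis** — the *common network* of areas and links present in
   nearly all subjects, with averaged weights.
4. **k-core occupancy** — which areas populate the innermost, most resilient
   k-core of each individual network, against a label-permutation null.
5. **Rich-club analysis** — whether hubs are more densely interconnected than
   degree alone requires, and whether that conclusion survives threshold
   perturbation.

Because real scanner data cannot ship with a package, a synthetic cohort
generator with planted ground truth drives all tests and examples.

## Task design and regressor

The default design is a six-epoch block paradigm: each epoch is 10 s rest
followed by 10 s task. We sample it at TR = 2 s (5 + 5 volumes per epoch, 60
volumes total) so that block boundaries align with volume boundaries;
acquisitions with non-integer volumes per block would need edge handling that
adds nothing to the method. The boxcar is convolved with a canonical
double-gamma haemodynamic response function (peak 6 s, undershoot 16 s, unit
dispersions, undershoot ratio 1/6, 32 s support, peak-normalized). The HRF
family is configurable through `hrf_spec()` since "canonical" conventions
differ across software; the double-gamma default is the most widely used
parameterization. Note the convolved regressor can dip slightly below zero
after task offset — that is the HRF undershoot, not an error; non-negativity
holds only for non-negative kernels.

## The synthetic cohort generator

For voxel $v$ in fROI $f$ the generator draws

$$x_v(t) = \beta_v\, r(t) + \rho_w\, g_f(t) + \rho_{c,f}\, h(t) + \varepsilon_v(t),$$

where $r$ is the task regressor, $g_f = r + \eta_f$ is a per-fROI latent
series, $h = r + \eta_h$ is a single latent shared by the planted core
areas, $\eta \sim N(0, \sigma_\ell^2)$ white noise, and
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. noise. $\beta_v$ equals
`beta_active` for active voxels (a `fraction_inactive` share of voxels gets
$\beta_v = 0$), and $\rho_{c,f}$ is `rho_core` for core areas,
`rho_peripheral` for the designated peripheral core area, 0 elsewhere.
Latent-factor coupling (rather than an explicit covariance matrix) keeps
generation O(voxels) and guarantees a positive semidefinite, all-positive
correlation structure — matching the empirical fact that correlations among
voxels driven by a common external stimulus come out positive.

The default catalog plants the five-area core of the verb-generation
literature — `op-BA`, `tri-BA`, `WA`, `preMA`, `pre-SMA` — among nine weakly
coupled background areas, with 20 subjects and roughly 300 voxels per
subject. `WA` is designated *peripheral*: it participates in the core latent
with an attenuated loading, so its fROI-level links to the core persist
(thousands of voxel pairs only need one supra-threshold correlation) while
its voxels accumulate too few edges to reach the innermost k-core — the
qualitative signature reported for Wernicke's area.

Default parameters were solved analytically from the model above (with the
regressor variance $\approx 1.41$ of the default design) and fixed once:

| parameter | default | resulting population quantity |
|---|---|---|
| `beta_active` | 0.5 | voxel-regressor correlation ≈ 0.63 (effect d ≈ 1.5) |
| `sigma_noise` | 0.75 | — |
| `rho_within` | 0.2 | within-fROI (background) correlation ≈ 0.67 |
| `rho_core` | 0.4 | core-core voxel correlation ≈ 0.77 (within ≈ 0.87) |
| `rho_peripheral` | 0.18 | WA-core voxel correlation ≈ 0.65 |
| `latent_sd` | 3.3 | keeps inactive voxels near-uncorrelated with the task |
| `p_dropout` | 0.1 | a non-obligatory area absent in ~2 of 20 subjects |
| `fraction_inactive` | 0.15 | — |

Large latent noise (`latent_sd`) matters: inactive voxels still load the
latents, and since each latent contains the regressor, a small latent noise
would make "inactive" voxels strongly task-correlated, erasing the ground
truth the generator exists to plant.

**Dropout.** `p_dropout` removes whole non-obligatory fROIs per subject,
emulating how missing activation manifests in group analysis. Core areas are
obligatory by default: a persistent-core recovery experiment needs the core
present, and a user who wants to emulate subjects missing core activation
(as a few individuals in any real cohort do) can clear the `obligatory` flag
in the catalog.

**What the generator does not emulate:** spatial structure (no voxel
geometry, smoothing or motion), scanner drift and physiological noise,
hemispheric lateralization, and between-subject variation in HRF shape or
effect size. Passing tests therefore demonstrate that the pipeline's
*inference machinery* is correct under a known truth, not that real
acquisitions meet its assumptions.

## Activation mapping

The per-voxel statistic is the Pearson correlation of the BOLD series with
the regressor; for a single regressor plus intercept this equals the GLM
t-test on the slope, and the p-value uses the exact
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ transform. The test is one-sided by default
(activation is a positive association; two-sided available). Voxels with
zero variance get $r$ = NA, $p = 1$ and a warning, instead of silent NaN.
Thresholds follow clinical practice: uncorrected $p < 10^{-4}$ selects
voxels, and the step-up Benjamini-Hochberg q-values provide the FDR
diagnostic ($q < 10^{-3}$).

## Individual networks

Voxel networks connect active-voxel pairs whose correlation
$C_{ij}$ (temporal-moment form, full run) meets an **absolute threshold**
$\theta$; correlations are signed, so anticorrelations never form edges, and
ties at exactly $\theta$ are included. The literature rarely prints its
threshold; we make it an explicit, sweepable parameter with default 0.7 and
a ±5% sensitivity sweep built in. Isolated voxels stay in the node set so
fROI sizes equal analyzed voxel counts. Constant-series voxels were already
excluded by the activation stage, keeping sizes consistent.

At the fROI level, areas $i, j$ are linked iff at least one voxel-level
edge crosses between them, with weight
$W_{ij} = \#\text{links}/(\text{size}_i + \text{size}_j)$ and the
per-subject normalization $\tilde W_{ij} = W_{ij}/W^{\max}$, which puts all
subjects on the same scale with maximum exactly 1.

## Group analysis

A link (and its endpoint areas) enters the common network when present in at
least $\lceil 0.85 N\rceil$ subjects — 17 of 20 at the default cohort size,
the persistence level at which a five-area core is typically reported. The
common weight averages $\tilde W$ **over the subjects that possess the
link**; averaging over all $N$ (the literal reading of a cohort-mean formula)
is available via `denominator = "all"`, but the possessor average is the
default because reported group weights in this literature are possessor
averages. SD is the sample (n−1) SD, defined as 0 with a degeneracy flag
when only one subject possesses a link. Node retention requires both enough
activation presence and one retained incident link, so no isolated areas
appear.

## k-core occupancy

Core numbers come from standard iterative pruning of each subject's voxel
graph (including within-fROI edges; weights ignored). Because subjects
differ in their maximal core $k_{core}^{max}$, shell values are normalized
per subject by $k_{core}^{max}$, mapping every top shell to 1 before
pooling. Occupancy uses 10 equal-width bins on $(0,1]$ (top bin $(0.9,1]$);
isolated voxels (core 0) fall in the bottom bin. The null model permutes
voxel-to-fROI labels within each subject — preserving per-subject topology,
core numbers and fROI sizes, the only structure the observed statistic
conditions on — then re-pools. The permutation p is two-sided with the
add-one estimator $(b+1)/(n_{perm}+1)$, which cannot return 0 at finite
$n_{perm}$.

## Rich club

$\phi(k) = 2E_{>k}/[N_{>k}(N_{>k}-1)]$ with degrees for the $>k$ filter
taken in the original graph (the standard convention; filtering by residual
degree would change the quantity). $\phi$ is undefined and omitted when
fewer than 2 nodes survive. The null rewires with double-edge swaps
preserving the degree sequence; defaults are 10× the edge count of swap
attempts and 100 null graphs — common mixing heuristics, stated explicitly
because the literature rarely does. The threshold sweep rebuilds the voxel
network at $\theta(1\pm 5\%)$ and summarizes each curve by the sign of the
least-squares slope of $\phi/\phi_{rand}$ against $k$.

## Numerical choices and degenerate inputs

- Edgeless fROI networks normalize to an empty result with a warning and are
  excluded from the group stage (N shrinks accordingly).
- Edgeless voxel graphs have $k_{core}^{max} = 0$; shell normalization
  raises an error and the subject is skipped.
- Complete graphs admit no degree-preserving swap and are returned unchanged
  with a warning.
- All randomness flows through per-stage seeds derived from one master seed;
  identical configs give byte-identical outputs.
- Undirected edges are stored once with ordered endpoints; voxel ids are
  0-based in files.

## Problem sizes used in the test suite

The tests exercise the pipeline at the package's default study conditions:
20-subject cohorts of ~300 voxels × 60 volumes for end-to-end recovery (20
replicate cohorts), 10^5 null voxels for calibration, and a few hundred
random graphs (n ≤ 12) for the brute-force oracle comparisons. These sizes
give each Monte-Carlo check a 3-SE margin while keeping a full run in a few
minutes on one core.

## Known limitations

- fROI labels are an *input*; the package does not parcellate anatomy.
- No preprocessing (motion correction, detrending, smoothing) — inputs are
  assumed preprocessed.
- Correlation is computed over the full run, not task blocks only; for block
  designs with strong responses the distinction is minor, but it is a choice.
- No weighted (s-core) decomposition or weighted rich-club variants.

## A short worked example

```{r example, eval = FALSE}
design <- task_design()
cohort <- simulate_cohort(cohort_spec(n_subjects = 20, seed = 1), design)
regressor <- make_regressor(design)

fnets <- lapply(cohort, function(s) {
  build_froi_network(s, activation_map(s, regressor = regressor), theta = 0.7)
})
common <- build_common_network(fnets, presence_fraction = 0.85)
common
autoplot(common)
```
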