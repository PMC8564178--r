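---
title: "Methods: CBF, FCS, and neurovascular coupling across WMH groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBF, FCS, and neurovascular coupling across WMH groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical decisions,
and limitations behind `neurocouple`. The package implements an analysis of
neurovascular coupling — the association between cerebral blood flow (CBF)
and functional connectivity strength (FCS) — across groups of subjects with
mild, moderate, and severe white-matter-hyperintensity (WMH) load, together
with the synthetic cohort generator that makes the whole chain testable
without scanner data.

## The measurement chain

### CBF from pCASL

The quantification is the standard single-compartment model for
pseudo-continuous labeling. With ΔM the voxelwise mean of control − label
differences and PD the proton-density reference,

$$\mathrm{CBF} \;=\; \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
{2\,\alpha\,T_{1b}\,\mathrm{PD}\,\bigl(1 - e^{-\tau/T_{1b}}\bigr)}
\quad [\mathrm{ml}/100\mathrm{g}/\mathrm{min}],$$

with defaults λ = 0.9 ml/g (blood–brain partition coefficient), α = 0.85
(labeling efficiency, applied globally), T1b = 1.65 s (arterial blood T1),
τ = 1.45 s (labeling duration), PLD = 2.025 s (post-label delay; the
acquisition's inversion time is read as the post-label delay). All are
overridable via `asl_params()`. Assumptions: single well-mixed tissue
compartment, complete label delivery by the PLD, no partial-volume
correction (deliberately, matching common practice for this analysis).
Noise can drive quantified CBF negative; values are floored at 0 and the
count logged, because downstream statistics assume nonnegative perfusion.

### Temporal BOLD preprocessing

The stage order is fixed: discard the first 10 frames (magnetization
equilibration), regress nuisance signals (intercept, linear trend, mean
white-matter and CSF signals, rigid-body motion parameters) by ordinary
least squares, then band-pass 0.01–0.08 Hz. Reordering regression and
filtering changes the result (an integration test asserts this on a series
with a known trend); regression first removes the trend exactly.

Two genuinely open readings were settled as follows:

- *Motion regressors*: descriptions of "motion at the x-, y-, and z-axes"
  are ambiguous between 3 translations and all 6 rigid-body parameters. The
  default is all 6 (field standard); `nuisance_set()` accepts any subset of
  columns, preserving the literal 3-translation reading.
- *Band-pass implementation*: a zero-phase DFT filter with even (reflection)
  extension of each series. The contract is spectral, not
  implementation-specific: in-band amplitudes preserved within 5%, stopband
  (≥ 2× the upper edge) attenuated ≥ 90%, DC removed; the tests assert
  exactly that, so a different filter meeting the contract would also pass.

Motion QC: framewise displacement uses the Power-style formulation
`FD_t = Σ|Δtrans| + r Σ|Δrot|` with rotations converted from degrees to
radians on an r = 50 mm sphere, and the exclusion rule is "no more than
3 mm / 3°" — boundary values pass, strictly larger values fail.

### FCS

For gray-matter voxel *i*,
$$\mathrm{FCS}_i = \frac{1}{N-1} \sum_{j \ne i} r_{ij}\,[r_{ij} \ge r_0],
\qquad r_0 = 0.2 .$$

Decisions: correlations *lower than* the threshold are zeroed, so
`r = 0.2` exactly survives (asserted at the boundary); the divisor is all
remaining voxels N − 1, so FCS ∈ [0, 1], with the alternative
suprathreshold-only divisor available via `denominator =
"suprathreshold"` — the text this follows does not determine which of the
two its authors used, so both are implemented and the literal reading is
the default. Pearson correlations and z-scores use the sample (n − 1)
convention throughout. Voxels with zero temporal variance cannot be
correlated; they are dropped from the mask with a logged count rather than
poisoning the map. No spatial smoothing is applied before FCS; smoothing
belongs to the coupling stage only.

### CBF–FCS coupling

Per subject, both maps are smoothed with a 6-mm FWHM Gaussian
(σ = FWHM / 2√(2 ln 2) per axis, in mm), z-scored within the gray-matter
mask, and correlated across in-mask voxels — one global coupling
coefficient per subject, plus one per atlas region. The smoothing kernel is
mask-renormalized: out-of-mask voxels carry zero weight, so constants are
preserved and nothing bleeds across the mask edge.

The regional definition needed a decision: within a single subject there is
no per-voxel coupling coefficient to average (each voxel contributes one
CBF/FCS pair), so "regional coupling" is computed as the across-voxel
correlation within the region, per subject — the reading consistent with
comparing regional coupling *between groups of subjects*. The
across-subject per-voxel alternative (a group-level coupling map) is
provided as `coupling_group_map()` but is not part of the default pipeline.
Regions with fewer than 3 in-mask voxels are reported missing, never
fabricated.

## Group inference

Demographics are compared with the test a clinical Table 1 would use: χ²
(Pearson, no continuity correction) for categorical rows, one-way ANOVA or
Kruskal–Wallis for continuous ones, selectable per variable (published
tables mix the two without stating why; the choice is therefore exposed
rather than hard-coded). A summary-statistic ANOVA
(`oneway_anova_summary()`) reproduces the raw-data decomposition exactly
and lets published n/mean/SD rows serve as worked examples.

Region-wise group comparisons use a partial F for the group factor over
covariates (age, sex; covariates are mean-centered, which changes nothing
testable but stabilizes conditioning). The permutation scheme is
Freedman–Lane: residuals of the covariate-only model are permuted and added
back to its fitted values, so the null respects the covariates; plain label
permutation is available via `scheme = "labels"`. p-values use the add-one
convention `p = (1 + #{F* ≥ F}) / (1 + n_perm)` and are therefore never
zero and reproducible given the seed. Post-hoc pairwise contrasts run only
when the omnibus test passes α = 0.01 (standard post-hoc usage). No
multiple-comparison correction is applied across regions by default — the
emulated analysis deliberately reports uncorrected permutation p-values at
a strict α — but `fdr = TRUE` adds Benjamini–Hochberg values.

Cognition raw scores are z-scored against the whole cohort and sign-flipped
for time-scored tests (trail-making, seconds, larger = worse) so higher z
always means better performance.

## Mediation

Simple mediation X → M → Y (lesion load → regional CBF → cognition) with
the same covariates (age, sex, education) in every OLS equation, so the
decomposition `c = c' + a·b` is an algebraic identity (asserted at 1e−10 on
every fit). Inference on the indirect effect is a percentile bootstrap
(default n = 5,000 resamples of whole subject rows), significant when the
95% interval excludes zero; the percentile flavor is the default because
that is the common default in the macro this emulates, with
bias-corrected-and-accelerated intervals behind `ci_type = "bca"`. Lesion
load (Fazekas 1–6) enters as a numeric predictor. Degenerate resamples
(constant predictor or mediator) are redrawn and counted.

## The synthetic cohort generator

The generator's defaults *are* the emulated study conditions: three groups
of 32/24/30 subjects; BOLD with TR 2 s and 130 frames of which 10 are
discarded; global coupling targets ρ = 0.225 / 0.209 / 0.156
(mild/moderate/severe); hub-region CBF deficits of 0 / 0.6 / 1.2 SD
(the severe-group effect size is the anchor; the moderate group sits
halfway, monotone with load); vascular-risk prevalences, demographics, and
cognition score distributions shaped like a clinical Table 1, with
timed tests generated on a seconds scale to exercise the z-score sign flip.
The default grid is 18³ with a 1-voxel non-gray border (4,096 gray-matter
voxels) and 24 block-shaped regions, 25% flagged as hubs.

Key construction choices:

- *Coupling by construction.* CBF z-maps are generated as
  `ρ·fcs_z + √(1−ρ²)·ε` and only affine maps follow (rescale to mean 50,
  SD 10 ml/100g/min), so ρ is exactly the population value of the global
  coupling statistic. Parameter recovery is therefore a clean acceptance
  surface: the recovery experiment applies the coupling statistic directly
  to the generated z-maps, without smoothing — smoothing exists to suppress
  measurement noise in estimated maps, and on spatially structured maps it
  would change the expected correlation, clouding what the experiment
  measures.
- *Hub deficits act on CBF only* in the default pipeline. An optional
  `group_effect` argument of `generate_subject_bold()` can additionally
  attenuate hub community weights (reducing hub FCS), but it is off by
  default: routing the lesion effect through both maps makes the two maps
  co-vary through the lesion pattern, which inflates measured coupling with
  load and spreads group effects over non-hub regions — the opposite of the
  targeted structure.
- *ASL noise is additive Gaussian on frames*, not physiological: the
  quantification is a deterministic map, so the property that matters is
  unbiased round-trip recovery, which additive noise exercises directly.
- *Determinism.* Every randomized operation takes an explicit seed; a
  cohort derives per-subject, per-purpose sub-seeds from one master seed,
  so full generation is bit-reproducible.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: MR physics and artifacts, spatial registration
error, partial-volume effects, physiological noise spectra, lesion
geometry (lesion load enters only as the Fazekas covariate/grouping, as in
the emulated analysis), and realistic spatial autocorrelation of
gray matter. Results on real cohorts depend on preprocessing choices this
package deliberately leaves out of scope (slice timing, realignment,
normalization).

## Numerical choices and degenerate inputs

- Gaussian kernels are truncated at 4σ and renormalized; `fwhm = 0` is the
  exact identity.
- The FFT band-pass uses an even reflection extension (length 2n), which
  keeps the filter zero-phase and the extension continuous at both ends.
- OLS residuals are computed through QR; rank deficiency is an error that
  names the collinear columns rather than a silent drop.
- Permutation and bootstrap p-values/CIs use add-one and type-6 quantile
  conventions respectively; with a fixed seed both are exactly
  reproducible.
- Constant maps cannot be z-scored (error); regions with < 3 voxels yield
  `NA` coupling; zero-variance BOLD voxels are dropped with a count;
  degenerate bootstrap resamples are redrawn with a count.
- Grids are index-addressed; every input must share one grid, and grid
  mismatches are validation errors that name the offending subject.

## Simulation sizes

The test suite and `scripts/acceptance.R` use: 100 simulated cohorts for
coupling-target recovery and ordering; 1,000 null regions (n_perm = 1,000)
for the permutation type-I rate and 200 effect regions for power; 400
datasets for bootstrap type-I rate and 500 for CI coverage, at 1,000
bootstrap resamples per dataset — CI calibration is a property of the
percentile method, not of the resample count, so the default of 5,000
resamples applies to analyses while calibration studies use 1,000; and one
full end-to-end run at the default cohort (86 subjects, 18³ grid, 1,000
permutations, 5,000 bootstrap resamples).

## Known limitations

- FCS is O(N²) in in-mask voxels (the full correlation matrix is formed);
  the default synthetic grids keep this cheap, but whole-brain 3-mm real
  data (~50k voxels) would need a blocked implementation.
- The single-compartment model ignores arterial transit effects and
  assumes one global labeling efficiency.
- Regional coupling on small regions is noisy; the < 3 voxel guard is a
  floor, not a cure.
- Mediation here quantifies association, not causation: the model is
  an OLS path decomposition with resampling inference, and the lesion-load
  predictor is observational.
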