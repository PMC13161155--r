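---
title: "Single-cell Raman chemometrics for therapy-response classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell Raman chemometrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Single-point Raman spectra of individual bone-marrow cells carry a
label-free fingerprint of the cell's biochemical composition: ring-breathing
modes of nucleic-acid bases, aromatic amino-acid bands, amide backbone
vibrations, acyl-chain modes of lipids, and skeletal carbohydrate modes all
fall in the 600–1800 cm^-1 fingerprint region. In acute myeloid leukemia,
cells from patients who go on to achieve complete remission (CR) after
induction therapy differ systematically in this fingerprint from cells of
non-remission (NR) patients. `ramanaml` implements the full analysis chain
for this discrimination problem — spectral preprocessing, PCA-LDA
classification with cross-validation and permutation testing, MCR-ALS
pure-component resolution, and characteristic-peak statistics — together
with a synthetic-data generator that emulates the statistical structure of
such a cohort and retains its ground truth, so every stage is testable
end to end.

# The synthetic cohort: what it emulates and what it does not

A measured single-cell spectrum is modeled as a bilinear mixture plus
additive interference:

    x_i = c_i' S  +  b_i  +  g_i * glass  +  eps_i

where `c_i >= 0` are per-cell component concentrations, the rows of
`S >= 0` are pure biochemical component spectra (protein,
lipid/carbohydrate, nucleic acid, and a mixed component, each rendered as a
sum of Lorentzian bands at the canonical fingerprint positions and
max-normalized to 1), `b_i` is a broad fluorescence baseline, `g_i` scales a
fixed glass-substrate reference, and `eps_i` is additive gaussian channel
noise. The bilinear core is exactly the model under which MCR-ALS is
well-posed; the interferents are exactly what the preprocessing chain is
built to remove.

Concentrations follow a two-level lognormal hierarchy: the group mean is
multiplied by a patient-level and a cell-level factor, each lognormal with
unit mean and configurable coefficient of variation (defaults 0.15 and
0.25). Lognormal factors keep concentrations positive and produce the
right-skewed cell-to-cell heterogeneity typical of single-cell data. The
default cohort shape matches the study design this pipeline targets: 9
patients per response group, 335 CR and 322 NR cell spectra, a 1761-channel
grid spanning 600–1800 cm^-1.

**The group contrast default is a calibration, not a biological claim.**
The direction of the contrast is fixed — protein elevated in CR,
lipid/carbohydrate and nucleic acid elevated in NR — but no quantitative
effect size is available to emulate. The default relative shift of 0.55 was
chosen once so that the full pipeline (preprocessing, in-fold component
selection, ten-fold PCA-LDA) operates in the reported single-cell
discrimination regime: at the default it attains a five-seed mean
cross-validated accuracy of ~0.89 and AUC of ~0.96. A 20% shift, for
comparison, yields only ~0.69 accuracy under the same heterogeneity. Users
probing other regimes should set `default_group_profiles(contrast = ...)`
explicitly.

Features of real data the generator deliberately omits: cosmic-ray spikes,
wavenumber miscalibration, instrument response and focal variation,
non-gaussian detector noise, and any correlation between components beyond
the shared patient effect. Passing recovery tests therefore demonstrates
the correctness of the algorithms under the model's assumptions, not
robustness to every artifact of a real instrument.

The fluorescence baseline is drawn per cell as
`amplitude * (exp(-t/tau) + offset)` with `t` the grid position rescaled to
[0, 1], `tau ~ U(0.5, 1.5)` and `offset ~ U(0.2, 1)` — a smooth, strictly
positive, monotone pedestal like the falling fluorescence background under
green excitation. Its curvature is bounded in closed form
(`baseline_curvature_bound()`), which the tests exploit. The glass
reference is a fixed mixture of three wide gaussians (200–250 cm^-1 FWHM)
normalized to unit maximum; per-cell glass scales are lognormal around the
configured amplitude.

# Preprocessing

Four steps run in fixed order per spectrum, then the set is cropped to
600–1800 cm^-1:

1. **Savitzky–Golay denoising** (`sg_denoise`), order 3, window 25
   channels. The filter reproduces polynomials up to its order exactly;
   edges are handled by the filter's transient matrices. When a clean
   reference is available (synthetic calibration), `select_sg_window()`
   picks the window minimizing RMSE, breaking ties toward the smallest
   window; the pipeline default stays at the fixed (25, 3).

2. **Glass-background removal** (`remove_glass_background`). Both the cell
   spectrum and the glass reference are reduced to their coarse wavelet
   approximation band — a periodic orthogonal DWT with the 16-tap symlet-8
   filter, implemented in-package, at depth 6 by default — and the cell's
   coarse band is regressed on the reference's coarse band with a single
   non-negative glass coefficient. Narrow Raman peaks live in the detail
   bands, so they cannot bias the fit; but the cell's own broad content
   (its fluorescence pedestal and the smooth envelope of dense overlapping
   bands) does reach the coarse band, so the regression includes a
   quadratic detrend in the grid position to absorb it. Without the
   detrend the glass scale is overestimated by 30–130% on realistic
   bilinear cells; with it, recovery is accurate to about ±0.03 in
   absolute scale units (within 10% for substantial substrate
   contributions). The glass reference's moderate structure (three humps,
   all well above Raman linewidths) is what keeps the glass coefficient
   identifiable against the polynomial.

3. **Fluorescence-baseline correction** (`correct_baseline_spline`). The
   spectrum is smoothed once with a zero-order Savitzky–Golay
   (moving-average) filter whose window is half the knot interval; then,
   iteratively, the minimum of the working curve within each equal
   interval (default 120 channels) becomes a knot, a cubic spline through
   the knots is the candidate baseline, and working points above the
   baseline are clamped down to it for the next round. The loop stops at a
   0.1% relative baseline change or 20 rounds. Two numerical choices
   matter here. First, smoothing once (rather than re-smoothing the
   suppressed curve each round) prevents a ratchet: re-smoothing a clamped
   curve walks the baseline downward by the averaging bias on every round,
   which on a pure smooth baseline accumulates to a ~15% error; smoothing
   once makes the pure-baseline case converge in two rounds with residuals
   of order the spline interpolation error. Second, the spline uses
   polynomial ("fmm") rather than natural end conditions — natural end
   conditions force zero curvature at the grid edges and systematically
   sag there on curved baselines. The corrected spectrum is clipped at 0
   so no negative intensities reach the non-negativity-constrained
   decomposition.

4. **Min–max normalization** (`minmax_normalize`) to [0, 1] per spectrum.
   Constant spectra are refused rather than silently mapped.

Cropping runs last; whether normalization preceded or followed cropping was
left open by the source protocol, and cropping-last is the convention here
(on the default grid the two coincide, as the grid already spans exactly
600–1800 cm^-1).

# PCA-LDA classification

PCA is computed on the covariance of the (already min-max normalized, hence
commensurate) spectra via mean-centered SVD, with a deterministic sign
convention (each loading's largest-magnitude element positive). The number
of retained components is the smallest k whose cumulative explained
variance exceeds 0.90. The discriminant is the two-class Fisher direction —
the pooled within-class scatter inverted via pseudo-inverse when singular —
with the decision threshold at the midpoint of projected class means (equal
priors; group sizes in the target design are near-equal, and the midpoint
makes separable toy cases exact). Higher decision scores indicate NR by
convention, and `decision_scores()` subtracts the threshold so 0 is always
the boundary.

Cross-validation is stratified by class with a seeded fold assignment; the
entire model — including the cumulative-variance component selection — is
refit inside each training fold, so selection cannot leak information from
held-out rows. Out-of-fold scores are pooled across folds and feed both the
confusion metrics (at the common 0 threshold) and the ROC curve; pooled
rather than fold-averaged metrics are reported because they are exact at
small fold sizes. The AUC is the rank (Mann–Whitney) estimator with
half-credit for ties, which the tests pin against the exhaustive pairwise
estimator.

The permutation test refits the full cross-validated model under randomly
permuted labels and uses the add-one p-value
`(1 + #{null >= observed}) / (1 + B)`, which cannot be exactly zero.
Patient-level aggregation (`patient_mean_spectra`) averages each patient's
cells and is the recommended unit for peak statistics, since cells within a
patient are not independent observations.

# MCR-ALS

The chemical rank is suggested at the largest elbow of the log singular
value spectrum (the maximum of its second difference); the full singular
spectrum is returned so the suggestion can be overridden — the documented
reproduction setting is k = 4. Initial pure spectra come from classical
determinant-based SIMPLISMA at 10% noise: variable purity is the
standard-deviation-to-offset-mean ratio, deflated after each selection by
the determinant weight on the length-scaled correlation-around-origin
matrix so successive pure variables are mutually independent. Channel
(pure-variable) mode is the default — pure wavenumber channels give initial
concentration profiles, converted to spectra by non-negative least
squares — with sample mode available (`mode = "sample"`).

The ALS core alternates exact non-negative least squares for C and S. Each
subproblem is solved to optimality (normal equations where the
unconstrained solution is already feasible, Lawson–Hanson NNLS for the
violating columns), never by clip-after-solve; exact subproblem solves are
what guarantee the monotone decrease of the residual, which the tests
assert at every iteration. Convergence is declared when the residual
standard deviation `||X - CS||_F / sqrt(np)` changes by less than 0.1%
(default), with a 50-iteration cap. Scale ambiguity is fixed by
max-normalizing each pure spectrum and absorbing scales into C; components
are reported in descending total-concentration order, and
`match_components()` resolves the remaining permutation ambiguity against
any reference by exhaustive assignment (k <= 6). Group comparison of the
resolved abundances reuses the peak-statistics test-selection rule.

# Peak statistics

Peak intensity is the windowed maximum within ±5 cm^-1 of the nominal
center — robust to small calibration shifts, and the nominal extraction
rule was not otherwise specified. The two-group test follows the stated
selection rule: Shapiro–Wilk normality on each group and an F-ratio
variance-homogeneity check, all at alpha = 0.05; a pooled-variance t test
when all three pass, otherwise Mann–Whitney with tie correction. The
F-ratio was chosen over Levene as the simplest two-group homogeneity check
consistent with the rule; it is isolated in `group_compare()` and easy to
swap. Degenerate zero-variance groups are routed to Mann–Whitney. Star
annotations follow the *, **, ***, **** convention at 0.05, 0.01, 0.001,
0.0001. Per-peak ROC curves are oriented so the reported AUC is at least
0.5, with the direction recorded.

# Problem sizes used in the shipped checks

The recovery and calibration suites run at sizes chosen to exercise the
study-shaped conditions while staying cheap: MCR recovery on noiseless
200-cell x 1761-channel three-component mixtures over 10 seeds; the
permutation-null calibration on 600 exchangeable spectra x 300 channels
with 99 permutations (patient effects are disabled there on purpose — with
no group contrast but patient-level random effects, cells cluster by
patient and the observed AUC's variance is inflated relative to a
label-permutation null, the classic pseudoreplication trap, which would
confound a calibration check aimed at the permutation machinery itself);
the classifier-regime check on five full 657-cell cohorts; and the
type-I-error check of the test-selection rule at the study's patient-level
n of 9 per group over 2000 replicates. `scripts/acceptance.R` reruns the
pipeline at the full cohort shape and writes its headline numbers as JSON.

# Known limitations

- The coarse-band glass fit degrades when the substrate contribution is
  small relative to the cell's own broad pedestal (relative error grows
  roughly as 0.03 / scale); heavy-tailed lineshapes push its accuracy
  toward ~15%.
- MCR-ALS inherits the usual rotational ambiguity of bilinear models;
  non-negativity narrows but does not eliminate it, and no band-boundary
  analysis is provided.
- The classifier is strictly two-class and linear; batch effects,
  multi-site harmonization and nonlinear models are out of scope.
- Min–max normalization discards absolute intensity; analyses relying on
  total signal must work upstream of step 4.
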