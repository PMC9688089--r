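---
title: "Methods: Raman assessment of sperm DNA integrity on glass slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman assessment of sperm DNA integrity on glass slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, defaults and design choices behind
`ramanSDI`, in the spirit of a statistical methods section: what each
stage assumes, which knobs matter, and what the tests do and do not show.

## The measurement problem

A Raman spectrum of a sperm head on a glass slide is, to a good
approximation, a sum of four things: the cell's own biochemical signal,
a broad glass band centred between 1050 and 1150 cm⁻¹, a contribution
from the agarose mounting layer, and a smooth fluorescence background.
The diagnostic information — relative intensities of DNA-associated bands
(782, 896, 1089, 1258, 1319 cm⁻¹) and of protein/lipid bands (1001, 1208,
1460, 1673 cm⁻¹, …) — is small compared with all three nuisances, so the
pipeline's job is essentially careful subtraction followed by a
discriminant model honest enough to survive cross-validation.  The binary
reference label (DNA-intact / DNA-damaged) comes from sperm chromatin
dispersion (SCD) staining performed after the Raman measurement.

The working spectral range is 600–1800 cm⁻¹ at 1 cm⁻¹ spacing;
`crop()` uses closed intervals, so both endpoints are kept.

## Fluorescence baseline: iterative peak-excluding polynomial fit

`vancouver_baseline()` fits a degree-`order` polynomial (Legendre basis
on the axis rescaled to [−1, 1], for conditioning) by least squares,
estimates the noise level as the standard deviation of the residuals
*below* the fit (peaks only ever push residuals up, so the negative side
is peak-free), clamps every point above `fit + noise` down to that bound,
and refits until the baseline changes by less than `tol` in relative
max-norm.

Defaults: `order = 5`, `max_iter = 100`, `tol = 1e-4`.  Order 5 is the
common choice for biological spectra over this range: low enough not to
chase the glass band's shoulders, high enough to track lamp/fluorescence
curvature.  Corrected intensities are *not* clipped at zero — clipping
would bias the EMSC least squares that follows.  On polynomial-only input
the algorithm converges in two passes and returns a numerically exact
baseline; on peaky input the clamp excludes peaks from the fit within a
few iterations.  Simulation at SNR 20 (peak height = 20 × channel noise)
puts the mean per-peak recovery error below 2%, with single-replicate
scatter of about 2% coming from the baseline estimate itself.

## Smoothing and normalization

`smooth_spectra()` is Savitzky–Golay filtering (via the `signal`
package), default window 7 and polynomial order 3: at 1 cm⁻¹ spacing this
leaves the ~8–10 cm⁻¹-wide bands of interest essentially untouched while
attenuating channel noise.  `vector_normalize()` scales each spectrum to
unit Euclidean norm, removing focus- and cell-size-driven intensity
differences; it is idempotent and scale-invariant, and refuses all-zero
input.

## EMSC: interference removal by linear superposition

`fit_emsc()` models a spectrum as

$$ s(\nu) = b\,r(\nu) + \sum_i c_i g_i(\nu) + \sum_{j=0}^{m} p_j P_j(u) + e(\nu) $$

with $r$ a sperm reference measured free of interference, $g_i$ the glass
and agarose spectra, and $P_j$ Legendre polynomials of degree up to
`poly_order = 4` on $u \in [-1,1]$.  Ordinary least squares gives
$b, c_i, p_j$; `emsc_correct()` subtracts the fitted interference and
baseline (`subtract` mode, the default) or additionally divides by $b$
(`normalize` mode, the textbook EMSC convention).  Both are exposed
because either reading of "glass signal subtracted" is defensible; the
default pipeline subtracts and then applies vector normalization, which
makes the division by $b$ immaterial.

Reference and interferent spectra are expected to be baseline-corrected
and vector-normalized before entering the design.  The design matrix is
checked for rank; duplicated or collinear columns produce an error naming
the offending column.  Residuals are orthogonal to every design column to
numerical precision, and nested designs can only decrease the residual
norm — both are asserted as tests.

The pipeline order is: baseline → smoothing → EMSC → normalization.
Baseline removal first keeps the fluorescence out of the EMSC fit (the
degree-4 EMSC polynomial would otherwise have to absorb it), and the EMSC
step then deals with the structured interferents that a polynomial cannot
represent.  All four stages act on one spectrum at a time with no
parameters learned across spectra, so the chain can be applied once,
before cross-validation, without leaking class information.

## Classification

**PCA–LDA.**  `fit_pca()` is mean-centred SVD (computed from the Gram
matrix when channels outnumber spectra, which is exact and much faster).
Components are *not* selected by variance: `select_pcs_ttest()` keeps the
components whose scores differ between classes by a two-sided pooled
two-sample *t*-test at `alpha = 0.05`, in PC order, with no
multiple-testing correction (a Welch option exists).  The first 20 PCs
are candidates by default.  The type-I behaviour of this selection is
checked by simulation: under permuted labels it retains 5% ± 2% of
components.  If nothing passes the threshold — routine on null data
inside CV folds — the single best-p component is used so a model always
exists.  `fit_lda()` is the two-class Fisher discriminant
$w = \Sigma^{-1}(\mu_{pos} - \mu_{neg})$ with pooled covariance, ridge-
regularized by `1e-8 · trace/d` only if numerically singular.  Priors
default to *equal*: with 361 intact versus 65 damaged cells, empirical
priors would buy accuracy by sacrificing sensitivity on the minority
(diagnostically positive) class.  The threshold is the midpoint of the
projected class means shifted by the log prior ratio; ties classify as
positive.

**PLS-DA.**  `fit_plsda()` codes damaged = 1 / intact = 0 and runs NIPALS
PLS1 with X- and y-deflation; successive X-scores are orthogonal, and
with as many latent variables as the data's rank the predictions equal
ordinary least squares (both are tested against explicit oracles).
`n_lv = "auto"` (default) picks the number of latent variables in 1–15 by
stratified 5-fold inner cross-validation on the training rows,
maximizing *balanced* accuracy — the mean of sensitivity and
specificity.  Plain accuracy was tried first and is still available
(`inner_metric = "accuracy"`), but under 85/15 imbalance it is almost
flat in the number of LVs, and the fewer-LV tie-break then systematically
underfits the minority class (observed as a collapse of LOOCV sensitivity
from ~0.8 to ~0.55 with no visible change in accuracy).

**The decision threshold.**  The textbook PLS-DA rule cuts the predicted
response at 0.5, and `fit_plsda()` keeps that default with a documented
tie-goes-positive rule.  The pipeline default (`pipeline_config()`),
however, is `threshold = "midpoint"`: the midpoint of the two class-mean
training responses.  The reason is structural, not cosmetic.  For any
least-squares-type fit of a 0/1 response, the fitted values satisfy
$\mathrm{var}(\hat y) = \mathrm{cov}(\hat y, y)$, which with class
prevalence $p = 65/426$ forces the intact-class mean response toward
$p$ and caps the within-class spread; the 0.5 cut then sits several
standard deviations above the intact mean *regardless of how strong the
signal is*, so specificity saturates near 1 while sensitivity pays the
entire error budget.  The midpoint rule is the standard chemometrics
remedy for unbalanced PLS-DA and is exactly what LDA with equal priors
already does on its discriminant axis.

## Cross-validation

`make_folds()` builds leave-one-out or k-fold plans over *groups* —
cells (default; one spectrum per cell makes LOOCV leave-one-spectrum-out),
subjects, or raw spectra — and never splits a group across train and
test.  K-fold defaults to k = 10, stratified by class at the group level,
with a mandatory seed.  `cross_validate()` refits the entire trainable
chain (PCA, *t*-test selection, LDA / PLS including the auto-LV search)
inside every fold and pools the out-of-fold predictions before computing
metrics once — with only 65 positives, per-fold metric averaging would be
unacceptably noisy.  ROC curves are built from the pooled out-of-fold
continuous scores (LDA decision values, PLS responses); the trapezoidal
AUC with simultaneous tie steps equals the Mann–Whitney statistic
exactly, and a brute-force pair-count oracle asserts this on random
instances.  A leakage canary — a channel equal to the labels injected
into one fold's test rows — verifies that out-of-fold predictions cannot
see test information.

## Band mapping

`assemble_map()` snaps raster coordinates (tolerance 10⁻⁶ µm) onto the
lattice inferred from the unique sorted x/y values, fills an
`ny × nx × channels` cube, masks missing pixels, and errors on duplicate
or off-lattice points.  A stated instrument step size is deliberately
ignored in favour of the coordinates themselves, because point counts and
nominal resolutions in acquisition software routinely disagree.
`band_image()` renders either the maximum intensity in a
`center ± halfwidth` window (default halfwidth 8 cm⁻¹, a typical
biological band half-width at this resolution) or the trapezoidal area
above the linear chord between the window endpoints, which cancels any
locally linear background.  Row 1 of an image is the smallest y,
column 1 the smallest x.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code and defines the reference
conditions for every end-to-end test: 361 intact / 65 damaged cells from
10 subjects, 600–1800 cm⁻¹ at 1 cm⁻¹.  Each cell's spectrum is

```
b · profile(cell) + c_glass · glass + c_agarose · agarose + baseline + noise
```

with per-cell uniform draws of `b` (0.8–1.2), glass weight (0.5–2),
agarose weight (0.1–0.5), a random Legendre baseline of degree 3, and
additive Gaussian channel noise (sd 0.004; an intensity-scaled
shot-noise-like option exists).  The profile is a sum of 12 Gaussian
bands at the canonical sperm wavenumbers whose heights are modulated by
three biological terms:

* **class effect** — each band's height scales by
  `1 + class_effect · effect_scale · severity`; the signs follow the
  direction expected for DNA fragmentation (782, 920, 1001, 1089, 1460,
  1580, 1673 cm⁻¹ weaker in damaged cells; 1208, 1258, 1319, 1367 cm⁻¹
  stronger);
* **subject effect** — a log-normal subject-by-band multiplier
  (`subject_sd = 0.08`) giving every donor a stable idiosyncratic band
  pattern;
* **severity and assay discordance** — the per-cell damage severity is
  continuous (sd 0.15 around 0 for intact, around 1 for damaged), and a
  fraction of cells (12% of intact, 13% of damaged) carries a severity
  drawn from the *other* class's distribution.

The last term deserves justification, because a literal reading of the
design — fixed class shift plus independent band-wise subject noise —
cannot produce the error structure real cohorts show.  The halo assay
thresholds a continuous fragmentation index with subjective scoring, so
label-versus-spectrum discordance is a property of the reference method,
not of the spectroscopy; without it, simulations (backed by the variance
identity above) drive specificity to ≥ 0.95 whenever sensitivity clears
0.7, which real cohorts of this kind do not achieve.  The discordance
fractions, severity spread, subject spread, effect magnitudes and noise
level were calibrated **once** by simulation so that the default cohort
yields leak-free PLS-DA LOOCV sensitivity and specificity in the
70–90% regime with AUC near 0.85, and then frozen; the intact-side
fraction is structurally capped near 0.12, because beyond that the
flipped intact cells outnumber the 65 labeled-damaged cells in spectral
space and the regression's response for damaged-looking spectra drops
below any usable cut.

What passing tests on these cohorts shows: the pipeline recovers known
mixing coefficients exactly in the noise-free limit, is calibrated under
the null, respects fold boundaries, and degrades gracefully to the
realistic regime.  What they cannot show: robustness to features the
generator does not model — cosmic rays, detector etaloning, focus drift,
wavenumber miscalibration between sessions, or Mie scattering distortions.

`generate_map_phantom()` places the sperm reference inside an elliptical
head mask on a glass background (default 38 × 43 pixels, 1634 spectra)
and returns the truth mask; segmenting the 1089 cm⁻¹ band image at
Otsu's threshold recovers the mask with Dice > 0.9 in the tests.

## Numerical and degenerate-input choices

* Wavenumber axes are stored ascending everywhere; files in either order
  are normalized on read; duplicate wavenumbers are errors.
* Interpolation never extrapolates; a target outside the source range is
  an error rather than a silently invented value.
* All polynomial bases (baseline, EMSC) are Legendre on [−1, 1].
* LDA's pooled covariance gets a relative ridge only when its reciprocal
  condition number falls below 10⁻¹²; a still-singular matrix errors.
* Decision-rule ties (scores exactly at a threshold) classify as the
  positive class, deterministically.
* Degenerate ROC input (constant scores) yields AUC 0.5 with a warning.
* Fold plans, cohort generation and the inner LV search restore the
  global RNG state; identical seeds give bit-identical outputs.

## Problem sizes used by the checks

The packaged checks run the full-size cohort (426 spectra, 1201
channels) for LOOCV and k-fold, 100 zero-noise spectra for EMSC
recovery, 20 replicates × 3 peaks for baseline recovery, 1000 label
permutations for selection calibration, and 10 seeds × 3 effect scales
for the effect-size monotonicity check; unit tests use miniature cohorts
(~32 cells, 301 channels) so the full suite stays fast.

## Known limitations

* Two-class problems only; no multiclass LDA/PLS-DA or kernel variants.
* No cosmic-ray despiking, wavelet baselines, or derivative spectra.
* EMSC uses a single multiplicative reference term `b`; Mie-extended
  variants are out of scope.
* The subject effect is multiplicative on band heights only; baseline and
  interferent weights are drawn independently per cell.
* AUC confidence intervals (DeLong) are not provided.
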