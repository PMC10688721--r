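---
title: "Measuring and modelling sex differences in the ocular fundus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling sex differences in the ocular fundus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusex)
```

## The problem

Color fundus photographs carry a surprising amount of demographic
signal: deep networks can identify a person's sex from a single fundus
image with high accuracy, yet no single anatomical feature separates the
sexes well. One interpretable way to study this is to quantify a large
panel of conventional clinical measurements --- vessel geometry, optic
disc shape, and retinal color tone --- and ask how much sex information
a transparent linear model can pull out of them, and at what age that
signal emerges in children.

`fundusex` implements this pipeline end to end:

1. a **54-parameter measurement protocol** applied to a fundus raster
   plus a small set of human-placed landmarks,
2. the **statistical stage**: per-grade Mann-Whitney screening of each
   parameter, ridge (L2-penalized) binomial logistic regression scored
   by leave-one-out cross-validation (LOOCV), AUROC estimation, and
   paired DeLong comparisons of AUROCs across grades with Holm
   adjustment, and
3. a **synthetic generator** that draws per-sex feature tables from
   configurable multivariate normal distributions and renders schematic
   eyes with analytically exact landmarks, so that both stages are
   testable against closed-form ground truth without any image data.

## The measurement protocol

All coordinates are raster pixel coordinates: origin at the top-left
pixel, x rightward, y downward, pixel centers at 0-based integers.
Landmarks (disc center, fovea, disc boundary polygon, and the four
points where the major supratemporal/infratemporal arteries and veins
cross the vessel measurement circle) are *inputs*: the package does no
segmentation, mirroring the semi-automated protocol in which a grader
clicks the anchor points and every parameter then follows
deterministically.

The geometric parameters are:

* **Vessel angles** (`ST_RA`, `IT_RA`, `ST_RV`, `IT_RV`): each clicked
  crossing is first snapped radially onto the vessel measurement circle
  (default diameter 520 px, centered on the disc center); the angle is
  the unsigned angle at the disc center between the *temporal
  horizontal ray* (the horizontal ray pointing toward the fovea's side)
  and the ray to the crossing. `T_RA = ST_RA + IT_RA` and likewise for
  veins: the total angle subtended between the two vessels.
* **Crossing-fovea metrics** (`STAFD` ... `ITVFA`): Euclidean distance
  from each snapped crossing to the fovea, and the unsigned angle at
  the fovea between the fovea-crossing ray and the fovea-disc ray.
* **Papillomacular geometry**: `PMD` is the disc-center-to-fovea
  distance; `PMA` is the unsigned acute angle of that line against the
  horizontal, in [0, 90] degrees.
* **Disc shape**: `disc_area` is the number of pixel centers strictly
  inside the boundary polygon (even-odd rule), matching a
  pixel-counting definition; `ovality_ratio` is the minimum divided by
  the maximum Feret (caliper) diameter of the boundary, computed by
  rotating calipers on the convex hull.

The color parameters are the mean red, green and blue intensities and
the tessellation fundus index

$$\mathrm{TFI} = \frac{\bar R}{\bar R + \bar G + \bar B}$$

in nine circular regions: eight peripapillary circles (default diameter
240 px) whose centers sit at 45-degree steps on a ring around the disc
(the temporal one on the disc-fovea ray, the sweep passing first
through the superior side), plus one foveal circle (default diameter
80 px). Higher TFI means a redder, more tessellated (tigroid) fundus.
No vessel masking is applied inside the color regions.

### Conventions the protocol does not pin down

Several details of the published protocol are ambiguous; the package
fixes them as explicit, configurable choices in
`measurement_config()`:

* The "520-pixel", "240-pixel" and "80-pixel" circles are read as
  **diameters** (the bounding-box convention of the oval tool in the
  macro software the protocol was built on).
* The radial distance of the eight peripapillary circle centers is not
  stated; the default, 380 px, places each 120-px-radius circle tangent
  to the 260-px-radius vessel circle.
* All angles are unsigned, measured from the temporal horizontal ray;
  the temporal side is decided by the sign of (fovea.x − disc.x),
  so the same code handles right and left eyes, and a horizontal mirror
  of image plus landmarks leaves every parameter unchanged (this is
  asserted in the test suite).
* `PMA` is unsigned; a fovea above or below the disc by the same amount
  gives the same angle.
* Crossings are snapped radially onto the measurement circle before any
  angle or distance is computed; a snap larger than
  `crossing_tolerance` (default 5 px) warns but proceeds.

## The statistical stage

### Screening

`mw_screen()` runs a two-sided Mann-Whitney U test (female vs male) per
parameter and grade. Following the exploratory character of the
screening, the per-parameter p-values are *not* multiplicity-adjusted.
The implementation uses midranks for ties and the tie-corrected normal
approximation with continuity correction; for very small samples
(n ≤ 12 combined) it switches to exact enumeration of all group
assignments, which remains valid under ties.

### Ridge logistic regression

With many parameters (54) relative to eyes (about 109 per grade),
unpenalized logistic regression overfits badly. `fit_ridge_logistic()`
maximizes the penalized binomial log-likelihood

$$\ell(\beta) = \sum_{i=1}^n \left[ y_i x_i\beta - \log\!\left(1 +
e^{x_i\beta}\right) \right] - \lambda \sum_{j=1}^p \beta_j^2,$$

which reduces to ordinary maximum likelihood at $\lambda = 0$ (asserted
against `glm()` to 1e-6 in the tests). Predictors are standardized to
mean 0, SD 1 *within the training rows* and the intercept is
unpenalized --- the standard convention, consistent with a penalty that
runs over the slope coefficients only. The concave objective is
maximized by damped Newton iterations (step-halving), converged at
gradient max-norm below 1e-8 (cap 200 iterations). At $\lambda = 0$
with separable classes the MLE diverges; the fit detects this (all
residuals collapsing to zero) and reports non-convergence rather than
silently clipping.

### LOOCV scoring and the penalty policy

`loocv_scores()` refits the model n times, each time standardizing and
(optionally) selecting $\lambda$ *inside* the training fold, and scores
the held-out eye with its linear predictor. The held-out label can
never influence its own score; the tests assert this leakage contract
directly by flipping a held-out label and checking its score is
unchanged.

The source protocol names ridge and LOOCV but not $\lambda$. The
package therefore makes the policy explicit:

* `lambda_policy = "fixed"` (default $\lambda = 1$ on standardized
  features), and
* `lambda_policy = "cv"`: inner stratified 5-fold cross-validation per
  training fold, minimizing out-of-fold binomial deviance over a
  log-spaced grid ($10^{-2}$ to $10^3$).

Any reproduction on real data should report both.

### AUROC, DeLong, Holm

`roc_auc()` computes the AUROC by tie-aware pair counting
($U / (n_+ n_-)$ with midranks), which equals the trapezoidal area
under the tie-aware ROC curve; both identities are property-tested.
`delong_paired()` compares two AUROCs computed from the *same eyes*
(e.g. consecutive grades of a longitudinal cohort) using the
placement-value covariance estimator for correlated ROC curves, and is
cross-checked against an independent implementation (pROC) in the
tests. `per_grade_analysis()` tests the three consecutive grade pairs
(8.5↔9.5, 9.5↔10.5, 10.5↔11.5) and Holm-adjusts that family of three;
with identical score vectors the variance of the difference is zero and
the comparison degenerates to $\Delta = 0$, $p = 1$ by convention.

Scores being linear predictors (not probabilities) is immaterial for
every rank-based quantity above. The positive class is *female*
throughout.

## The synthetic generator

### Feature tables

`sim_config()` describes each sex's feature distribution as a
54-dimensional normal with shared SDs and correlation (identity by
default, injectable for stress tests; validated symmetric PSD with unit
diagonal). `generate_feature_table()` draws a cohort deterministically
from a seed. Two modelling notes:

* Real per-grade summary statistics exist only as mean ± SD in the
  study's supplementary material, so a multivariate normal with those
  margins is the natural emulation; the shipped default values are
  synthetic, chosen once at magnitudes typical of 1500-px-class fundus
  rasters (e.g. supratemporal artery angle 38 ± 7°, papillomacular
  distance 600 ± 35 px, peripapillary TFI 0.53 ± 0.02).
* The additive identities `T_RA = ST_RA + IT_RA` (and veins) hold
  exactly for image-extracted vectors, but statistical draws sample all
  54 margins; default means are kept additive so the identity holds in
  expectation. Tests never assert the identity on drawn tables.

The default sex-difference vector points the way the study found:
girls with higher green/blue intensities (hence lower TFI), the
supratemporal artery closer to the fovea, slightly larger artery
angles. Its full-strength Mahalanobis norm is about 1.45 (Bayes-optimal
AUROC $\Phi(1.45/\sqrt2) \approx 0.85$), and grade multipliers
(0.35, 0.15, 0.75, 1.0) emulate the reported trajectory: weak and
noisy discrimination before age 10 (including the non-monotone dip at
9.5 years), rising clearly by 11.5 years. `sexdiff_mahalanobis()`
exposes the separation of any configuration for exactly this kind of
design reasoning.

### Rendered eyes

`render_fundus_image()` produces a schematic, not photorealistic,
fundus: a filled rotated ellipse for the disc (semi-axes solved from
the drawn disc area and ovality), four vessels drawn as circular arcs,
and a tessellated background of brightness patches. Schematic is
sufficient because extraction is landmark-driven geometry plus region
means --- the point of the renderer is exact ground truth, achieved by
two constructions:

* **Closed-form crossings.** Each vessel is the circular arc of a
  configured radius through the disc center and the point at the
  configured launch angle on the measurement circle; that point *is*
  the ground-truth crossing, no intersection solving needed. Arcs too
  tight to reach the circle are rejected at construction.
* **Brightness-only texture.** Background patches and vessels rescale
  the base color's brightness without changing its hue, so the TFI of
  every region equals the base-color TFI analytically, no matter how
  much texture or vessel area falls inside a region. The only
  round-trip error sources are 8-bit rounding (≤ ~0.002 in TFI) and
  the 64-gon polygonalization of the disc ellipse (≤ ~0.001 in
  ovality, ~0.2% in area).

The round-trip contract asserted over rendered eyes: vessel angles
within 0.5° (observed: ~1e-14), distances within 1 px (observed:
~1e-13), TFI within 0.01 (observed: ≤ 0.0005), ovality within 0.03
(observed: ≤ 0.002).

### What the generator does and does not emulate

It emulates per-sex location/scale structure, optional correlation, the
longitudinal design (same ids across grades) and grade-growing effect
strength. It does **not** model within-subject correlation across
grades (draws are independent given sex), axial-length magnification,
non-normal feature distributions, or photographic artifacts
(illumination gradients, blur, vessel sheen). Green tests therefore
validate the *pipeline* --- measurement correctness and statistical
calibration --- not the biological effect sizes themselves, which only
the deposited study data can provide.

## Numerical and design choices

* **Disc area** uses strict-interior pixel-center counting (even-odd
  rule); points exactly on an edge are excluded, which is measure-zero
  for real landmarks. Self-intersecting boundary polygons are rejected
  by an explicit segment-intersection check.
* **Feret diameters** come from the convex hull: the maximum over
  vertex pairs, the minimum over edge-normal widths (exact for convex
  polygons); tested against a brute-force direction-grid oracle.
* **Ties** are handled by midranks everywhere (U statistic, AUROC,
  placement values), never broken randomly.
* **Determinism**: every random draw routes through an explicit seed,
  and the generator restores the caller's RNG state; the disk pipeline
  (`run_pipeline()`) is byte-reproducible given its configuration and
  embeds the seed and a configuration hash in each output.
* **Problem sizes in the test suite** were chosen to make Monte-Carlo
  checks decisive at modest cost: 20 rendered eyes for the geometry
  round trip; 100 null cohorts of 100 eyes for LOOCV calibration (the
  mean AUROC lands within 0.02 of chance --- LOOCV's well-known slight
  pessimism stays inside that band at these sizes); 500 replicates for
  the uniformity of paired-null DeLong p-values; and 100 replicates of
  a four-grade cohort for the monotonicity check, with effect
  multipliers (0.25, 1.25, 2.5, 5) spaced by a binormal power analysis
  so AUROC sampling noise at n = 109 per grade cannot mask the
  ordering.

## Known limitations

* Reproducing the study's printed per-grade AUROCs requires the
  deposited raw data (an export path is documented in the README); the
  package cannot redistribute it, and the penalty value used in the
  original analysis is unknown, which is why both penalty policies are
  offered and a tolerance is expected in any reproduction.
* The measurement protocol reports distances in pixels; no conversion
  to retinal millimeters (which would need axial length) is attempted.
* `extract_features()` trusts its landmarks; garbage landmarks yield
  garbage parameters, flagged only when geometric preconditions break
  (e.g. crossings far off the measurement circle, regions leaving the
  raster).

## A worked example

```{r example, eval = FALSE}
library(fundusex)

# simulate the default four-grade study and analyze it
cohort <- simulate_longitudinal_cohort(seed = 1)
report <- per_grade_analysis(cohort)
report
glance(report)          # per-grade LOOCV AUROC
tidy(report)            # 54 x 4 Mann-Whitney p-values, long form
autoplot(report)        # overlaid per-grade ROC curves
plot_pvalue_map(report) # feature-by-grade significance map

# render one synthetic eye and re-measure it
eye <- render_fundus_image(
  sample_eye_parameters(default_sim_config(11.5), "female", seed = 7)
)
extract_features(eye$image, eye$landmarks)
```
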