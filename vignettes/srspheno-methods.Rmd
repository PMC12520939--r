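---
title: "Methods: chemical mapping and single-cell phenotyping with srspheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical mapping and single-cell phenotyping with srspheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srspheno)
```

## The measurement and the model

Hyperspectral stimulated Raman scattering (SRS) microscopy records, at
every pixel, an intensity spectrum over a window of Raman shifts. In
the C–H stretch window (2800–3050 cm⁻¹) the dominant cellular
scatterers — proteins (CH₃ stretch near 2930 cm⁻¹), nucleic acids
(near 2955 cm⁻¹), and lipid acyl chains (CH₂ near 2850 cm⁻¹, with the
olefinic =C–H band near 3010 cm⁻¹ marking unsaturation) — all
contribute strong, heavily overlapping bands. A single channel
therefore never isolates one molecule class; recovering interpretable
chemistry requires spectral unmixing against reference standards.

`srspheno` models each pixel spectrum $s \in \mathbb{R}^C$ as a
nonnegative mixture of four reference spectra collected from purified
standards — BSA for protein, DNA for nucleic acid, triolein for
unsaturated lipid, palmitic acid for saturated lipid — stacked as the
columns of a library matrix $X \in \mathbb{R}^{C\times 4}$:

$$\hat c \;=\; \arg\min_{c \ge 0}\; \tfrac12\,\lVert s - X c\rVert_2^2
\;+\; \lambda \lVert c\rVert_1 .$$

The L1 penalty encodes the prior that most pixels contain only a few
of the four components at appreciable level; the nonnegativity
constraint encodes physical abundance. Solving this independently at
every pixel and rasterizing each coefficient yields four *chemical
maps*. Cells are then segmented from the summed maps, and each cell is
summarized by the 5-feature phenotype — cellular area plus the
integrated (summed over the mask) protein, nucleic acid, saturated-
and unsaturated-lipid content — that feeds an OPLS-DA classifier of
cell populations.

## Reference library

Library columns are resampled to the acquisition axis by linear
interpolation (zero outside the source support) and **l2-normalized**.
Unit-norm columns make coefficients comparable across components and
give the all-zero solution a closed-form threshold
$\lambda_{\max} = \max_k x_k^\top s$: any penalty at or above it
produces exactly $\hat c = 0$. Library validity requires linear
independence of the four columns (smallest singular value $> 10^{-6}$);
violating it (e.g. feeding one spectrum for two standards) is a hard
`degenerate-library` error, because unmixing coefficients would be
unidentifiable.

When no measured standards are available,
`synthesize_reference_spectrum()` builds idealized standards as sums
of Gaussian bands; the default band tables
(`default_peak_table()`) follow the standard C–H assignments listed
above. They are free parameters of the simulator, not measurements,
and are exposed so users can substitute their own CSV spectra via a
library manifest.

## Synthetic cohorts and what they do (not) emulate

`generate_cohort()` renders seeded in-silico cohorts: cells are filled
disks placed without overlap (dissociated single cells; rejection
sampling, at most 1000 attempts per cell), each carrying a true
4-vector of per-pixel abundances drawn log-normally around its class
profile (nonnegative, right-skewed biological variation), an optional
per-cell multiplicative intensity factor (log-normal, CV 0.1 by
default) mimicking inter-sample intensity variation, and additive
i.i.d. Gaussian channel noise approximating shot-noise-limited SRS
detection (default σ = 0.02 on top of a 0.02 background, against
per-pixel total signals of order 1–2).

Eleven hematopoietic populations are parameterized in an editable YAML
(`inst/extdata/class_profiles.yaml`): AML subtypes M2–M5, B-ALL Ph⁻
and Ph⁺, and five normal populations. The profile means encode the
qualitative contrasts expected of these populations — AML blasts
protein- and lipid-rich but nucleic-acid-poor relative to
granulocytes; M5 elevated in all four components relative to
monocytes; M3 the most unsaturated-lipid-rich and M5 the most
saturated-lipid-rich AML subtype; ALL lipid-poor relative to every AML
subtype, with Ph⁺ at least as unsaturated-enriched as Ph⁻. The
magnitudes themselves are simulator plumbing: they were chosen once so
that the six leukemia classes are separable to the degree a linear
5-feature classifier can realistically deliver high (~0.9)
cross-validated accuracy, and the test suite asserts the orderings,
not the magnitudes. Limitations worth keeping in mind: no subcellular
texture (nucleus/cytoplasm), no point-spread blur, no touching cells,
and noise that is white across channels. Passing tests on these
cohorts therefore validate the *computational chain*, not instrument
physics or the biology of real specimens.

## Numerical choices in the unmixing solver

The solver is cyclic coordinate descent with soft-thresholding and a
nonnegative clamp, the standard scheme for separable L1 problems. With
only four coordinates, each update is a closed-form scalar
minimization, so the objective is monotonically nonincreasing; the
test suite verifies the solution against an independent
projected-gradient oracle. The implementation updates all pixels of an
image simultaneously (one vectorized update per coordinate per sweep)
from a zero start rather than pixel-by-pixel with warm starts — in R
the vectorized form is orders of magnitude faster and, because the
problem is convex and tolerances are tight, the result is independent
of the start. Convergence is declared when the largest coefficient
change in a sweep falls below `tol` (default 1e-10, at most 1000
sweeps); the tight default costs a handful of extra sweeps and makes
pure standards recover their unit coefficient to ~1e-10.

The default penalty λ = 1e-3 refers to unit-norm references and
spectra of order 1; it barely biases abundances (soft-thresholding
shifts coefficients by at most λ per unit Gram diagonal) while zeroing
noise-level components. `select_lambda_cv()` offers a data-driven
alternative that cross-validates reconstruction error over held-out
spectral channels on a pixel subsample. Scaling covariance holds
exactly: scaling a spectrum by $a$ with λ scaled by $a$ scales the
solution by $a$, so intensity-calibration choices commute with
unmixing.

## Segmentation and features

Segmentation operates on the sum of the four maps (best SNR): Otsu
threshold (or a fixed value), hole filling, 8-connected component
labeling, removal of components below `min_area` (default 30 px —
cells in these data are hundreds of pixels, debris is tens), and
deterministic relabeling in raster order of component centroids. An
all-constant image yields an empty mask rather than an error. No
watershed splitting is attempted by default because the simulator
never renders touching cells.

Contents are **sums** of map coefficients over the mask, a
total-amount measure that deliberately co-varies with area (a mean
per-pixel variant is available). With noiseless data, λ = 0 and exact
masks, content equals true abundance × area identically; the
end-to-end test holds this to within 1%.

## OPLS-DA, from first principles

Features are autoscaled (column mean 0, sample s.d. 1; constant
columns become zero columns with s.d. recorded as 1). Class labels
become a one-hot dummy matrix $Y$ (centered). For each orthogonal
round, the first PLS2 component weight is computed by NIPALS
(deterministic initialization from the largest-variance dummy column;
tol 1e-10, ≤ 500 iterations), its X-loading $p$ is orthogonalized
against the span of $X^\top Y$, normalized, and the resulting
component removed from $X$. Projecting out span($X^\top Y$) makes the
orthogonal scores *exactly* uncorrelated with every dummy column
($Y^\top X w_o = (X^\top Y)^\top w_o = 0$), which the tests assert at
1e-8. Deflation is an orthogonal decomposition, so the sum of squares
of the input equals filtered + removed parts to machine precision.
Predictive components are then plain NIPALS PLS2 on the filtered
matrix; with zero orthogonal components the whole model is exactly
PLS2-DA, verified against an independent minimal NIPALS oracle.
Weight signs are fixed so each column's largest-magnitude element is
positive, making scores plots reproducible.

Prediction applies the stored scaler, strips orthogonal components
sequentially, projects with $R = W(P^\top W)^{-1}$, and returns
$\hat Y = T C^\top + \bar y$; the label is the argmax column, ties
resolving to the lowest class index.

Two design points were genuinely open and resolved as follows.
*Component counts:* the classical display convention suggests two
predictive components, but with $K$ classes the dummy response spans
$K-1$ directions, and capping the predictive rank at 2 demonstrably
cripples 6-class discrimination (pooled CV accuracy drops from ~0.89
to ~0.67 on the default benchmark because indicator regression then
masks nearby classes). The default is therefore
$A = \min(K-1,\, p - A_o)$ predictive components, with the scores plot
simply showing the first two. *Orthogonal feasibility:* orthogonal
components live outside span($X^\top Y$); when $K-1 \ge p$ (six
classes, five features) that span is all of feature space and **no**
orthogonal component exists — `fit_oplsda()` raises a rank-error, and
the evaluation layer caps $A_o$ at $\max(0, p-(K-1))$ with a logged
warning, so the six-class benchmark runs as PLS2-DA. PCA-reduction of
the five features before OPLS-DA was considered and rejected: with
$p = 5$ there is nothing to reduce.

## Evaluation

Confusion matrices use rows = true, columns = predicted. Precision is
column-wise TP/(TP+FP); a class never predicted has *undefined*
precision, reported as `NA` (never 0) and excluded from macro
averages. Total accuracy is the trace over the total and equals the
frequency-weighted mean of per-class sensitivities — asserted
algebraically in the tests. Cross-validation is stratified k-fold
(default k = 7, the usual chemometrics convention), with the scaler
and model refitted on training folds only and predictions pooled; k is
reduced to the smallest class count when necessary. Resubstitution
metrics are reported alongside CV, clearly labeled, since fitted-model
and held-out accuracies answer different questions.

## Problem sizes and determinism

The shipped study design simulates 6 leukemia classes × 30 cells on
320×320-pixel fields with 126 spectral channels; the full pipeline
(render, unmix ~615k pixels, segment, phenotype, classify, 7-fold CV)
completes in well under a minute on one core, and the test suite uses
smaller fields (51 channels, 96–160 px) for unit-level checks. All
randomness flows from one integer seed, fanned out to fixed per-stage
child seeds, so the truth CSV, feature CSV and metrics JSON are
byte-identical across reruns; artifact MD5 hashes are recorded in the
run manifest.

## Known limitations

The four-standard library cannot represent molecular diversity within
a class (e.g. diverse proteomes vs BSA), and strong band overlap in
the C–H window leaves residual cross-talk between chemical maps —
visible here as correlated Gram off-diagonals (≈0.7–0.8 for the most
overlapping pairs) and a known ceiling of the approach rather than a
solver defect. Abundances are recovered accurately (RMSE ≈ 0.02 at
noise σ = 0.01) but are *not* molar concentrations; they are
coefficients on the unit-norm reference scale. The classifier is
linear in the five features; populations that differ only in feature
covariance or in spatial organization within the cell are invisible
to it.
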