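---
title: "Models and methods behind smatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`smatkit` quantifies actin turnover from time-lapse imaging of the
fluorogenic F-actin probe SiR-actin (SA). This vignette is the package's
own account of the models it implements, the parameters that matter, the
synthetic data it validates against, and the design choices that were
genuinely open.

## The binding model

SA binding to filamentous actin is modeled as a reversible
ligand–receptor reaction `L + R <-> C` in which only the bound complex
`C` fluoresces. Two regimes are used, both linear ODEs with closed-form
solutions (time unit: minutes throughout, matching typical imaging
intervals):

* **Dissociation** (after washout of the staining medium, binding sites
  in excess): `dC/dt = kf_d (C0 − C) − kr C`, with `C(0) = C0`. The
  signal relaxes from `C0` toward `C∞ = kf_d C0 / (kf_d + kr)` at rate
  `kf_d + kr`. With `C0 = 1` (a normalized curve) the trajectory lives in
  `(0, 1]` and is non-increasing whenever `kr > 0`.
* **Association** (initially unstained cells, unbound ligand in excess):
  `dC/dt = kf_d L_T − kr C`, relaxing toward `Ceq = kf_d L_T / kr` at
  rate `kr`, or a linear ramp when `kr = 0`.

Assumptions worth stating: binding sites and (in association mode) free
ligand are treated as unchanging pools; the model describes a whole-field
scalar signal, not spatially resolved kinetics; and photobleaching is
assumed negligible relative to turnover-driven probe loss.

**Identifiability.** The forward rate `kf` and the site abundance `R_T`
enter both equations only as the product `kf_d = kf · R_T`, so they are
not separately identifiable from intensity data; the package estimates
the composite and reports `kr / kf_d` as the turnover-ranking ratio. A
slower-turnover condition dissociates less probe per unit of effective
association and has the smaller ratio.

**Estimation.** Parameters are estimated sequentially, mirroring the
experimental logic: `(kf_d, kr)` by least squares on the dissociation
curve, then `L_T` from the association curve with the rates held fixed —
at which point the problem is linear in `L_T` and solved in closed form.
`C0` is fixed at 1 because curves are normalized to their first
timepoint (an option frees it for raw data). The nonlinear step uses
box-constrained quasi-Newton iterations from a fixed 5 × 5 log-spaced
grid of starting rates over `[1e-3, 10]`/min, followed by a tighter
polish from the winner; best SSE wins and exact ties go to the smaller
`kr` (so a flat curve is attributed to "no dissociation" rather than an
arbitrary `kf_d`). The grid is deterministic, so fitting needs no random
seed. Non-convergence is reported as a flag, never an exception.
Standard errors come from the Gauss–Newton approximation
`s² (JᵀJ)⁻¹` with a numerically differentiated Jacobian.

## SMAT quantification

The measured quantity is the arithmetic mean pixel intensity of each
whole imaged field (per-mask measurement is available but not the
default, since the assay is designed for low-magnification fields).
Every field trace is normalized to its own first timepoint before any
averaging — consequently each condition curve starts at exactly 1 with
SEM 0 there — and the condition curve is the pointwise mean ± SEM across
replicate × field traces.

Conditions are compared per timepoint: a two-way ANOVA
(condition × time, each field trace contributing one observation per
frame) supplies the pooled residual variance, and
reference-vs-condition t contrasts at each timepoint are
Bonferroni-corrected across the number of timepoints, starred at
0.05/0.01/0.001. Two choices deserve note:

* whether the replication unit is the well or the field is ambiguous in
  such designs; the package treats each field trace as an observation
  and records `n` in every curve;
* the first timepoint is kept in the contrast table — its difference is
  identically zero, so it reports `p = 1` rather than being dropped.

For media-switch experiments the post-switch window is re-normalized to
each trace's value at the switch frame before comparison, because the
curves have typically decayed substantially by the time the media are
swapped; the pre-switch window is compared as usual. Background is not
subtracted by default (the raw mean gray value is the assay's readout);
a constant-background option exists for data with a known dim offset,
such as the synthetic stacks.

## The 41-descriptor single-cell panel

The dual-stain arm segments cells by a CellProfiler-style two-stage
recipe: nuclei from an Otsu threshold of the nuclear channel (hole
filling, connected components, removal of fragments below 15 px), then
cell bodies by seeded region propagation of the nuclei labels inside an
Otsu mask of the summed SA + phalloidin signal. Seeded propagation is
the same secondary-object assignment CellProfiler uses and is what
splits touching cells between their nuclei; border-touching cells are
excluded and counted. The image primitives (thresholding, labeling,
propagation, filling) come from EBImage.

Each cell yields exactly 41 descriptors, a documented reconstruction of
a shape/intensity/texture panel:

* 9 shape: area, perimeter (exposed 4-connected pixel faces),
  eccentricity and equivalent-ellipse axes from second central moments
  (eccentricity 0 for isotropic regions), solidity against the convex
  hull of pixel corners, extent, form factor `4πA/P²` and compactness
  `P²/(4πA)`;
* 3 intensity statistics (mean, integrated, sd) per stain channel;
* 13 co-occurrence (Haralick) texture statistics per stain channel,
  computed on the cell's bounding-box patch min–max quantized to 8 gray
  levels within the mask, distance 1, averaged over the 4 standard
  directions. Conventions: natural logarithms with `0 log 0 = 0`;
  sum-variance centered on the sum-average; correlation and the
  information measures defined as 0 when the relevant marginal variance
  or entropy vanishes (e.g. a constant patch). Pixel pairs never cross
  the cell mask. Cells too small to form any co-occurrence pair are
  dropped with a logged reason.

The panel is versioned (`sp-41-v1`) and its name list is exported, so
downstream reports can state exactly which descriptors produced them.
One algebraic fact matters downstream: for a symmetrized co-occurrence
matrix, `sum_variance + contrast = 4 · variance` exactly, once per
channel, so the 41 columns span a 39-dimensional space. The feature
table always carries all 41; the multivariate analyses (LDA, Wilks) run
on the pivoted full-rank column subset, which is recorded in the result.

## Canonical discriminant analysis and its companions

Features are z-scored before LDA so that heterogeneous units (pixel
areas vs texture statistics of order 1) do not dominate the scatter
matrices. Canonical coefficients are eigenvectors of the within-scatter
whitened between-scatter matrix, scaled so canonical scores have
identity pooled within-group covariance; eigenvalues are those of
`Sw⁻¹Sb` in decreasing order. A numerically singular within-scatter
triggers a small ridge (`1e-6` of the mean diagonal), flagged on the
model — expected whenever a (sub)population has fewer cells than
features, as in binary analyses of small test populations.

Classification assigns each cell to the nearest group mean in canonical
space under equal priors (equidistant ties to the lowest group index).
Percent correctly classified is resubstitution on the supplied set by
default — labeled as such — with a k-fold cross-validated variant
available; resubstitution is systematically the more optimistic of the
two, which the tests assert.

Wilks' lambda is `det(Sw)/det(St)` with Rao's approximate F
transformation; for one feature and two groups this reduces exactly to
the one-way ANOVA F, which serves as an algebraic cross-check, and the
general case is verified against an independent MANOVA implementation.
The 50% contour ellipses are covariance ellipses of a bivariate normal
fit to a group's first two canonical scores, scaled by the χ²(2)
quantile of the requested mass. Predictor screening uses a
bootstrap-resampled tree ensemble (200 trees by default, impurity
importance, fixed seed) via `ranger`.

## What the synthetic data emulate — and what they do not

The generators exist so that every downstream claim can be tested
against known ground truth:

* **Traces**: closed-form condition kinetics plus iid Gaussian noise
  (`sd = 0.02` by default, giving SEM bars of a few percent of the
  normalized signal on triplicate × 4-field designs), truncated at 0;
  media switches swap parameters mid-course with a continuous signal.
* **Stacks**: 512 × 512 fields (about 30 cells at 10×-like scale) of
  anisotropic Gaussian cells modulated by an oriented stripe texture —
  enough structure to make the texture statistics non-trivial — whose
  intensity follows the per-field noisy trajectory over a constant
  background capped at 1% of unit cell brightness, honoring the
  >100-fold fluorogenic contrast of probe detachment. Pixels carry
  Poisson-like shot noise (2 × 10⁴ counts at unit intensity) and are
  written as 16-bit multi-page TIFF.
* **Dual-stain populations**: each cell draws a latent turnover score
  and a latent texture score around condition-specific centers whose
  separation scales with a per-timepoint effect size (default 0.7, 1.4,
  2.8 at 1 h / 8 h / 24 h — a doubling schedule chosen once to emulate
  progressive lineage divergence). SA amplitude rises and phalloidin
  amplitude falls with the turnover score, so the two stains are
  anticorrelated across cells by construction, as expected of competing
  probes; the texture score modulates stripe frequency and depth.
  Nuclei are rendered round, at roughly a third of the cell's major
  axis.

The preset rate constants (per minute) — AD (0.004, 0.004),
CH (0.003, 0.009), OS (0.002, 0.018), BA (0.002, 0.020) — were chosen
once so that the conditions reproduce the qualitative design of the
emulated experiments: adipogenic slowest decay reaching a high plateau,
chondrogenic intermediate, osteogenic barely distinguishable from basal,
and `kr/kf_d` increasing from ~1 to ~10 across that order. Other presets
cover low-dose cytoskeletal drugs, serum deprivation with switches,
basal/adipogenic swaps, passage comparison, and an identical-parameter
null for calibration.

What the generators do *not* emulate: point-spread blur, uneven
illumination, drift, cell motility or division, or segmentation-hostile
morphologies. Passing tests therefore demonstrate correctness of the
computation and sensible behavior under realistic noise — not robustness
to every artifact of real microscopy.

## Determinism and numerical conventions

All generators consume a scenario seed and restore the caller's RNG
state; a fixed seed yields byte-identical files, which the tests verify
by checksum. Output CSVs carry a commented header with tool version,
seed and a config hash. Closed-form trajectories agree with numerical
integration of the rate equations to better than 1e-8 over rates in
`[0, 10]`/min. Pixel coordinates are row-major with the origin at the
top-left.

Test and validation problem sizes are deliberately modest — 256 px
fields with 9–12 cells, 2–3 fields per condition, 200-replicate
recovery studies, 500–1000-repeat calibrations — sizes at which the
statistical behavior is already unambiguous while a full run stays in
the minutes range.

## Known limitations

* `R_T`, `kf` and (when `kf_d = 0`) `L_T` are structurally
  unidentifiable; the package reports composites and flags rather than
  guessing.
* The exact membership of the historical 41-descriptor panels used by
  commercial HCIA software is not public; `sp-41-v1` is a faithful
  reconstruction of the stated categories, not a claim of
  column-for-column equivalence.
* The per-timepoint contrast scheme inherits the conservatism of
  Bonferroni correction; under the null it flags far fewer than 5% of
  timepoints.
* Resubstitution accuracy overstates generalization; use the
  cross-validated variant when the question is predictive performance.
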