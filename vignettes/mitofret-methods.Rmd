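---
title: "Measuring mitochondrial calcium from ratiometric FRET z-stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mitochondrial calcium from ratiometric FRET z-stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofret)
```

`mitofret` turns two-channel (CFP/YFP) multiphoton z-stacks of a
mitochondrially targeted cameleon calcium sensor into per-mitochondrion
free-calcium estimates and cohort-level statistics. This vignette explains
the model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The calibration model

A cameleon sensor's YFP/CFP emission ratio *R* increases sigmoidally with
free calcium. We model the titration with the Hill function in
concentration *C* (µM),

$$R(C) = R_\min + (R_\max - R_\min)\,\frac{C^n}{K_d'^n + C^n},$$

because its algebraic inverse,

$$[\mathrm{Ca}^{2+}] = K_d'\left(\frac{R - R_\min}{R_\max - R}\right)^{1/n},$$

is the standard ratiometric conversion equation, and the parameters have
direct sensor meaning: $R_\min$/$R_\max$ are the ratios at zero and
saturating calcium, $K_d'$ (µM) the apparent dissociation constant, $n$ the
Hill cooperativity. The packaged profile (`default_calibration()`) is the
in-situ N2a titration: $R_\min = 0.606$, $R_\max = 2.6921$,
$K_d' = 4.21$ µM, $n = 1.57$. Concentrations are stored in µM internally
and reported in nM (fixed factor 1000), matching how such measurements are
usually quoted.

**Fitting** (`fit_calibration()`): Levenberg–Marquardt least squares with
$\log K_d'$ and $\log n$ as the free parameters, which enforces positivity
without constraints. Initialization is deterministic and data-driven:
$R_\min$/$R_\max$ start at the observed ratio extremes, $K_d'$ at the
concentration whose ratio is nearest the midpoint, $n$ at 1. Convergence
tolerances are tightened (`ftol = ptol = 1e-14`) so that a noise-free
13-point table reproduces its generating parameters to machine precision;
the parameter-recovery suite verifies this for 100 random parameter sets in
physiological ranges.

**Out-of-range ratios.** Under measurement noise a real ratio can fall
below $R_\min$ or at/above $R_\max$, where the inverse is undefined.
`ratio_to_ca()` returns `NA` for those rather than clipping, because
clipping would fabricate 0 or infinite concentrations; `conversion_qc()`
counts them. $R = R_\min$ itself maps to exactly 0 nM (the continuous
limit).

## Image preprocessing

Processing order is fixed: per-slice background subtraction, then
smoothing, then segmentation, then ratio measurement.

* **Background** (`subtract_background()`): for each channel and z-slice
  independently, the mean of the bottom 5 % of intensities
  (`fraction = 0.05`) is subtracted and negatives are clamped to zero. The
  per-slice offsets are kept as a QC table. Note a known property of this
  estimator: under shot noise the bottom 5 % of a Poisson background lies
  below its mean, so a small positive residual background survives; its
  main effect is a slight pull of measured ratios toward 1 for dim,
  few-voxel objects (quantified in the end-to-end tests at a few percent).
* **Smoothing** (`smooth_stack()`): a per-slice 2D mean filter of radius 2
  (square $(2r+1)^2$ kernel by default; a disc is available). Borders are
  replicated so constants are preserved exactly. Smoothing exists to
  stabilize detection; by default ratios are measured on *unsmoothed*,
  background-subtracted intensities (`process_stack(ratio_on =
  "unsmoothed")`), since averaging before summation only correlates voxels
  without changing object sums, and the alternative is one flag away.

## Segmentation

Detection runs on the total indicator signal CFP + YFP, so it does not
favor low- or high-calcium mitochondria. Each slice is binarized by a
local-mean adaptive threshold (window `block_size = 51` px, additive
`offset = 0`) **and** a per-slice noise floor, median + 4 MAD. The floor is
needed because with `offset = 0` a bare local-mean rule marks about half of
any pure-noise region as foreground; median and MAD scale with intensity,
so the segmentation remains invariant under a common positive scaling of
both channels (a tested invariant).

The mean filter dilates each object's support by its radius, so the
detection support is refined before labeling. When the unsmoothed stack is
available (the default in `process_stack()`), a two-scale rule keeps only
support pixels whose raw intensity also clears its own per-slice noise
floor. On clean data this reproduces object boundaries exactly — the
smoothed support always contains the object, and the raw gate trims exactly
the blur halo — and the test suite holds the pipeline to voxel-exact
recovery (IoU 1) on noise-free stacks and to IoU ≥ 0.7 with recall ≥ 0.9
under the generator's default noise. Without the raw stack the support is
instead eroded by the smoothing radius, a coarser fallback.

Components are labeled in 3D with 26-connectivity (6 available) and kept if
their physical volume lies in [`min_size` = 0.2, `max_size` = 500] µm³ —
physical units so the defaults survive resampling; the wide upper bound
admits somatic mitochondrial clusters. Labels are renumbered 1..N.

**Compartments.** Somas versus neurites are tagged by an explicit,
overridable heuristic: objects above 20 µm³, or whose centroid falls in a
user-supplied soma mask, are "soma". The cut is a parameter because no
principled value exists at typical resolutions.

**Plaques** (`extract_plaques()`): either a supplied manual mask (the
practice for amyloid plaques) or a global threshold on the RED channel
(default: midpoint of median and max). Edge voxels are mask voxels
6-adjacent to background — an explicit, oracle-checkable definition used by
the distance analysis.

## Quantification

Per-object ratio is the ratio of channel sums over the object's voxels,
$R = \sum \mathrm{YFP} / \sum \mathrm{CFP}$ — not the mean of per-voxel
ratios, which would be noise-amplifying. A zero CFP sum flags the object
instead of erroring. Volume (z-stack) summaries average objects unweighted
(each mitochondrion counts once; voxel-weighted available), because
per-object equal weighting is the interpretation consistent with counting
overloaded mitochondria.

**Overload**: a control pool defines the threshold mean + 2 SD (sample SD;
the choice matters little at control pool sizes but is declared). Exceedance
is strict (`>`), and the responder rule for treatment effects is inclusive
(ΔR/R₀ ≥ 5 %); both conventions are pinned by tests. Somas and neurites are
pooled when computing the control threshold.

**Pseudocolor**: ratio maps to a hue ramp anchored at $[R_\min, R_\max]$
(blue → red, hue 240° → 0°, full saturation), and the HSV value channel is
the mean of the YFP and CFP images normalized to its maximum, so dim pixels
are dark regardless of ratio. The palette is fixed and stated here for
reproducibility.

## Spatial analysis

Distances are 3D anisotropy-aware Euclidean distances (µm) from object
centroids to the nearest plaque edge voxel center, 0 inside a plaque. We use
3D rather than projected 2D centroids and note that tissue-constrained
(geodesic) distances are out of scope. Overload percentages are binned in
contiguous right-open 10 µm bins to 100 µm (both configurable); the
statistical unit for the Kruskal–Wallis test across bins is the per-plaque,
per-bin overload percentage. The Kruskal–Wallis statistic comes from
`stats::kruskal.test` (tie-corrected H, χ² reference); an all-tied input is
answered with H = 0, p = 1 rather than 0/0. Its type-I error under a flat
null is verified by simulation.

## Morphology

Area and perimeter follow the pixel-count conventions used for hand-drawn
ROIs: area = pixel count × pixel area; perimeter = count of pixels
outlining the ROI (object pixels 4-adjacent to background) × pixel side.
Circularity is $P^2 / (4\pi A)$ — 1 for a perfect circle, larger for less
circular shapes; we keep this orientation rather than inverting it. Pixel
counting is biased on oblique boundaries (a diagonal staircase step counts
one pixel for $\sqrt2$ of true length), so a crack-length estimator —
exposed pixel edges × π/4, a two-direction Cauchy–Crofton formula — is
available via `perimeter = "crofton"`; digitized disks converge to
circularity 1 under it (tested at radii 5–40 px). Objects whose pixels are
all boundary pixels are flagged `below_resolution`; a single pixel yields
the convention's $1/(4\pi)$, illustrating the small-object bias. Analysis
slices are drawn from the 30–60 µm depth window with a seeded sample of up
to 125 ROIs. The package measures segmented masks where the original
workflow drew ROIs by hand on pseudocolor images; circularity values are
therefore comparable in convention but not in ROI provenance.

## Longitudinal matching

Sessions are matched by greedy nearest-centroid assignment within a radius
(default 10 µm, soma scale): candidate pairs sorted by displacement, ties
broken by index, each follow-up object used once; unmatched baseline
objects are "disappeared". An exhaustive optimal assignment is available
for small sessions and the tests show greedy equals optimal whenever true
displacements are below half the radius. The 2×2 survival table splits
baseline ratio at 1.4 (strict `>`), and group baseline ratios are compared
with a Student t-test (equal variances), with the degenerate
zero-within-variance case answered deterministically (t = 0, p = 1 when the
group means agree).

## Cohort statistics

Group comparisons respect the hierarchy mice → volumes: a linear
mixed-effects model `response ~ group + (1 | mouse)` fitted by REML
(lme4), least-squares means ± SE per group via emmeans, and Satterthwaite
degrees of freedom for contrasts (lmerTest). Each group needs at least two
mice; with one observation per mouse the fit collapses, as it should, to a
two-sample comparison of mouse means (tested). The response variable is
caller-specified (volume mean ratio, overload %, ΔR/R₀), since the
appropriate residual unit varies by question. A mouse-level cluster
bootstrap (`cluster_bootstrap()`, percentile CI of the difference of group
means of per-mouse means) serves as a nonparametric cross-check; the two
agree in sign and approximate magnitude on recovery simulations but weight
mice slightly differently, so exact equality is not expected. Significance
is declared at p < 0.05.

Simulation checks in the test suite use 11 vs 7 mice × 10 volumes with
σ(mouse) = 0.03 and σ(residual) = 0.05: 500 replicates for effect-size
recovery (true difference 0.06) and 1000 for the null rejection rate —
sizes chosen so Monte-Carlo error is well below the tolerances being
verified.

## The synthetic-data generator

`generate_stack()` emulates the structure of an in-vivo acquisition:

* ellipsoidal objects — ~80 % small elongated "neuritic" mitochondria
  (semi-axes ≈ 0.3–0.6 µm laterally, 1–2 µm along the long axis) and ~20 %
  larger "somatic" clusters (1.5–2.5 µm) — placed without overlap
  (≥ 8 µm center separation) in a 16 × 128 × 128 µm field sampled at
  1 × 0.5 × 0.5 µm;
* per-voxel channel intensities encoding each object's true ratio exactly:
  CFP = I/(1+R), YFP = I·R/(1+R), with per-object intensity lognormal
  around 150 counts (CV 0.2) — so segmentation-free measurement recovers R
  to machine precision;
* true ratios drawn from a shifted lognormal above the sensor floor
  ($R_\min$ + 0.02) with mean 0.67 and SD 0.16 by default. A normal
  truncated at the floor would inflate the realized mean (the nominal mean
  sits only ~0.4 SD above the floor), whereas real ratio histograms are
  bounded and right-skewed; the lognormal keeps the realized mean at the
  nominal value. Objects are re-drawn until they rasterize to at least
  ~1.25 µm³ of voxels, so every ground-truth object actually exists in the
  image;
* slice-wise background offsets (default 10 counts) added to both channels,
  then Poisson shot noise and Gaussian read noise (SD 2);
* spherical plaques rendered into the RED channel on request.

`generate_cohort()` generates the tabular hierarchy (group → mouse → volume
→ object ratios) used by the statistics modules, with a mouse random
intercept (SD 0.03). Its default groups echo the anchors a wild-type /
transgenic comparison would show: control N(0.67, 0.16²) (≈ 2.3 % of
objects above 0.99) versus a 96:4 mixture of N(0.71, 0.13²) and
N(1.25, 0.10²) (volume mean ≈ 0.73, ≈ 5.5 % above 0.99). These are
generator settings validated against their own closed-form exceedance
probabilities — not reproductions of animal data, which a desk pipeline
cannot provide. `generate_timelapse()` provides step, slow-rise, and
exponential-decay traces for the trace-normalization utilities, and
`generate_longitudinal()` paired sessions with a ratio-rule for
disappearance (default: everything above 1.4 disappears).

All generators are pure functions of their arguments and a seed, restore
the caller's RNG state, and attach their ground truth.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: optical point-spread blurring and depth-dependent
attenuation (objects have crisp voxel boundaries), motion between slices,
spectral bleed-through between channels, photobleaching, autofluorescence
structure in the background, and non-ellipsoidal mitochondrial shapes.
Segmentation scores on synthetic stacks are therefore upper bounds; the
calibration, statistics and geometry modules are exercised on footing
equivalent to real use.

## Numerical choices and degenerate inputs

* Voxel `(z, y, x)` is centered at `((z−0.5)dz, (y−0.5)dy, (x−0.5)dx)` µm
  everywhere (centroids, distances, rasterization).
* Histogram bins are right-open with the last bin closed; normalized
  frequencies sum to exactly 1.
* All-equal titration ratios, empty masks, empty match tables,
  single-mouse groups, non-positive baselines and bin widths are rejected
  with classed errors; zero-spread overload pools and undersized ROI
  requests warn and proceed.
* Test problem sizes (stacks of 12–16 slices at 128–256 px, 10–50 objects,
  10⁴-draw pools, 200–1000 simulation replicates) were chosen so each
  suite verifies its tolerance with comfortable Monte-Carlo margin while
  the whole suite runs in a few minutes on one CPU.

## Known limitations

* The bottom-5 % background rule is biased low under shot noise (see
  above); the bias is visible in the ratio of dim few-voxel objects and
  bounded in tests at a few percent.
* The two-scale segmentation refinement needs the unsmoothed stack; the
  erosion fallback over-trims ragged objects whose blur halo falls below
  an elevated local mean (e.g. near bright neighbors).
* Greedy matching is not globally optimal for dense fields; the optimal
  mode is exponential and capped at 8 objects.
* FRET-efficiency, pH and Mg²⁺ corrections, spectral unmixing, and
  registration across sessions are out of scope; inputs are assumed
  registered.
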