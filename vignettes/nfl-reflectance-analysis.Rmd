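---
title: "Focal loss analysis of NFL reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal loss analysis of NFL reflectance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflreflect)
```

## The measurement problem

Glaucoma destroys retinal ganglion cell axons. Before the nerve fiber layer
(NFL) visibly thins, the axons lose microtubule content and with it optical
reflectivity, so the *reflectance* of the peripapillary NFL in OCT scans is
an attractive early biomarker. Raw NFL reflectivity, however, is corrupted
by two extrinsic factors:

* **beam coupling** — defocus, media opacity and vignetting attenuate the
  whole image. This is multiplicative and affects all retinal layers, so it
  cancels in the ratio of NFL intensity to a reference layer. We use the
  photoreceptor/pigment-epithelium complex (PPEC: ellipsoid zone down to
  Bruch's membrane), whose reflectivity is insensitive to the second factor
  below;
* **beam incidence angle** — nerve fiber reflectivity falls steeply as the
  beam departs from perpendicularity to the fibers. The beam's pupil
  position and the nasal offset of the nerve head make this bias vary
  predominantly as the *first harmonic of the azimuth* around the disc,
  `A cos(theta - phi)`, with per-scan amplitude and phase.

The pipeline therefore: (1) forms the NFL/PPEC ratio map, inpaints the
large-vessel shadows, divides by a normal-population normalization constant
and converts to dB; (2) removes the first azimuthal harmonic over the
peripapillary annulus; (3) averages onto 160 fiber-aligned superpixels;
(4) adjusts for age and axial length against a normative model; and (5)
summarises each eye by three diagnostic parameters and a defect-pattern
label.

## Map model and conventions

Maps are square rasters (default 400 px over 4.5 mm) centred on the disc;
all analysis happens in right-eye orientation (+x temporal, azimuth
counterclockwise from temporal), left eyes being mirrored first. The dB
transform is `10*log10` (OCT intensity is a power quantity; a `db_factor =
20` amplitude convention is available as a config option). The analytic
zone is the 1.1–2.0 mm annulus: inside 1.1 mm the disc interferes, outside
2.0 mm scan decentration can crop the raster. The normalization constant is
the average over training *normal* eyes of per-eye annulus-mean ratios —
individual eyes are never self-normalized, which would erase the very
signal of diffuse loss.

Vessel pixels carry no NFL signal; they are replaced by iterative
4-neighbour mean diffusion (Jacobi sweeps to a `1e-6` dB tolerance), i.e.
the discrete harmonic interpolant of their surroundings: continuous,
order-independent and incapable of inventing values outside the local
range. A PPEC floor of `1e-6` times the usable-pixel median guards the
division; flooded pixels are treated as vessels.

## The azimuthal filter

In polar coordinates each radius row is fitted with
`a0 + a1 cos(theta) + b1 sin(theta)` by least squares over valid samples
and the first-harmonic part is subtracted. On complete uniformly sampled
rows this equals zeroing the DFT bins ±1: the row mean and all degrees ≥ 2
(where wedge defects live) pass through exactly, while any injected
`A cos(theta - phi)` is annihilated to machine precision.

At the Cartesian level the package does *not* round-trip through a polar
resampling. `azimuthal_filter()` groups annulus pixels into 64 thin radial
rings (0.9–2.2 mm, a margin around the analytic zone) and performs the
same least-squares fit directly on the pixels of each ring, subtracting the
fitted harmonic re-centred to preserve the ring mean. Because this is an
orthogonal projection on the actual pixel sample, the filter is exactly
idempotent, exactly linear, exactly mean-preserving, and does not blur
defect edges the way interpolate–filter–interpolate would. The polar
utilities (`to_polar()`, `azimuthal_bandstop()`, `from_polar()`) remain
available for inspection and for data already on polar grids. The filter
removes degree 1 only; its behaviour is therefore identical at every
radius, which also makes it robust to the radius scaling caused by axial
length. The price of the filter is that genuinely asymmetric disease whose
signature happens to sit in the first harmonic is attenuated; this is the
accepted trade-off for suppressing the incidence bias.

Masked fits require the valid samples of a ring to span more than half the
circle; degenerate rings pass through unfiltered with a warning.

## The superpixel grid

The annulus is divided into 32 angular *tracks* times 5 radial *segments*
(equal radial width, 0.18 mm each; equal-area division is a config
alternative). Tracks follow a parametric arcuate trajectory model —
`theta(r) = theta0 + curvature * sin(theta0) * (r - r_in)/(r_out - r_in)`,
non-crossing for `|curvature| < 1` (default 0.5; straight radial spokes are
the fallback) — and their widths are set so each track carries an equal
share of the angular nerve-fiber flux profile. With the default double-hump
profile the arcuate regions get narrow, dense tracks, weighting the regions
glaucoma attacks most. Track 1 starts at the temporal horizontal and tracks
increase counterclockwise (right-eye frame); segment 1 is innermost. These
ordering conventions are declarations of this implementation, not
properties of the data.

Equal-flux boundaries invert the cumulative flux integral on an 8192-point
grid; the per-track flux imbalance is below 0.1% for smooth profiles.
Pixel membership is found by tracing each pixel back to its entry angle
with a fixed-point iteration (a contraction for `|curvature| < 1`,
converged to `1e-12`).

## Normative model and adjustment

On normal eyes the superpixel reflectance is modelled by a linear
mixed-effects regression with fixed effects age, axial length, their
interaction and gender, and random intercepts for **superpixel location
and for eye**. The eye intercept is essential: superpixel values within
one eye are strongly correlated, and omitting it shrinks the covariate
standard errors several-fold below their true sampling variability. With
complete 160-superpixel data the design is balanced, so the fixed-effect
slopes equal those of regressing per-eye mean reflectance on the
covariates; `method = "fast"` uses that shortcut inside the bootstrap
loop (it carries valid eye-level standard errors but no variance
decomposition).

Covariates are centred at the reference point — age 50 years, axial length
23.6 mm (the normal-group mean) — so adjustment,

```
adjusted = value - b_age*(age-50) - b_axl*(AL-23.6) - b_int*(age-50)*(AL-23.6),
```

is exactly the identity there. Gender stays in the fit (it absorbs
variance and is reported) but out of the adjustment. Per-superpixel means
and SDs of the *adjusted* normal values give plug-in Gaussian cutoffs
`q5 = mu - 1.6449 sigma`, `q1 = mu - 2.3263 sigma`. The normality
assumption is checked by Shapiro–Wilk on an independent subsample (one
superpixel per eye, deterministic rotation): pooling all 5600 correlated
values would invalidate the test's iid null and reject even perfectly
Gaussian margins.

Cross-validation uses the 0.632+ bootstrap: each trial resamples the
normal eyes with replacement (≈ 63.2% unique in-bag), fits adjustment and
cutoffs in-bag, and scores out-of-bag normals plus all glaucoma eyes;
per-eye parameters are averaged over trials. The plug-in cutoff is mildly
anticonservative at small training n (a t- vs z-quantile effect: expected
false-positive rate ≈ 5.7% at n = 35, ≈ 5.1% at n = 200). The calibration
check in the acceptance suite therefore uses large training cohorts and
averages the held-out false-positive rate over replicated train/test
pairs: held-out superpixel values are correlated within an eye and share
each fit's estimation error, so replication — not merely more draws — is
what pins down the procedure's expected calibration.

## Diagnostic parameters and patterns

* **average reflectance** — mean of the 160 adjusted values (dB);
* **low-reflectance superpixel count** — number of superpixels *strictly*
  below `q5` (ties at the cutoff are not low; measure-zero for continuous
  data);
* **focal reflectance loss** — `sum(value - mu)` over low superpixels,
  divided by 160 (dB, ≤ 0). Restricting the sum to superpixels beyond the
  5% cutoff keeps measurement noise out of the statistic, which is what
  makes it sensitive to early focal damage.

The defect pattern is classified on the 32×5 lattice of low superpixels
with 4-connectivity and cyclic wrap in the track dimension (diagonal
contact is deliberately *not* contiguity — the conservative reading):
*diffuse* = all 5 segments low in strictly more than 8 consecutive tracks
(more than a quadrant); *wedge* = a connected component touching both the
innermost and outermost segment; *other grouping* = a non-wedge component
of ≥ 3; *isolated* = low superpixels but none of the above; *none* =
empty. When patterns coexist the most severe label wins. The quadrant
threshold, connectivity and the 5%-mask choice are config options; the
published category counts distributed with the package
(`reported_pattern_counts()`) are used to verify the fraction arithmetic
(88% of glaucoma eyes vs 11% of normals with wedge/diffuse patterns; 22 of
30 preperimetric eyes).

## Statistics suite

AUC is nonparametric pair counting with ties at 0.5; its variance comes
from cluster-level structural components so two-eye-per-participant data
are handled, collapsing to the DeLong form for singleton clusters.
Sensitivity at 99% specificity places the cutoff at the smoothed quantile
of the normal scores (Gaussian-kernel KDE, Silverman bandwidth, CDF
inverted by bisection); the kernel smoothing slightly inflates the tail
quantile (factor `sqrt(1 + h^2/s^2)` for Gaussian scores), a bias that is
negligible at the n = 1e5 benchmark scale but worth remembering on small
samples. McNemar is the exact binomial test on discordant pairs. The
Gaussian-mixture clustering of (focal, average) loss uses full-covariance
mclust with its deterministic hierarchical initialisation. The piecewise
severity regression fixes the breakpoint at −6 dB VF MD rather than
estimating it.

## The synthetic-eye generator

The generator emulates exactly the statistical structure the pipeline
assumes, so every stage is testable without clinical data:

* an angular reflectance template with inferotemporal (6:30), superotemporal
  (11:00) and secondary superonasal (1:00) von Mises peaks, normalized to a
  0 dB annulus mean by construction;
* a per-superpixel population SD of 1.8 dB, budgeted as eye-level offset
  (0.7 dB) + per-scan angularly correlated measurement noise (0.55 dB) +
  intrinsic angular field (the remainder). Angular fields are random
  Fourier series over degrees 2–24 (degree 0 is the eye offset; degree 1 is
  reserved for the incidence bias), with the spectrum rescaled so the SD
  *after* superpixel-window averaging hits the target; the intrinsic field
  blends two independent series across radius so inner and outer segments
  decorrelate;
* a per-scan incidence bias `A cos(theta - phi)` with `A = |N(0, 0.75 dB)|`
  and uniform phase — with these defaults the pooled between-repeat SD
  lands near 0.7 dB unfiltered and 0.55 dB filtered, the regime the filter
  is meant for;
* white per-pixel speckle-like noise (0.6 dB) that averages out over
  superpixels; a beam-coupling field applied to both bands (cancelled by
  the ratio); radially oriented curvilinear vessels biased toward the
  arcades; defects specified in *track space* (aligned with trajectories)
  so ground-truth superpixel masks are exact.

Cohorts mimic the study population: 35 normal / 30 preperimetric / 35
perimetric eyes; normal ages 60.0 ± 10.8 yr (truncated 40–80), axial
lengths 23.6 ± 0.9 mm; covariate effects default to −0.03 dB/yr and
−0.4 dB/mm; preperimetric eyes draw defect patterns in proportion
10:12:4:3:1 (diffuse:wedge:other:isolated:none) at 3.5–5.5 dB depth,
perimetric eyes 24:11 diffuse:wedge at 4.5–10 dB. Every generator is a pure
function of (config, seed).

What the generator does *not* emulate: real OCT speckle statistics,
peripapillary atrophy, segmentation failures, media-opacity spatial
structure, or disease-driven template remodelling. Passing tests therefore
demonstrate the *internal* correctness and calibration of the pipeline,
not clinical performance; the published accuracy figures depend on the
clinical cohort and are treated as directional references only.

## Problem sizes and numerical choices

The test and acceptance runs use the full 400-px raster for the end-to-end
cohort (35/30/35 eyes) and the repeatability experiment (20 eyes × 2
repeats), and a 200-px raster of identical physical extent for unit-level
image tests; resolution only changes pixel counts per superpixel, not the
physics. Statistical calibration experiments (covariate recovery over 50
replicates, cutoff false-positive rates at 1e4 draws) run at superpixel
level, where the generator draws the same model directly. Inpainting stops
at `1e-6` dB; harmonic fits require > half-circle support; equal-flux
inversion uses 8192 quadrature nodes; the KDE cutoff bisection runs to
machine tolerance. Missing superpixels (empty aggregation) propagate as
`NA` and are excluded from fits, never imputed.

## Known limitations

* The trajectory model and flux profile are stylized parametric stand-ins;
  with real data users should supply trajectory/flux inputs derived from
  their own measurements.
* The plug-in Gaussian cutoffs ignore training-sample estimation error
  (anticonservative by ~0.7 percentage points at n = 35).
* The azimuthal filter removes genuine first-harmonic disease signal along
  with the bias.
* Superpixels near large vessels inherit inpainted (interpolated) values.
* The pattern classifier is an explicit operationalization of a taxonomy
  that was originally human-assigned; its thresholds (quadrant rule,
  4-connectivity) are declared conventions.
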