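# nflreflect

Analysis of peripapillary **nerve fiber layer (NFL) reflectance** from
volumetric optic-disc OCT scans for glaucoma detection.

Glaucoma reduces the optical reflectivity of retinal ganglion cell axons
before the NFL measurably thins, but raw reflectivity is confounded by beam
coupling (media opacity, defocus) and by the beam incidence angle, whose
variation around the disc is dominated by the first azimuthal harmonic
`A·cos(θ − φ)`. This package implements the full pipeline that turns a pair
of en-face intensity maps into calibrated diagnostic parameters:

1. **Normalized reflectance map** — the NFL-band summed intensity is divided
   by the mean intensity of the photoreceptor/pigment-epithelium complex
   (PPEC) pixel by pixel, vessel shadows are inpainted, the ratio is divided
   by a normal-population constant and expressed in dB
   (`10·log10(ratio / constant)`).
2. **Azimuthal filtering** — the first azimuthal harmonic is removed over the
   1.1–2.0 mm peripapillary annulus by mask-aware least squares in thin
   radial rings, annihilating the incidence-angle bias while preserving ring
   means and all higher harmonics (where wedge defects live) exactly.
3. **Superpixel grid** — the annulus is partitioned into 32 nerve-fiber-
   trajectory-aligned tracks of equal fiber flux × 5 radial segments = 160
   superpixels, and the map is averaged per superpixel.
4. **Normative model** — on normal eyes, superpixel reflectance is regressed
   on age, axial length, their interaction and gender in a linear
   mixed-effects model (random intercepts for superpixel and eye); all eyes
   are adjusted to age 50 / axial length 23.6 mm, and per-superpixel Gaussian
   5% / 1% cutoffs are derived from the adjusted normal distribution.
5. **Diagnostic parameters** — per eye: the *average reflectance*
   `mean(adjusted)`, the *low-reflectance superpixel count*
   `#{s : adjusted_s < q5_s}`, and the *focal reflectance loss*
   `Σ_{s low} (adjusted_s − μ_s) / 160` (dB ≤ 0), plus a five-way defect
   pattern (diffuse / wedge / other grouping / isolated / none) from
   connected components on the 32×5 lattice.
6. **Statistics** — clustered-data nonparametric AUC (cluster-robust
   variance), sensitivity at 99% specificity via a Gaussian-KDE cutoff,
   exact McNemar, Wilcoxon, pooled repeat-scan SD, bootstrap comparison of
   Pearson correlations, Gaussian-mixture clustering of loss phenotypes, and
   two-segment piecewise regression against visual-field mean deviation.

A synthetic-eye generator (`sim_config()`, `make_normal_map()`,
`make_cohort()`, `inject_defect()`, `make_repeat_scans()`) reproduces the
statistical structure the pipeline assumes — double-hump angular template,
1.8 dB per-superpixel population SD, per-scan first-harmonic bias, vessels,
trajectory-aligned defects — so every stage is testable end to end without
clinical data. See the methods vignette
(`vignettes/nfl-reflectance-analysis.Rmd`) for models, parameter choices and
limitations.

## Worked example

```r
library(nflreflect)

sc  <- make_cohort(sim_config(), seed = 7)   # 35 normal / 30 PPG / 35 PG
fit <- fit_normative(sc$cohort)              # LME on the normal eyes
print(fit)
#> <nfl_normative> lme fit on 35 normal eyes, 160 superpixels
#>   coefficients (dB/yr, dB/mm, dB/(yr*mm)):
#>          age axial_length      age_axl
#>      -0.0540      -0.4101       0.0062

summary(fit)
#> Normative model (lme fit, 35 normal eyes)
#>              estimate      se       p
#> age          -0.05395 0.02282 0.02471
#> axial_length -0.41008 0.33035 0.22409
#> age_axl       0.00623 0.02658 0.81630
#> mean superpixel SD 1.81 dB, peak 2.34 dB
#> Shapiro-Wilk on standardized adjusted values: P = 0.74

res <- predict(fit, sc$cohort)               # per-eye diagnostic parameters
head(res[c("eye_id", "group", "average_reflectance",
           "low_count_5", "focal_loss", "pattern")], 4)
#>   eye_id  group average_reflectance low_count_5 focal_loss        pattern
#> 1 eye001 normal         -0.01266252          11 -0.2472543 other_grouping
#> 2 eye002 normal         -1.31050307          50 -1.2203614          wedge
#> 3 eye003 normal          0.11658348          15 -0.3561147          wedge
#> 4 eye004 normal          0.14716765          11 -0.2534064 other_grouping

auc_clustered(-res$focal_loss, res$group != "normal", res$eye_id)
#> AUC 0.932 ± 0.025 (95% CI 0.883-0.982; 65+/35-, 100 clusters)
```

The fitted coefficients recover the generator's covariate effects
(−0.03 dB/yr, −0.4 dB/mm) within their standard errors; the mean superpixel
SD sits at the configured 1.8 dB; and focal reflectance loss separates
glaucomatous from normal synthetic eyes with an AUC near 0.93. Glaucomatous
damage shows as a more negative focal loss, a higher low-reflectance count,
and wedge/diffuse patterns.

For file-based workflows there is a thin command-line front end
(`inst/cli/nflreflect.R`) with `simulate`, `process`, `fit-normative`,
`evaluate` and `render` subcommands over CSV/JSON artifacts.

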