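Package: nflreflect
Title: Focal Loss Analysis of Peripapillary Nerve Fiber Layer Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for normalized nerve fiber layer (NFL)
    reflectance maps from volumetric optic-disc OCT scans, aimed at glaucoma
    detection. Builds NFL/PPEC reflectance ratio maps with vessel inpainting
    and population normalization, suppresses beam-incidence-angle bias by
    removing the first azimuthal harmonic in the peripapillary annulus,
    partitions the 1.1-2.0 mm annulus into 160 fiber-trajectory-aligned
    equal-flux superpixels, fits a normative reference model on normal eyes
    with age and axial-length adjustment through a linear mixed-effects
    regression, and derives three diagnostic parameters (average reflectance,
    low-reflectance superpixel count, focal reflectance loss) plus a five-way
    defect-pattern classification. Includes clustered-data ROC analysis,
    sensitivity at fixed specificity via kernel density estimation, 0.632+
    bootstrap cross-validation, and a synthetic-eye generator for end-to-end
    validation without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lmerTest,
    mclust,
    jsonlite
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
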