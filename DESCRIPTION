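Package: stereotestis
Title: Design-Based Stereology and DAB Immunoquantification for Testicular
    Maturation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for quantitative histology of
    postnatal testis maturation. Generates synthetic seminiferous-tubule
    cross-section fields with exactly known analytic ground truth, implements
    the design-based stereological estimators (point-counting volume density,
    intersection-counting surface density, unbiased-counting-frame numerical
    density, Cavalieri volumes with Gundersen-Jensen error coefficients,
    orientator angles, systematic uniform random field sampling, shrinkage
    correction), quantifies DAB immunoreactivity on RGB fields by colour
    deconvolution (immunoreactive area percentage and mean optical density),
    computes macroscopic morphometric indices, and provides the statistical
    reporting layer (distribution checks, ANOVA/Tukey, Kruskal-Wallis/Dunn,
    compact letter displays, Fisher-z correlation intervals, principal
    component analysis with the Kaiser criterion) used to summarise such
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
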