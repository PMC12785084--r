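---
title: "Design-based stereology and DAB quantification on synthetic testis tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology and DAB quantification on synthetic testis tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereotestis)
```

## What the package models

`stereotestis` implements the complete quantitative chain of a design-based
stereological and immunohistochemical study of postnatal testis maturation:

1. a **synthetic tissue generator** producing 2D cross-section fields with
   exactly known ground truth,
2. the **sampling design** (orientator angles for isotropic uniform random
   sections, Cavalieri slab series, systematic uniform random field
   placement, shrinkage and section-thickness corrections),
3. the **stereological estimators** — volume density $V_V$ by point
   counting, surface density $S_V$ by intersection counting, numerical
   density $Q_A$ with an unbiased counting frame, absolute volumes
   $V = V_V \times V_{REF}$ — together with their error coefficients,
4. **DAB densitometry** — colour deconvolution, fixed-threshold
   segmentation, immunoreactive area (IRA, %) and mean optical density
   (IOD) — and
5. the **statistical layer** (distribution checks, ANOVA/Tukey and
   Kruskal–Wallis/Dunn with compact letter displays, Fisher-z correlation
   intervals, PCA with the Kaiser rule) that regenerates the study's
   summary tables.

Because every synthetic field carries an analytic ground truth, each
estimator can be validated for unbiasedness instead of merely for
plausibility.

## The tissue model and its ground truth

A field is a rectangle (default $600 \times 600\ \mu m$, the scale of a
low-magnification histological field) of interstitium into which circular
seminiferous-tubule profiles are packed by random sequential adsorption
until a target area fraction is reached (generation fails loudly if the
achieved packing deviates more than 10% from the target). Each tubule is an
annulus: the lumen radius is $r\sqrt{f_{lumen}}$ so that the lumen occupies
exactly the fraction $f_{lumen}$ of the profile. Cells are circular
profiles: Leydig cells lie wholly in the interstitium (mutually
non-overlapping), Sertoli and germ cells lie wholly inside an epithelium
annulus; epithelial cell profiles of the same class may overlap slightly,
as nuclear profiles in a packed epithelium do.

Ground truth is computed **analytically from the circles** — area fractions
from exact disk–rectangle intersection areas (closed-form quadrant
integrals, so border-crossing profiles are clipped exactly), boundary
length from exact clipped arcs, and profile densities by the
centre-in-field rule — never from a raster. Rasterisation
(`rasterize_labels()`) exists for the image-based parts of the pipeline and
converges to the analytic fractions as the pixel size shrinks; the test
suite asserts this at 2 and 0.5 µm/px.

The packaged age-group parameter sets (`default_cohort_setpoints()`) encode
a maturation series of five groups (6, 8, 12, 24, 36 months, $n = 5$):
epithelium volume fractions around 33–35%, growing tubule radii and lumen
fractions, Sertoli profile densities giving $Q_A \approx 96{-}102$ per
mm² and germ-cell densities of $\approx 1700{-}2000$ per mm², a constant
Leydig density, microscopic reference volumes rising from 0.34 to
2.15 mm³, and macroscopic body/testis weights with the group means and SDs
of the study design. These set points are study conditions, not tuning
knobs: the estimation pipeline is judged by how well it recovers them.

What the generator deliberately does **not** emulate: non-circular or
anisotropic tubule profiles, spermatogenic staging, optical-section (3D)
effects, uneven illumination or staining gradients, and spatial clustering
of Leydig cells beyond non-overlap. Passing tests therefore demonstrate
correctness of the estimators under the model's assumptions, not robustness
to every artefact of real micrographs.

## Probe placement and unbiasedness

The M36 grid is a $6 \times 6$ point lattice with unit length $d$, a test
segment of length $d/2$ per point (total test line $18d$), nominal test
area $36.36\,d^2$, and an unbiased counting frame (top/left inclusion
edges; bottom/right edges and their extensions forbidden). Three numerical
choices matter:

* **Toroidal probe placement.** The lattice translation is uniform within
  one grid period and positions wrap at the field boundary; the counting
  frame is dropped uniformly over the full field period and profiles are
  tested together with their $3\times3$ periodic copies. This makes every
  probe point exactly uniform over the field and gives every profile an
  acceptance probability of exactly $a_{frame}/(WH)$, eliminating edge
  bias without edge-correction weights. Exact lattice coverage additionally
  requires $6d$ to equal the field side, so the cohort default is
  $d = 100\ \mu m$ for the 600 µm field.
* **Tangency convention.** A segment tangent to a tubule counts as one
  intersection — a measure-zero event under continuous randomisation, so
  any consistent convention is unbiased.
* **Outer boundary.** "Tubule surface" is read as the outer (basal)
  boundary; the luminal boundary is available behind a flag.

With isotropic profiles (circles), horizontal test lines are unbiased for
$S_V$ without grid rotation, and in 2D the identity
$B_A = \tfrac{\pi}{4} S_V$ links the intersection-count estimator to the
analytic boundary-length density; the acceptance suite verifies the
identity to within 5% and verifies $Q_A$ against the analytic profile
density to within 5% over 100 replicate cohorts of 50 fields.

## Cavalieri volumes and the error coefficient

`cavalieri_volume()` implements $V = t\sum a_i$, unbiased under a uniform
random start (verified on sphere and ellipsoid phantoms to within 1% over
200 starts). The error coefficient uses the Gundersen–Jensen
smoothness-class $m=1$ form with **end-corrected covariogram terms**:
$B' = \frac{n}{n-1}\sum a_i a_{i+1}$ and
$C' = \frac{n}{n-2}\sum a_i a_{i+2}$, with
$CE = \sqrt{\max(0, 3A + C' - 4B')/240}\,/\sum a_i$. The correction makes
the covariogram terms comparable averages regardless of series length, so a
constant slab series reports exactly $CE = 0$ (the uncorrected sums leave a
spurious positive end term), while long series recover the classical
value. The radicand is clipped at zero.

The orientator is modelled at the level of its angle laws: the azimuth
class is uniform on ten equal divisions, and the colatitude is drawn so
that $\cos\theta$ is **uniform within the selected cosine-weighted class**
— hence exactly uniform on $[0,1]$ marginally, which is the property that
makes the resulting sections isotropic uniform random. The class index and
class midpoint are reported alongside for protocol-style output. Full 3D
re-slicing of the tissue model is out of scope (the tissue model is 2D);
the angle laws are what is testable and tested.

Shrinkage follows the convention $f_L = $ geometric mean of
processed/fresh ratios, $f_A = f_L^2$, $f_V = f_L^3$ by construction, and
real section thickness $=$ block advance / sections cut. For reference
volumes the default mode is **uniform-shrinkage invariance**: $V_V$
measured on uniformly shrunken tissue is unchanged (numerator and
denominator shrink together), so the fresh volume is used directly; a
`"processed"` mode divides a processed-block volume by $f_V$ instead. Both
modes are logged in the result's attributes.

## DAB synthesis, deconvolution and thresholds

Positive staining is laid down inside Leydig profiles, cell by cell in
random order, until the positive pixel count equals the requested fraction
of the interstitial area (the last cell is filled from its centre
outwards); requesting more than the Leydig compartment can hold is an
explicit error. Optical densities (Normal, clipped at zero) are pushed
through the inverse Beer–Lambert transform with the fixed Ruifrok–Johnston
H/DAB colour vectors; intensities stay unquantised doubles so the
zero-noise round trip through `rgb_to_od()` and `separate_dab()` is exact
to machine precision (the test suite asserts $\le 10^{-6}$).

Two deliberate definitions:

* **IOD is the mean DAB optical density over the immunoreactive area**,
  not a pixel-summed integral: group IOD reference values of order 0.2–0.8
  are only compatible with a per-pixel mean, and a sum would depend on
  magnification and field size. The definition is recorded in the result.
* **The detection threshold is calibrated once** — the midpoint between
  the background DAB density and the weakest positive set point in the
  study (0.1226 OD by default) — and applied uniformly to every field and
  group, mirroring fixed-threshold practice in densitometry. Raising the
  threshold can only lower IRA and raise IOD; this monotonicity is a
  tested property.

## Statistics

* Normality: D'Agostino–Pearson omnibus ($Z_{skew}$ by D'Agostino,
  $Z_{kurt}$ by Anscombe–Glynn, $K^2 \sim \chi^2_2$), implemented in the
  package and verified against an independent reference implementation to
  $10^{-7}$. Groups of $n=5$ are below the omnibus test's validity, so the
  test runs on **pooled within-group residuals** and refuses pooled
  $n < 8$ with an explicit flag.
* Homogeneity: median-centred Levene (Brown–Forsythe) via `car`.
* Parametric branch: one-way ANOVA + Tukey HSD; non-parametric branch:
  Kruskal–Wallis + Dunn mean-rank $z$ tests with tie correction,
  unadjusted two-sided by default (a Bonferroni option exists). The branch
  router is configuration, with macroscopic variables conventionally
  parametric and stereological/IHC variables non-parametric.
* Compact letter displays are built by insert-and-absorb over the pairwise
  significance matrix; a brute-force test checks on every output that two
  groups share a letter exactly when they are not significantly different.
* Correlations report $r$, $R^2$, the $t$-based $p$
  ($t = r\sqrt{n-2}/\sqrt{1-r^2}$) and the Fisher-z 95% interval
  $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$. The age-correlation
  table is computed on the **five group means against age** ($n = 5$) —
  the only convention under which a printed morphometric correlation table
  of this design (its $r$, CI and $p$) is reproducible — and this
  convention is what `reference_correlation_table()` implements.
* PCA z-scores columns ($n-1$ SD), eigendecomposes the correlation matrix,
  retains components with eigenvalue $> 1$ (strict Kaiser), and fixes
  signs so each loading vector's largest element is positive.

A unit note: the gonadosomatic index is implemented exactly as
testis weight / body weight × 100 with both masses forced into the same
unit (the conversion is recorded in the output attributes), and the
T-index uses millimetres and kilograms — the only convention consistent
with reference T-index magnitudes. Published GSI tables of this design are
not reproducible from their own printed weights under any single unit
convention, which is why every morphometric function demands explicit
units and why GSI reference values are not recovery targets anywhere in
the package.

## Precision accounting and a structural limitation

Per-animal CEs use the Cochran ratio-estimator form across fields;
`precision_decomposition()` splits group variance into biological CV and
estimation noise (OCV/OCE, subtraction in quadrature, floored at zero).

One limitation deserves emphasis. With the M36 grid, 50 fields contribute
$50 \times 36 = 1800$ points per animal. For a compartment occupying a
fraction $p$ of the tissue, the point-count CE cannot fall below the
binomial floor $\sqrt{(1-p)/(1800\,p)}$ — about 6.5% at $p = 0.115$
(lumen) and 7.5% at $p = 0.09$ (Sertoli), however carefully the grid is
randomised (systematic grids beat the floor only for structures larger
than the point spacing). A blanket "CE below 5% for every estimator" is
therefore **not attainable for the rare compartments at this sampling
intensity**; the corresponding acceptance check documents this honestly
rather than relaxing the gate: the abundant compartments, $S_V$, $Q_A$ and
the Cavalieri volumes meet 5% comfortably, the rare-compartment volume
densities do not. Reaching 5% there would need roughly 2.5× more points
(more fields or a denser point grid).

## Problem sizes and reproducibility

The shipped validation uses 100 replicate estimations of 50 fields for the
unbiasedness checks, the full 25-animal cohort at 50 fields per testis for
the precision accounting, and 5 animals × 5 fields per group for the DAB
recovery — sizes chosen so the whole validation runs in minutes on one
core while keeping Monte-Carlo error well below the tolerances tested.
Every random step is a pure function of an explicit seed: cohorts derive
per-animal and per-field seeds from a single master seed, so
`generate_cohort()` and both pipelines are byte-reproducible.

## A short tour

```{r, eval = FALSE}
# one field and its ground truth
geom <- generate_geometry(tissue_params(), seed = 42)
truth <- analytic_ground_truth(geom)

# estimate from 50 fields
recs <- lapply(1:50, function(s) {
  count_field(generate_geometry(tissue_params(), s), build_grid(100, s))
})
estimate_vv(recs)
pi / 4 * estimate_sv(recs)$sv   # compare with truth$B_A
estimate_qa(recs)

# the cohort pipelines
cfg <- cohort_config(master_seed = 1)
cohort <- generate_cohort(cfg)
ihc <- run_ihc_pipeline(cohort, ages = c(6, 36))
aggregate(cbind(ira, iod) ~ age_months, ihc$animals, median)
```
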