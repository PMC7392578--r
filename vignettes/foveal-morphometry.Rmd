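---
title: "Foveal morphometry from infant OCT: models, landmarks and longitudinal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal morphometry from infant OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveametry)
```

## The problem

In preterm infants the fovea is still forming: the pit is shallow, inner
retinal layers persist across the center, and the contour changes week by
week between roughly 31 and 44 weeks postmenstrual age (PMA). Hand-held
OCT makes it possible to image this process at the cot-side, and the shape
of the internal limiting membrane (ILM) — the inner boundary of the retina
— carries quantitative information about both the degree of prematurity
(gestational age, GA; birthweight, BW) and retinopathy of prematurity
(ROP). `foveametry` implements the full measurement chain from a raw
B-scan to longitudinal mixed-effects models of six foveal parameters, plus
a synthetic-data generator with known ground truth so that every stage can
be validated without patient data.

## The contour model

Each half of the pit-centered ILM profile (nasal and temporal, distance
$d = |x| \ge 0$ from the pit center) is modelled as a difference of
Gaussians over a shared baseline:

$$h_s(d) = B + A_{para,s}\, e^{-d^2 / 2\sigma_{para,s}^2}
             - A_{pit,s}\, e^{-d^2 / 2\sigma_{pit,s}^2},
  \qquad s \in \{\text{nasal}, \text{temporal}\}.$$

The narrow inverted Gaussian ($A_{pit} \ge 0$, $\sigma_{pit}$) carries the
pit; the wide Gaussian ($A_{para}$ free in sign, $\sigma_{para}$) carries
the parafoveal mound. In immature retinas the parafovea frequently slopes
*inward* instead of mounding — the fitted wide Gaussian then has negative
amplitude, which `classify_parafovea()` reports as an *inverted*
parafovea. Modelling the two sides separately respects the known
nasal–temporal asymmetry of the fovea.

Fitting (`fit_dog()`) is bounded Levenberg–Marquardt least squares with an
analytic Jacobian, minimizing the residual sum of squares plus a penalty
$\lambda\,(h_s(0) - h_{obs}(0))^2$ per side that ties both half-fits to
the observed pit-bottom height — a continuous contour must have the same
height at $d = 0$ from either side, and the shared baseline $B$ plus this
penalty (default $\lambda = 10$) enforce that agreement softly.
Data-driven starting values follow the typical profile (narrow inverted +
wide non-inverted Gaussian) and five jittered restarts (±30%, seeded)
guard against local minima.

Numerical choices that matter:

* **Bounds.** $B \in [0, 2000]$, $A_{pit} \in [0, 1000]$,
  $A_{para} \in [-1000, 1000]$ µm; $\sigma_{pit} \in [20, 2000]$,
  $\sigma_{para} \in [500, 5000]$ µm. The asymmetric width boxes are
  deliberate: with a common lower bound the optimizer can repurpose the
  "parafoveal" Gaussian as a spike a few pixels wide at the pit center,
  which leaves the fitted heights almost unchanged but destroys the
  derivative-based landmarks below. A 500 µm floor encodes that the
  parafovea is a millimetre-scale structure, and incidentally enforces
  $\sigma_{pit} < \sigma_{para}$ in practice.
* **Tolerances.** Cost and parameter tolerances are $10^{-10}$; on
  noise-free synthetic profiles all nine parameters are recovered to well
  below 0.1% (machine precision in practice).
* **Degenerate inputs.** A flat profile fits with $A_{pit} \approx 0$ and
  is flagged `degenerate` rather than raising an error.
* **Identifiability.** With 2 µm height noise and 500 samples the pit
  parameters are estimated to a few percent, but the parafoveal pair
  ($A_{para}$, $\sigma_{para}$) is nearly collinear with the baseline
  inside a 10 mm window and carries roughly twice the relative
  uncertainty. Tests assert 5% recovery for the pit terms and 10% for the
  parafoveal terms at these conditions.

## Landmarks and the six parameters

All parameters derive from closed-form derivatives of the fitted contour
(`dog_eval()` implements orders 0–3 analytically):

* **Rim edge** (`locate_rim_edge()`): the maximum of the *third*
  derivative of $h_s$ over $(0, d_{max}]$ — the earliest indication of
  the ILM falling away into the pit. The classic rim definition (zero
  slope at the crest) fails when the contour keeps rising beyond the rim,
  as it often does with an inverted parafovea; the third-derivative rule
  applies identically to every fit. For a pure single-Gaussian pit it has
  the closed form $d^* = \sigma_{pit}\sqrt{3 + \sqrt{6}} \approx
  2.3344\,\sigma_{pit}$ (the relevant root of $d^4 - 6\sigma^2 d^2 +
  3\sigma^4 = 0$), which the implementation reproduces and the tests
  verify against brute-force grids. The maximum is bracketed on a 1 µm
  grid and refined by golden-section search; a maximum on the search
  boundary raises a rim-not-found error rather than returning a spurious
  landmark.
* **Width** = nasal + temporal rim distance.
* **CFT** (central foveal thickness) = fitted height at $d = 0$ (heights
  are measured above the Bruch membrane, so height equals thickness),
  averaged over the two half-fits; the raw-sample CFT is also emitted.
* **Depth** = mean rim height − CFT. The per-side depths are reported
  too, since asymmetric rims make "the" depth a convention.
* **Area** = area between the chord joining the two rim points and the
  contour, from the closed-form Gaussian integral
  $\int_0^a e^{-d^2/2\sigma^2}\,dd = \sigma\sqrt{2\pi}\,(\Phi(a/\sigma) -
  \tfrac12)$; tests require agreement with a 0.1 µm trapezoid oracle to
  0.1%.
* **Steepest slope** (`steepest_slope()`): maximum $|h_s'|$ on
  $(0, d^*]$, reported as a gradient (µm/µm) and in degrees
  ($\arctan$ of the gradient) since the field uses both.
* **pRT** (parafoveal retinal thickness): fitted height at 1000 µm per
  side, from the fitted contour by default (noise robustness); a flag
  switches to the nearest raw sample. Profiles shorter than 1000 µm on a
  side yield a flagged missing value, not an error.

These definitions make the metrics invariant under horizontal translation
(the profile is re-centered before fitting) and under left/right
mirroring with nasal/temporal labels swapped; scaling all heights by $c$
scales CFT, depth, area and slope by $c$ and leaves width and rim
distances unchanged. All three invariances are property-tested.

## From B-scan to profile

`detect_bruch()` finds the deepest hyperreflective band per A-scan
(threshold at 70% of the column intensity range — above tissue speckle
excursions, below the Bruch band — taking the deepest run of at least two
super-threshold pixels). Failed columns are interpolated and flagged; more
than half failing is a segmentation error. `flatten_bscan()` translates
each A-scan by an integer number of rows so Bruch sits on a reference row,
mirroring the acquisition-style flattening of individual A-scans
(sub-pixel flattening is deliberately not the default: integer shifts keep
pixel statistics untouched). `segment_ilm()` traces the first
vitreous-to-retina transition from the top, applies a running-median
smoothness refinement (maximum column-to-column jump 5 px by default), and
accepts an optional override table of (column, row) corrections — a
reproducible stand-in for manual touch-up. `select_foveal_bscan()` picks
the volume slice whose deepest ILM point is deepest overall, requires five
well-formed slices on either side, and resolves exact depth ties toward
the central slice and then the lower index. `to_micrometers()` applies
the pixel scales and the infant lateral-scale correction, and re-centers
the lateral axis at a sub-pixel pit center estimated by a quadratic fit
around the deepest samples (using the plateau midpoint when integer
quantization flattens the minimum).

The lateral correction deserves a note: OCT scanners assume an adult
axial length, and infant eyes are shorter, so the true lateral extent is
smaller than nominal. The published conversion values are not
redistributable; the correction therefore ships as a user-supplied factor
or per-(PMA, GA) table. A missing table entry is a hard error — never a
silent default — and omitting the correction entirely produces an identity
factor with a loud warning.

## The synthetic-data generator

`gen_ilm_profile()` samples the same two-sided DoG family the fit
estimates, plus i.i.d. Gaussian height noise — so noiseless recovery is an
exact identity test, not an approximation. `gen_bscan()` renders a
three-band piecewise-constant image (dark vitreous, bright ILM band,
mid-gray tissue, bright Bruch band) with optional Gaussian blur and
multiplicative log-normal speckle; real OCT speckle statistics are *not*
emulated, and the renderer only guarantees that the returned per-column
boundary rows are exactly the bands drawn. Axial depth defaults to 512
rows over 2 mm; the lateral geometry defaults to 500 A-scans over 10 mm
(20 µm/px).

`gen_cohort()` generates the longitudinal study structure: visits every
1–2 weeks across 31–44 weeks PMA, foveal width following group-specific
linear PMA trends (−11.18 µm/week without ROP, +24.96 µm/week with ROP,
around 32-week intercepts of 1,584.9 and 1,203.6 µm), quadratic PMA
trends for depth, CFT and slope, GA/BW effects on the secondary
parameters, a per-infant random intercept and visit-level residual noise.
The variance components are not published quantities: between-infant SD
150 µm and residual SD 100 µm (width; other parameters scaled
proportionally) were chosen once as values that make the effects visible
but recoverable at the study's sample size, and the other parameters'
generating coefficients (`default_param_effects()`) are likewise
plausible-magnitude inventions, not published estimates. ROP status is
persistent by default (per-visit transition probability 0, configurable
to emulate the mixed-status subgroup). What passing recovery tests show
is therefore that the *pipeline and models are correct and calibrated
under the stated effect structure* — not that real infant data behave
this simply: real contours deviate from the DoG family, segmentation
errors are not i.i.d., and visit schedules are irregular.

Each generator draws from its own named substream of the user seed, so
adding one generator never perturbs another, and identical spec + seed
gives bit-identical outputs (tables and images).

## Longitudinal models

`fit_mixed_model()` fits, per foveal parameter,

```
value ~ pma_c * rop + [pma_c^2] + (ga | bw) + sex + ethnicity + birth +
        eye [+ side] + (1 | infant_id)
```

by REML, with PMA centered at 32 weeks so the ROP main effect is the
32-week contrast. GA and BW are *separate predictor models* — the two
prematurity measures are strongly collinear, so the adjustment uses one
or the other, never both. Depth, CFT and steepest slope change
nonlinearly with PMA and take the optional quadratic term; slope and pRT
are modelled "sided" (long format with a nasal/temporal factor). The
random structure is a single intercept per infant; eye enters as a fixed
effect, since it is itself a factor of interest, and inter-eye
correlation beyond the shared infant intercept is not modelled — a
documented simplification, configurable in principle but fixed here.
Per-term tests are Wald-type t-tests with Satterthwaite degrees of
freedom; under a null cohort with no ROP effect the ROP×PMA test rejects
at 6–7% of 500 seeded replicates at the 5% level with 25 infants (the
calibration study in the acceptance suite). Visit-level ROP status enters
the model, so mixed-status infants contribute to both groups. No
multiplicity correction is applied across the six parameters; p-values
are per-parameter.

`predict_means()` evaluates the fixed-effect predictor at covariate
profiles with Wald 95% intervals, flags PMA extrapolation, and reports
the ratio of two predicted means as an integer percentage
(half-up rounding).

`cohort_accounting()` reproduces cohort-flow percentages using
largest-remainder (Hamilton) rounding within each family — exclusions
over the recruited denominator, ROP patterns over the analyzed
denominator — so each family sums to exactly 100%. This is the rounding
scheme consistent with the published cohort flow (e.g. 57/87 = 65.52%
reported as 65% within a 65 + 22 + 13 = 100 partition); plain half-up
rounding of each value in isolation cannot reproduce such tables.

## Problem sizes used in validation

The shipped validation suite runs: slope recovery on an 80-infant
two-eye cohort (~1,500 visit records); noiseless identifiability on
500-sample profiles and one 512×500 B-scan; oracle agreement on dozens of
random parameter draws; and the type-I study on 500 null cohorts of 25
infants (single eye). These sizes were chosen to give stable statistical
conclusions from a single seeded run.

## Worked example

```{r example, eval = FALSE}
# simulate, preprocess, fit, measure
sim <- gen_bscan(profile_truth(seed = 1))
profile <- preprocess_bscan(sim$image, lateral_correction = 1)
fit <- fit_dog(profile)
compute_metrics(fit, profile)

# longitudinal modelling on a synthetic cohort
cohort <- gen_cohort(cohort_spec(n_infants = 80, seed = 1))
model <- fit_mixed_model(cohort$table, "width", adjustment = "ga")
model
predict_means(model, list(list(pma = 32, rop = "present"),
                          list(pma = 32, rop = "absent")))
```

## Known limitations

* The DoG family cannot represent every immature contour (e.g. cystoid
  changes); such scans should be excluded upstream, as the exclusion
  flags in the cohort table anticipate.
* Only the ILM and Bruch boundaries are segmented; inner-layer
  persistence, cyst morphology and FAZ measurements are out of scope.
* The B-scan renderer is a geometric phantom, not a physical speckle
  model; segmentation robustness on real scans must be established
  separately.
* The mixed models assume a common residual variance across PMA and a
  single random intercept; richer covariance structures (random slopes,
  inter-eye correlation) are not fitted.
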