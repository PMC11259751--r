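---
title: "Methods: scaling analysis and acoustic predictions for canid ear morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling analysis and acoustic predictions for canid ear morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earscaling)
```

## The scientific question

Domestic dogs span an enormous range of body and skull sizes, yet behavioural
audiograms of breeds as different as a Chihuahua and a St Bernard are
strikingly similar. `earscaling` implements the quantitative chain needed to
examine this paradox from skeletal measurements alone: how do middle- and
inner-ear structures (ear cavity, ossicles, eardrum, stapes footplate, bony
labyrinth) scale with skull size across breeds, and what hearing differences
would standard acoustic models predict from those differences in size?

The package operates on per-specimen tables of micro-CT-derived measurements:
condylobasal length (CBL, the skull-length index), maximum zygomatic skull
width (MSW), interaural width (IW), middle-ear cavity volume (ossicles
excluded), malleus/incus/stapes/bony-labyrinth volumes, tympanic-membrane and
stapes-footplate areas, and optional annulus diameters, malleus length and
cochlear turns.

## Data model and units

A cohort is a data frame subclass (`ear_cohort`) with one row per specimen.
Internal canonical units are mm, mm², mm³ and mg; millilitres are accepted on
input only (1 mL = 1000 mm³) because cavity volumes are often reported that
way. Column mappings, per-column units and role assignments are supplied by a
schema (optionally read from a YAML key-value file), since source spreadsheets
have arbitrary headers.

Two design rules matter for the statistics downstream:

* **Roles.** Each specimen is `fit` or `projected`. Projected specimens (for
  example a mongrel or a wolf retained for comparison) never enter
  correlations or regressions; they are projected onto the fitted lines
  afterwards and assessed by the fit's own residual spread.
* **Missingness is per trait, never per specimen.** A damaged ossicle removes
  one cell, not the whole animal: every correlation cell and every regression
  uses its own pairwise-complete set. This mirrors how real skeletal material
  fails (e.g. a malleus lacking its manubrium tip is excluded from malleus
  analyses only).

## Derived morphometrics

* **Tympanic-membrane area.** The pars tensa is treated as a flat ellipse
  bounded by the bony annulus: area `= π·(d1/2)·d2`, with `d1` the longest
  annulus diameter and `d2` the maximum perpendicular distance to the
  perimeter (a semi-minor axis). When a directly measured area and the
  diameters are both present, the direct measurement wins and a consistency
  warning is raised if the ellipse estimate differs by more than 1% — flat
  estimates are known to overestimate the true curved surface by around 10%,
  and `percent_overestimate()` quantifies exactly that kind of bias.
* **Ossicle masses.** CT reconstructions yield volumes; masses follow as
  volume × density. Defaults are densities measured by weighing dissected
  ossicles of a medium-sized dog: malleus 2.04 mg/mm³, incus 2.09 mg/mm³. No
  intact stapes could be weighed in that reference animal, so the stapes
  density defaults to the incus value — a stated assumption, not a
  measurement.
* **Cephalic index** `= 100·MSW/CBL` (dimensionless; high = brachycephalic)
  and the **anatomical area ratio** (tympanic membrane / stapes footplate),
  the quantity classical impedance-transformer accounts of the middle ear are
  built on.

## Scaling analysis

All scaling work is done on base-10 logarithms. For each ear trait we fit
ordinary least squares of `log10(trait)` on `log10(CBL)`:

* slope `b = Sxy/Sxx`, intercept `a = ȳ − b·x̄`, `R² = b·Sxy/Syy`,
  `se_b = sqrt((Syy − b·Sxy)/((n−2)·Sxx))`.

OLS (rather than reduced major axis) is the deliberate choice for predicting
a trait from a size index; no phylogenetic correction is applied because
breed hybridization makes a tree-based correction ill-defined for domestic
dogs, and no multiple-testing correction is applied across the seven trait
fits (the report says so). The closed-form estimator is implemented directly
and is cross-checked in the test suite against R's QR-based `lm()` to 1e-9.

**Isometry test.** Geometric similarity predicts log-log slopes of 3 for
volumes, 2 for areas, 1 for lengths. We test `H0: b = expected` with
`t = (b − expected)/se_b` on `n − 2` degrees of freedom, two-tailed. A
one-tailed reading of "significantly lower" would halve the p-values; the
two-tailed point-null convention is reported explicitly, and the direction of
allometry is given alongside as the sign of `b − expected`. Slopes below the
expectation indicate negative allometry: larger dogs have absolutely larger
but relatively smaller ear structures.

**Degenerate fits.** With zero residual variance `se_b = 0` and the t
statistic is undefined. We define `p = 1` when the slope equals the
expectation exactly and `p = 0` otherwise — the continuous limit, which keeps
noise-free property tests total. "Zero" is decided at relative tolerance
`SSE < 1e-12·Syy` so that binary floating-point noise on exact data does not
leak into the t statistic.

**Outliers.** Standardized residuals divide each residual by the sample
standard deviation (n−1 denominator) of all fit residuals; |z| > 2 flags a
specimen. These are raw standardized residuals by construction — not
internally/externally studentized residuals — because that is the definition
appropriate to reproducing the published workflow this package automates.
Projection of a held-out specimen uses the same fit-derived
`sd_resid`: `z = (y0 − (a + b·x0))/sd_resid`, with a warning when `x0` falls
outside the fitted predictor range by more than 20% of the range.

**Correlations.** `pearson_matrix()` computes Pearson r between each ear
trait and each skull variable on logged values, except the cephalic index
which enters raw (it is already dimensionless). Cells with fewer than three
complete pairs are reported as undefined (`NA`), never as zero, and per-cell
sample sizes are attached.

## Acoustic predictions

* **Decibel convention.** All gains use `20·log10(ratio)`, the pressure-like
  convention: a 14-fold compliance ratio is 22.9 dB ("nearly 23 dB"), a
  6.1-fold velocity ratio is 15.7 dB.
* **Low-frequency chain.** At low frequencies middle-ear transmission is
  compliance-dominated. If cavity compliance dominates, the impedance ratio
  between two ears equals the inverse of their cavity-volume ratio; treating
  the eardrum as a piston, its linear velocity gain is the volume ratio
  divided by the membrane-area ratio. The piston assumption is carried in
  the result object as an explicit assumption flag. Whether cavity compliance
  actually dominates in dogs is an open empirical question — in cats the
  tympanic-ossicular compliance dominates instead — which is precisely why
  the package exposes the prediction rather than asserting it as truth.
* **High-frequency limit.** Across mammals the 60 dB SPL high-frequency
  hearing limit is approximately linear in the reciprocal cube root of
  combined malleus + incus mass. `calibrate_f_high()` fits
  `f_high = β0 + β1·m^(−1/3)` to user-supplied calibration pairs and
  `predict_f_high()` applies it; with `β1 > 0` the prediction falls strictly
  with ossicular mass. The full three-parameter electrical-analogue circuit
  model that has also been used for such predictions is not reimplemented
  here: its internal equations live in other work, so the package keeps the
  cube-root axis relationship with explicit user calibration instead, and a
  user wanting the circuit model can wrap it in the same
  calibrate/predict signature. Published predictions made with that richer
  model are therefore not targets this package attempts to reproduce.
* **Audiogram shifting.** `shift_lf_limit()` subtracts a predicted gain from
  an audiogram's thresholds and finds the lowest frequency at which the
  shifted curve reaches a criterion level (default 60 dB SPL), interpolating
  linearly in (log10 frequency, dB) — the space in which audiogram limbs are
  closest to straight. No audiogram data are bundled: published audiograms
  are figures, not printed tables, so audiograms are user-supplied
  two-column files.

## The synthetic-cohort generator

The generator exists so the full chain can be exercised, calibrated and
power-analysed without any raw-data download. Its defaults encode the study
conditions the package is built around: cohorts of `n = 17` breed-like
specimens whose log10 CBL spans 88.7–240 mm (the smallest and largest skulls
of the motivating comparison), with each of the seven ear traits generated
from its fitted power law (`slope`, `intercept` on log10 axes) plus Gaussian
noise on the log10 scale.

The noise level is not free: for each trait it is calibrated to the published
fit quality by inverting the R² decomposition,

```
sigma = |slope| · sd(log10 CBL) · sqrt((1 − R²)/R²),
```

using the *realized* sample SD of the drawn log10 CBL values, so the target
R² holds conditionally on the draw rather than only on average over draws.
CBL is drawn uniformly on the log10 scale by default (emulating deliberate
even coverage of a wide skull-length range); a `fixed_grid` option gives
deterministic spacing. MSW and IW are generated as fixed fractions of CBL
(0.55 and 0.45) with log-scale noise of SD 0.04 — labelled generator
conveniences so correlation analyses have material to work on, not estimates
of real skull-width scaling.

Randomness is structured: one root seed; the CBL draw, each skull width and
each trait use substream seeds derived by fixed integer offsets (modulo
2³¹−1, so any small root seed stays a valid 32-bit integer), which means
adding a trait law never perturbs the draws of the others, and replicate
seeds in `recovery_experiment()` use a distinct large stride.

What the generator deliberately does **not** emulate: residual correlation
between ear traits (noise is independent per trait — real ossicle volumes
surely co-deviate, as when one breed has all ossicles enlarged), breed
relatedness structure, and measurement-method error beyond log-normal noise.
Passing recovery tests therefore show that the fitter is calibrated for
independent log-normal deviations around power laws, not that real canid data
satisfy those assumptions.

## Recovery experiments, coverage and power

`recovery_experiment()` repeatedly generates cohorts, refits all laws and
reports per-trait mean/SD of the fitted slope, empirical 95% CI coverage and
the fraction of replicates rejecting isometry at `p < 0.001`.

Two interpretation choices are worth making explicit:

* **Coverage is assessed pooled.** With 500 replicates a single trait's
  empirical coverage has binomial SD ≈ 0.01, so per-trait coverage wanders
  outside a 93–97% band about once in twenty traits even for a perfectly
  calibrated generator-fitter pair. Pooling the 3500 intervals across the
  seven traits (SD ≈ 0.004) makes the 93–97% band an informative calibration
  check; per-trait values are still reported for inspection.
* **Power at n = 17 is limited for the cavity-volume law.** The
  noncentrality of the isometry test is `|b − expected| / se_b` with
  `se_b ≈ |b|·sqrt((1−R²)/R²)/sqrt(n−1)`, independent of the predictor
  spread. For the cavity law (slope 2.077, R² 0.879 against expected 3) this
  is ≈ 4.8 at n = 17, against a two-tailed p<0.001 critical value of
  t(15) ≈ 4.07: analytic power ≈ 0.74, and simulation agrees. The other six
  trait laws have noncentralities of 14–23 and power ≈ 1. A single observed
  dataset can of course still reject for all seven traits — a 74%-power test
  rejects more often than not — but repeated-sampling experiments should
  expect the cavity-volume rejection fraction near 0.74, not near 1. The
  package reports the fraction honestly rather than tuning the generator to
  inflate it.

## Problem sizes and numerical tolerances

The test suite uses 500 replicates at n = 17 for recovery and power, 100
replicates at n = 10⁴ for slope-bias bounds (< 0.5% of slope magnitude), and
single n = 10⁴ cohorts for realized-R² convergence (absolute tolerance 0.01)
— sizes chosen so Monte-Carlo noise is several standard errors below each
asserted bound. Exact-arithmetic identities (residual sum zero, R² = r²,
reciprocity, dB additivity) are asserted at 1e-9–1e-15. File round trips
write numerics with `%.17g` so a written cohort re-reads bit-identically.

## Limitations

* The package analyses measurement tables; it performs no CT segmentation or
  mesh processing, and curved-surface membrane areas must be supplied, not
  computed.
* Acoustic predictions are lumped-element reasoning; at high frequencies the
  eardrum breaks into complex modes and the ossicular chain stops moving as a
  rigid unit, so the cube-root predictor should be read as an empirical
  cross-mammal trend, not a mechanistic simulation.
* OLS on log-log axes is a choice; slopes from reduced-major-axis regression
  would be systematically steeper at moderate R².
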