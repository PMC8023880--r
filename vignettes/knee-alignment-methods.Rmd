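---
title: "Measuring knee alignment from standard radiographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring knee alignment from standard radiographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneealign)
```

## The problem

Knee malalignment — varus (bow-legged) or valgus (knock-kneed) deviation of
the mechanical leg axis — is a major mechanical factor in knee
osteoarthritis. The reference measurement is the hip–knee–ankle angle
(HKAA) between the femoral mechanical axis (femoral head center to femoral
notch) and the tibial mechanical axis (tibial spine base to ankle center).
It requires a standing full-limb radiograph, which many clinics and most
epidemiological cohorts do not acquire. Standard AP knee radiographs, by
contrast, are nearly universal. The femoro-tibial angle (FTA) between the
*anatomic* (shaft-based) femoral and tibial axes can be measured on a
standard knee film and used as a surrogate: this package implements an
automated FTA measurement from landmark outlines, a battery of nine
published axis-definition combinations, and a cross-validated regression
pipeline that predicts the HKAA from each FTA definition and quantifies
how well the prediction agrees with the gold standard.

Throughout, angles are expressed as deviation from a straight leg: 0° is
neutral, varus is negative, valgus positive. The alternative convention of
reporting the raw obtuse inter-axis angle (~180°) is deliberately not used;
deviation-from-straight keeps FTA and HKAA on the same scale, so the
regression slope between them is close to 1.

## Landmarks and coordinate conventions

Inputs are point lists in image coordinates (x rightward, y downward,
pixels; standard knee films carry no absolute calibration). Knee outlines
follow a named `knee_schema`: each anatomical region (femoral shaft medial
and lateral cortex polylines, condyle arc, notch apex, patella, tibial
plateau arc, spine base points, tibial shaft cortices) occupies a declared
contiguous index range. The shipped default schema has 111 points; it is a
synthetic stand-in layout of this package's own design — the proprietary
orderings of external landmark-search tools are not reproduced — and any
point count is acceptable given a matching schema file. All geometry code
addresses landmarks through region accessors only.

Left knees are mirrored on load about the vertical line through the
outline centroid, so every downstream computation sees canonical
right-knee orientation with the medial side towards +x. This fixes a
single varus/valgus sign convention for both sides; mirroring twice about
the (mirror-invariant) centroid line restores the original coordinates
exactly.

## Axis construction

Because the films are uncalibrated, the "about 10 cm from the joint line"
placement of mid-shaft measurement levels is operationalised as fixed
multiples of an internal length scale: the condyle width for the femur and
the plateau width for the tibia (Euclidean distance between the most
medial and most lateral landmarks of the respective arc). The ratios are
1.52 condyle widths proximal of the femoral notch and 1.42 plateau widths
distal of the tibial spine base. Both are exposed in `run_config()` but
default-correct. No alternative absolute-calibration path is offered: the
ratio surrogate *is* the method.

A mid-shaft point at a given level is the center of a circle touching the
medial and lateral cortices (`midshaft_point()`). The algorithm initialises
the shaft direction from the midpoints of the first and last cortical
landmark pairs, then iterates to a fixed point: place the level along the
current direction from the joint reference point (notch apex / spine base
midpoint), intersect the perpendicular with both cortical polylines
(piecewise-linear interpolation — no spline fitting, for determinism and
testability), take the circle center as the midpoint of the two
intersections and its radius as half the gap, and re-estimate the
direction from the joint reference to the center. Convergence tolerance is
1e-6 px on the center with at most 50 iterations. For straight cortices
with taper angles up to ~2.5° the resulting circle is tangent to both
polylines to better than 1e-3 of its radius (the error is 1 − cos of the
angle between cortex and cut plane), which the test suite verifies against
an exact point-to-polyline distance oracle on randomized shafts.

Two failure modes are handled explicitly rather than silently: a level
whose perpendicular does not intersect both landmarked cortices raises an
out-of-extent error, and non-convergence (possible when heavy landmark
noise makes the intersection oscillate between segments) raises an error
reporting the last residual. In the cohort pipeline such failures mark the
affected definition for the affected case as failed and the rest of the
battery proceeds.

The eight axis variants combine two point rules each: the main mid-shaft
point (all variants); a second mid-shaft point at the meta-/epiphysis
transition (Fem1/Tib1); the femoral notch center (Fem2, Tib2); the tibial
spine base midpoint (Fem3, Tib3); and the tibial plateau midpoint (Fem4,
Tib4). The transition level is not numerically defined anywhere
authoritative; it is fixed here at 0.4 of the main level (≈ 4 cm of the
10 cm surrogate, i.e. 0.608 femoral widths / 0.568 tibial widths) and
exposed as `metaphysis_fraction`. Nine femoral/tibial pairings form the
standard battery (`FTA_COMBINATIONS`), reported in a fixed canonical
order.

The signed angle between a femoral and a tibial axis orients both axes
distal-to-proximal and returns the plane angle from the femoral to the
tibial direction — zero for collinear axes, negative varus, positive
valgus. Angles beyond 45° in magnitude trigger a soft warning (implausible
anatomy) rather than an error.

## The synthetic cohort generator

The generator (`generate_leg()`, `generate_cohort()`) builds stylised 2-D
legs with exactly known ground truth. The mechanical axes realise the
requested true HKAA; the femoral anatomic axis is offset from the
mechanical one by a configurable bow angle (default 5°, the textbook
anatomic–mechanical femoral offset); shafts are straight with a 1°
cortical taper; condyles and plateau are shallow arcs whose endpoints are
the width-defining margins; spines, notch and patella are simple
primitives. The outline is sampled onto the landmark schema and perturbed
with i.i.d. Gaussian noise — knee landmarks only. The four full-limb key
points stay exact, so the gold standard has zero error by construction
(`hkaa_noise_sd` optionally relaxes this to emulate gold-standard
unreliability). All randomness flows from one explicit seed; cohorts are
bit-reproducible.

This is deliberately a geometric template, not a statistical shape model:
it reproduces exactly the relations the measurements depend on (width
scaling, axis directions, the affine FTA–HKAA link) and nothing else.
Passing tests therefore demonstrate that the *pipeline machinery* is
correct and unbiased where its model class contains the truth; they do not
certify performance on real radiographs, where shaft bowing, rotation of
the limb out of the coronal plane, osteophytes and landmark-search errors
add structure the generator does not model.

Two cohort profiles are used:

* `cohort_config()` — defaults: 50/50 sexes, true HKAA normal per sex
  (males mean −2°, females 0°, sd 3° — females skew valgus), condyle
  widths ~ N(310, 12²) px for males and N(285, 12²) for females, plateau
  width 0.93 of condyle width, landmark noise 2 px. The 2 px default
  represents automated landmark placement error alone. These population
  values are plausible stand-ins, stated once and not fitted to any
  dataset.
* `clinical_cohort_config()` — an orthopaedic-referral-like population:
  HKAA sd 5° and landmark noise 9 px. The noise was calibrated once so
  that the cross-validated MAE of the best FTA definition lands in the
  1.5–2° range; at that level the perturbation is a catch-all error budget
  standing in for everything the template omits (positioning, anatomy,
  gold-standard error), not a landmark-accuracy claim. The wider HKAA
  spread matters statistically: with a narrow (sd 3°) population, an MAE
  of 1.5–2° mathematically caps the achievable Pearson correlation at
  0.80 (MAE = 0.798·σ·√(1−ρ²)), so only a clinical-width cohort can show
  both the error and the correlation levels typical of referral
  populations.

## Prediction and validation statistics

Per definition, the HKAA is predicted from the FTA by ordinary least
squares (`fit_hkaa_model()`; fitted via `lm`). Variants: simple linear,
quadratic, and sex-adjusted (sex main effect plus FTA×sex interaction; it
refuses cases with missing sex). Evaluation uses 5-fold cross-validation:
a seeded uniform shuffle, contiguous split into folds differing by at most
one case, each fold predicted by a model fitted without it. No sex
stratification or patient-level grouping is applied by default — knees are
treated as independent — and the fold seed is a required, logged input.

Agreement between observed and predicted HKAA is summarised by:

* Pearson correlation;
* the intraclass correlation for absolute agreement, two-way model,
  single measures — ICC(A,1):
  \[(MS_R - MS_E) / (MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)),\quad k = 2,\]
  with the exact F-based confidence interval of McGraw & Wong (1996).
  Unlike Pearson's r, this coefficient penalises constant offsets, which
  is the relevant property when a predicted angle is meant to replace the
  measured one. The implementation computes the ANOVA mean squares from
  direct sums and is tested to 1e-10 against an independent `aov()`-based
  oracle;
* the mean absolute error (mean, SD, range of |observed − predicted|);
* Bland–Altman statistics with differences oriented observed − predicted:
  mean difference and limits of agreement at mean ± 1.96 SD (the standard
  construction; where a "95% confidence interval" of differences is
  reported elsewhere, these limits are what is computed and plotted here).

One design point deserves emphasis. For a *regression-calibrated*
prediction, the classical Bland–Altman check of proportional bias —
regressing the difference on the pairwise mean — is structurally biased:
for any OLS prediction, cov(obs − pred, (obs + pred)/2) =
(var(obs) − var(pred))/2, which equals half the residual variance and is
therefore strictly positive whatever the error structure. A slope test on
that abscissa rejects its null at realistic sample sizes even when the
model is perfectly calibrated. The package therefore tests proportional
bias against the *predicted* value (for which a correctly calibrated
predictor has exactly zero expected slope, residuals being orthogonal to
fitted values) and reports both slopes in `bland_altman()`; the default
plot abscissa is the predicted HKAA.

The per-definition report ranks definitions by cross-validated Pearson
correlation, ties broken by ICC, with no multiple-testing correction; all
nine are always reported, failed ones with a status string rather than
omission.

## Problem sizes and reproducibility

The validation experiments in the test suite and scripts use cohorts of
n = 100 (matching the 2·k·10 rule of thumb for 5-fold CV at these effect
sizes), 20 replicate seeds for distribution-level claims, n = 2000 for
Monte-Carlo oracles of generator moments, and 200 randomized shafts for
the tangency property. Every experiment is deterministic given its seed;
reports are byte-identical across reruns, and the run manifest records
seed, configuration, package version and input file hashes.

## Known limitations

* The landmark schema is a stand-in; real landmark sets must be mapped
  onto it (or a custom schema supplied) before the geometry applies.
* The generator cannot certify real-radiograph accuracy (see above); its
  role is structural validation of the measurement and statistics code.
* Knees with prostheses or major deformity are out of scope; the 45°
  plausibility warning is the only guard.
* Bilateral knees are treated as independent in fold assignment.
* The inscribed-circle step assumes locally near-parallel cortices; its
  tangency guarantee degrades beyond ~2.5° of taper at the measurement
  level.
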