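---
title: "Methods: GPS life-space features and within/between-person pain models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS life-space features and within/between-person pain models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Older adults with symptomatic knee osteoarthritis experience pain that
varies substantially from day to day. `lifespace` implements a pipeline
for asking whether, *within a person*, days of above-average pain are
days of contracted life-space mobility — and separately, whether people
with higher average pain move less than people with lower average pain.
The inputs are the two data streams a smartwatch platform produces:
ecological momentary assessments (EMA) of pain on the 11-point box scale
(0 = no pain … 10 = worst possible pain), prompted at random times in
three day windows (morning 8–12, afternoon 12–16, evening 16–20), and
GPS fixes captured every 15 minutes.

The pipeline has four stages: (1) daily life-space feature extraction
from fixes, (2) day-level pain aggregation, (3) panel assembly, and
(4) per-feature linear mixed models with within/between-person
disaggregation of pain. Because raw participant GPS streams are
identifying and are generally not shareable, the package also contains a
synthetic-cohort generator with known ground-truth effects; every
statistical claim the test suite makes is established by parameter
recovery and calibration on that generator.

## The ten daily features

All distances are great-circle (haversine) distances on a sphere of
radius 6371.0088 km. For one participant-day (local civil midnight to
midnight, in the participant's timezone):

* **Excursion size** (km): farthest distance from home reached that day.
* **Excursion span** (km): farthest pairwise distance among
  away-from-home fixes (those beyond the 100 m home radius); 0 with
  fewer than two away fixes.
* **Total distance** (km): sum of consecutive fix-to-fix distances.
* **Ellipse area / minor axis / major axis** (km², km, km): area and
  full diameters of the minimum-area enclosing ellipse ("ellipsoid
  hull") of the day's fixes, computed in a local planar projection.
* **Frequency of trips**: number of chronological home → away → home
  label sequences. Away runs truncated by the day boundary are not
  counted as trips.
* **Homestay** (fraction): share of fixes within the 100 m home radius;
  1 when the whole day is at home, 0 when none of it is. The radius
  comparison is inclusive ("within the home radius").
* **Number of clusters** and **entropy**: stationary fixes (speed
  < 1 km/h) are clustered by an adaptive k-means that increases k until
  every stationary fix lies within 500 m of its assigned centroid;
  entropy is `H = -sum(p_i log p_i)` over the dwell shares `p_i` of each
  cluster, 0 when the day is spent at a single place.

Speed at a fix is the backward time derivative: distance from the
previous fix over elapsed time. The first fix of a day has no backward
interval and inherits the second fix's speed; a single-fix day is
stationary.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `home_radius_m` | 100 | m | home geofence; also defines "away" for span and trips, so one home definition serves all features |
| `cluster_radius_m` | 500 | m | cluster-inclusion criterion for adaptive k-means |
| `speed_threshold_kmh` | 1 | km/h | stationary/moving cut for the time derivative |
| `entropy_base` | e | — | natural log; see "open choices" |
| `min_fixes_per_day` | 10 | fixes | days with fewer fixes are computed but flagged invalid and excluded from modelling |

## Numerical choices

**Projection.** The enclosing ellipse is a Euclidean object, so fixes
are projected to a local equidistant plane about their centroid
(meridional arc as `y`, arc along the mean-latitude parallel as `x`).
Distance distortion is below 0.5% within 100 km of the origin —
negligible at daily life-space scales and far below the GPS noise floor.
Points beyond 500 km are flagged.

**Minimum-area enclosing ellipse.** The ellipse solves the classical
dual problem: maximise `log det X(u)` over point weights on the simplex
(the D-optimal design formulation used by Khachiyan-style algorithms).
First-order ascent on this dual stalls badly on exactly the
configurations daily GPS traces produce — near-duplicate boundary
points from GPS noise at a revisited place, and nearly collinear
out-and-back days. The package therefore (a) reduces the input to its
convex hull, (b) whitens the points (the ellipse is affine-covariant),
and (c) runs an active-set Newton iteration that equalises the leverages
on the current support and exchanges support atoms until the global
optimality gap is below `1e-7` (iteration cap 10 000; non-convergence is
an error, never a silent result). The returned ellipse is rescaled so
every input point satisfies the containment inequality exactly. In 2-D
the optimal support has at most 5 atoms, so the Newton systems are tiny;
observed iteration counts are below 100. Degenerate inputs short-circuit:
one distinct point gives a zero-axis ellipse, collinear points give a
segment (semi-minor axis 0, area 0). The test suite checks the area
against `cluster::ellipsoidhull`, an independent implementation, to
within 1% on random point sets.

**Adaptive k-means.** For k = 1, 2, … the projected stationary fixes are
clustered with `stats::kmeans` (Lloyd, 300 iteration cap) using
deterministic farthest-point seeding (first the point farthest from the
centroid, then repeatedly the point farthest from the chosen set; ties
break to the lowest index). The first k for which every fix lies within
500 m — checked geodesically, not in the projection — of its assigned
centroid is accepted. k equal to the number of distinct points always
satisfies the criterion, so termination is guaranteed; empty clusters
are dropped.

**Trips at day boundaries.** A day that starts or ends away from home
contributes no trip for the truncated run; trips are strictly
within-day.

## Day-level pain

Prompt ratings are integers 0–10; day-level pain is the mean over the
answered prompts of that day (real-valued, never rounded). Days with no
answered prompt are missing and excluded from modelling; a config option
can require more than one answered prompt, but the default accepts one,
since excluding thin days is a data-quality decision the analyst should
make explicitly. Duplicate answered prompts within one day window are a
data error and are rejected with the offending records named. Day means
are dichotomised at 2 (low < 2 ≤ high) for descriptive grouping only;
the boundary value 2 is "high".

## The two-level model

For each feature, daily observations nested in participants:

```
feature_id = b0 + bw * pain_within_id + bb * pain_between_i
           + age_i + female_i + lives_alone_i + u_i + e_id
```

with `u_i` a participant random intercept and `e_id` independent
residuals (the independent covariance structure; no AIC-based structure
comparison is performed). Pain is disaggregated by person-mean centering
around the grand mean: `pain_between_i` is person i's mean pain minus
the grand mean, `pain_within_id` the day's pain minus person i's mean.
The reconstruction identity `pain = grand + between + within` and the
zero-mean property of the within component are asserted on every fit.

Estimation is REML via `lme4::lmer` (ML is available via `reml =
FALSE`; the original estimation method behind such analyses is typically
not identifiable from published tables, and REML is the conventional
default for variance components). Inference uses the normal reference:
`p = 2 pnorm(-|z|)`, CI = estimate ± 1.96 SE, matching the `P>|z|`
convention of the field's reports. No multiplicity adjustment is
applied. Singular fits (zero random-intercept variance) and
non-convergence are flagged on the returned object, never silent;
per-feature failures in the ten-feature batch are isolated and recorded.

**Grand-mean convention.** With unequal wear days per participant the
grand mean can be taken over person means (unweighted) or over pooled
observations. The default is the unweighted mean of person means, so the
between-person contrast is not dominated by participants who wore the
device longer; both options are exposed (`grand = "person"` /
`"pooled"`).

## What the synthetic cohort emulates

Defaults reproduce the study conditions the pipeline targets: 19
participants (age ~ N(73.1, 4.8) years, 68% female, 21% living alone),
wear days ~ round(N(13.16, 2.94)) floored at 1, fixes every 15 minutes,
3 prompts/day answered with probability 0.82. Latent day pain is
`clamp(round(mu_i + eps_id), 0, 10)` with `mu_i ~ N(1.40, 1.2)` between
persons and `eps_id ~ N(0, 1)` within; the grand mean 1.40 was
calibrated by simulation so that ~40% of day-mean pain values are ≥ 2,
the low-skewed mix characteristic of community knee-osteoarthritis
cohorts. Answered prompts carry the day pain plus optional rounding
jitter of ±1 point (probabilities 0.25/0.5/0.25 for −1/0/+1, clamped to
0–10).

Mobility is home-anchored: overnight and between-trip fixes sit at home
plus isotropic GPS noise (10 m per axis, typical smartwatch GNSS error
and well under the 100 m home radius). Each day's intended farthest
travel distance is

```
E_id = max(0, base_i + bb_true * (mu_i - grand) + bw_true * (p_id - mu_i) + noise_id)
```

with `base_i ~ N(20, 4.5)` km and day noise SD 2 km. The day is built as
1–3 out-and-back piecewise-linear trips on the fix grid, the farthest
reaching exactly `E_id`, each with a 2–5 fix dwell at its endpoint (so
clustering features are non-degenerate) and transit steps of ~1.3–10 km
per 15-minute fix (roughly 5–40 km/h; short errand trips may move
slower). Days with `E_id` below 0.3 km are homebound. The default true
effects are `bw_true = −3.06` km per within-person pain point and
`bb_true = −3.79` km per between-person point — effect sizes of the
magnitude reported for excursion size in smartwatch studies of knee
osteoarthritis — and are imposed on the farthest-trip distance only; the
other nine features respond geometrically. The base-mobility scale was
chosen a priori so that the linear effect model is essentially uncensored
(P(E < 0.3) ≈ 1%): a validation cohort for a linear estimator should not
embed substantial floor effects, or recovery bias would reflect the
floor, not the estimator.

**What the generator does not emulate**: prompt-time reactivity,
weekday/weekend or weather structure, within-day wear gaps, transport
modes, road networks, or any behavioural realism beyond home anchoring
and the imposed effect structure. Passing recovery tests therefore shows
that the *pipeline* is consistent and calibrated under its assumed model
— not that real cohorts satisfy those assumptions.

## Validation experiments (sizes and seeds fixed in the test suite)

* **Parameter recovery**: 50 cohorts of 100 participants × 30 days with
  `bw_true = −3.06`; the fitted within coefficient must average within
  0.5 km/point of truth with the correct sign. CI coverage is assessed
  on 200 lighter replicates (60 × 20); nominal 95% intervals must cover
  truth in 93–97% of them. These recovery runs disable prompt jitter:
  jitter is classical measurement error on the pain predictor and
  attenuates the within slope by ~14%, so an unbiasedness check against
  the latent-pain effect is only coherent with an error-free pain
  measure. (With jitter on, the same experiment recovers ≈ −2.6, a
  useful reminder that EMA measurement error biases within-person
  effects toward zero in real data too.)
* **Null calibration**: 200 default-size cohorts with both true effects
  zero; the within effect must reject at α = 0.05 in 3–8% of replicates.
* **Generator calibration**: across 50 seeds, the answered-prompt rate
  must lie within ±0.03 of 0.82 and the share of day means ≥ 2 near 40%.
* **Geometry**: on 1000 generated days, spans never exceed twice the
  excursion size, the ellipse major axis dominates the farthest pairwise
  distance, every stationary fix lies within 500 m of its centroid, and
  the extracted excursion size matches the generator's ground truth
  within 3× GPS noise.

## Known limitations

* Home locations must be supplied or estimated; the estimator (centroid
  of the modal midnight–6 AM cluster) assumes participants sleep at home.
* The entropy base is not uniquely determined by convention; natural log
  is the default and a config option. Reported entropies scale by
  `1/log(b)` under a change of base, so cross-study comparisons must fix
  the base.
* Day bucketing uses local civil midnight; trips spanning midnight are
  split and not counted as trips in either day.
* The between-person coefficient on synthetic cohorts is not recovered
  exactly when latent pain is clamped/rounded (the observed person mean
  compresses the latent spread); only the within-person effect is used
  for recovery acceptance.
* With 19-participant cohorts the z-based between-person inference is
  anti-conservative relative to a t reference; the within-person effect,
  which carries the scientific weight here, has hundreds of day-level
  degrees of freedom and is close to nominal.
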