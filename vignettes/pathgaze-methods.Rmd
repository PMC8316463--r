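---
title: "Models and methods behind pathgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pathgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgaze)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the underlying
methodology left the design open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The task and its decision geometry

A walker starts at the centre of one end of a walkway (213 cm wide,
750 cm long) and walks to a bookcase to pick a target (a cup) off a
shelf. An obstacle of width 45, 90 or 135 cm may sit across the walkway,
possibly shifted laterally, leaving an **avoidance margin** (AM) — the
passable gap between the obstacle's outer edge and the walkway edge — on
each side. The target sits at the shelf centre or ±30 cm from it.

All geometry lives in a start-centred frame: x lateral (positive right),
y forward, lengths in cm, angles in degrees. The frame itself is a
package convention — the measurements only ever involve relative angles
and distances.

Three feature families summarise the decision problem for each
condition × target cell:

* **Relative distance** `delta_d` = D_R − D_L, with D_s the Euclidean
  distance from the start centre to the obstacle's *front-face outer
  corner* on side s. The front face is used because it is what
  constrains the turn; the choice of corner is a package decision, as is
  the obstacle's longitudinal placement (default front face at 375 cm —
  "across the middle" of the walkway — configurable).
* **Deviation angles** `theta_left`/`theta_right`: the unsigned angle
  between the start→target ray and the start→corner ray on each side;
  `delta_theta` = θ_R − θ_L. Signs follow the field convention: an
  obstacle shifted right makes ΔD positive; a target shifted left makes
  Δθ positive. Note that for a *laterally shifted* obstacle Δθ is
  nonzero even with a centred target (condition 4 gives Δθ = +6.6° at
  target 0), so the "Δθ sign mirrors the target side" rule holds only
  for centred obstacles — the test suite asserts it exactly there.
* **Margins** `am_left`, `am_right` and their ratio `amr` = AM-R / AM-L.

The eight standard conditions ship as a plain-text table. Its published
margin values are carried as *overrides*: two centred rows print rounded
margins (83.5 and 61.0 where symmetric derivation from the geometry
gives 84 and 61.5; a third rendering of condition 2 as "80/80" exists in
the source material's figure labels). The package treats the published
table as canonical, derives margins from geometry only as a fallback for
custom layouts, and exposes both (`avoidance_margins(use_overrides =
FALSE)`), so the ≤1 cm discrepancy is visible rather than hidden.
NOBST (condition 1) has no obstacle: obstacle features are structurally
absent (NA) and only the deviation from straight ahead is defined.

## 2. The path-choice model

Choice is Bernoulli with logit-linear dependence on the features
(right = 1):

logit P(right) = β₀ + β₁ Δθ + β₂ ΔD + β₃ (AMR − 1) [+ interactions]

The AMR term is centred at 1 so that *neutral geometry* — symmetric
margins, centred everything — contributes nothing, which makes the
intercept interpretable: β₀ = logit(0.9) encodes the strong right-side
baseline bias (90 % right at neutral geometry) that right-handed,
right-footed walkers show.

**Generator defaults.** The distance and margin weights default to the
published univariate middle-target slopes (−0.35 per cm, +4.67 per unit
ratio). The deviation-angle weight defaults to **−0.5 per degree**, not
the published univariate −0.34: with −0.34 and the 90 % baseline the
model gives P(right) = 0.98 at Δθ = −5°, while the observed behaviour is
a *deterministic* right choice (≥ 99 %) from −5° on. No single slope
reproduces the published coefficient and the saturation point exactly;
the default favours reproducing the two probability anchors (0.90 at
neutral, ≥ 0.99 at −5°) because the generator's job is to emulate
behaviour, while every recovery test and acceptance target that claims
to generate *from the published coefficients* passes those coefficients
explicitly. Interactions default to zero: the published interaction
effects are on a standardized scale without printed raw-scale
equivalents.

Participant heterogeneity is multiplicative jitter (uniform ±10 %) on
the coefficient vector — a free choice; the source analysis reports but
does not model between-participant variability.

## 3. The gaze model

Gaze is generated as fixation *segments* (exponential durations, mean
0.4 s) rather than i.i.d. samples, so scanpaths have realistic runs.
Each segment draws an area of interest from a **five-phase categorical
model** over normalised trial time, encoding the observed structure:
early planning looks at target and margins; the margin-monitoring phase
(25–45 % of the trial) looks mostly at the margins; after passing the
obstacle gaze returns to the target; in the final 20 % path/margin gaze
falls to almost zero. Two couplings make the stream informative:

* margin-gaze probability grows with the *margin deficit* (how far the
  narrower margin falls below a comfortable 61 cm), scaled by
  `margin_attention_gain`, so narrow-margin conditions produce more
  margin gaze and hence condition-specific scanpaths;
* margin gazes land on the *to-be-chosen* side with probability
  `margin_side_bias` (default 0.8), so the avoidance-margin gaze ratio
  correlates with choice, as observed.

Samples are emitted at 120 Hz with 5 cm Gaussian jitter around the
segment anchor. For NOBST the margin mass joins the target (mostly
target gaze, few path gazes).

**AOI regions** are rectangles derived from the layout: target = bookcase
footprint + 10 cm halo; margins = the side gaps over the obstacle's
depth + 10 cm halo; path = the walkway strip excluding the margin band
and the target band. The obstacle footprint itself belongs to no AOI.
Region extents are conventions (the source defines the three AOIs but
never prints boundaries); halos are configurable.

**AMGR** = (right-margin dwell − left-margin dwell) / (their sum), in
[−1, 1]; with zero margin dwell it is undefined and returned as `NA` —
regressions refuse `NA` rows rather than silently dropping them. Dwell
is one nominal inter-sample interval (1/120 s) per sample; whether
"gaze frequency" should count samples or discrete events is unstated in
the source, so the package counts samples and records that in the
output metadata.

**Allocation maps** are Gaussian kernel density estimates (default
isotropic 15 cm bandwidth — unstated in the source, chosen at the scale
of the AOI structures) over in-AOI gaze points, weighted by dwell,
normalised by trial duration, then affinely rescaled to [0, 10] for
display. The unscaled surface is kept alongside because the rescaling
destroys comparability across trials.

## 4. Scanpaths: encoding, similarity, consensus

Each trial is normalised to its duration and cut into **exactly 100
bins**; each bin takes the majority in-AOI label (margins merged into
S), with ties broken by dwell and then the fixed order T > S > P. Bins
with no in-AOI gaze become gap symbols (`-`); a "carry last label" mode
exists as an alternative. Numeric view: T→2, P→5, S→10. Group matrices:
A (symbols), B (numeric), C (per-segment means, gaps excluded — whether
out-of-AOI frames belonged in the average was unstated; excluding them
means C reflects only labelled gaze).

**Similarity** is Needleman–Wunsch global alignment, the ScanMatch
approach with the 3-letter AOI alphabet. The default scoring is identity
(match 1, mismatch 0, inserted-gap score 0) because no substitution
matrix is published; a graded matrix (1 − |numeric difference|/8, so T–P
scores above T–S) is available. Scores are normalised to [0, 1] by the
self-alignment score of the sequence with more scoreable symbols, making
self-similarity exactly 1 and the score symmetric; raw scores are
exported alongside since it cannot be determined which scale the
original similarity tables used. The alignment core is compiled (Rcpp);
its correctness is pinned to a brute-force recursive oracle, exactly, on
1000 random short pairs.

**Characteristic sequences** use DTW barycenter averaging: initialise at
the medoid, repeatedly align all sequences to the barycenter by dynamic
time warping (squared local cost) and replace each coordinate by the
mean of its aligned values, until the summed DTW cost stops improving
(tolerance 1e-6) or 30 iterations. The objective trace is returned and
asserted non-increasing on every run. Gap bins are filled from the
nearest labelled bin before averaging so the barycenter keeps length 100
and values stay within [2, 10].

## 5. Inference

* **Univariate fits**: ML logistic regression with Wald p-values;
  complete separation is detected and flagged rather than silently
  reported as a huge finite slope.
* **Multivariate fit**: features standardized over the design, LASSO
  (glmnet, penalty by internal CV by default) for selection, then an
  unpenalised ML refit on the selected set so reported effects are free
  of shrinkage bias. In this design AMR is heavily collinear with ΔD
  (both derive from the lateral obstacle offset), so the LASSO
  legitimately drops one of them at small n — a property of the stated
  world, not a bug.
* **Surrogate bootstrap**: the phrase "bootstrapping with random
  shuffling of 2000 surrogate data" admits two readings, so both are
  implemented and reported separately: label-shuffle surrogates give a
  permutation-style null and p = fraction of |surrogate effect| ≥
  |observed| (which can be exactly 0); case-resampling gives percentile
  95 % CIs. Both are seeded.
* **Effect partition**: share_i = |standardized effect_i| / Σ|effect_j|
  × 100 over the three main effects, interactions excluded. This formula
  is a *reconstruction* — the original "ratio to total effect" /
  "variance accounted for" computation is never printed, and the source
  itself reports two slightly different share sets (26/39/35 vs
  26.2/37.7/36.1). The reconstruction guarantees shares are nonnegative,
  sum to 100, and are invariant to raw feature units (standardization
  absorbs rescaling — property-tested).
* **LOOCV**: hold out one unit (trial by default; participant blocks
  optional — the original unit is unstated), refit, predict at 0.5;
  a predicted probability of exactly 0.5 counts as incorrect
  (conservative). Accuracy reported as mean ± SD over folds.
* **Judgment threshold**: mean ratings / 10 are treated as P(right) and
  fitted with a 2-parameter logistic by least squares (Nelder–Mead,
  initialised at the empirical 50 % bracket); the threshold is the
  fitted crossing. No crossing inside the offset range ⇒ the result is
  flagged extrapolated. Monotonicity violations of the empirical curve
  are counted and reported, not "fixed".

## 6. What the synthetic world does and does not establish

The generator emulates: the 8 × 3 × 3 repeated-measures design; logistic
choices with the documented coefficient structure and right-side
baseline; phase-structured, condition-specific, choice-coupled gaze;
gait that slows in proportion to margin deficit (conditions with 39 cm
margins are slower to the obstacle than those with 83.5 cm); bounded-
noise judgment ratings crossing at −15 cm (slope 0.3 logit/cm, rating
noise SD 0.5).

It does **not** emulate: biomechanical gait (no swing phases — gait
speed uses first-to-last-sample elapsed time, with the to-margin segment
ending at the obstacle's longitudinal midline); 3-D gaze or head pose
(ground-plane points are generated directly; a ray–ground helper covers
(origin, direction) input); fixation/saccade event structure beyond
exponential segments; and any real-data idiosyncrasies (drop-outs,
tracker noise spectra, learning across trials). Consequently a green
test establishes *estimator correctness and pipeline integrity* —
recovery of generating parameters, exact analytic cases, oracle
equivalence — not reproduction of the original study's empirical
values (its headline LOOCV accuracy, similarity tables and ANOVAs were
computed on unreleased raw data).

Two statistical acceptance checks are run at reduced but honest scale:
the surrogate-null uniformity check uses 40 repeats × 500 surrogates
(the nominal "KS distance < 0.05 over 50 repeats" is unattainable as
written — a 50-sample empirical CDF sits at KS ≈ 0.12 from uniform in
expectation — so the check is a KS goodness-of-fit test that must not
reject uniformity), and the strong-effect permutation bound is asserted
at n = 2000 with 300 surrogates. The within- vs between-condition
scanpath similarity property runs at its stated 50 trials/condition.

## 7. Known limitations

* AOI rectangles approximate what were presumably hand-scored regions.
* The identity scoring scheme makes the NW similarity of long sequences
  dominated by shared phase structure; the graded scheme softens, but
  cannot remove, the arbitrariness of the 2/5/10 coding.
* DBA on categorical-coded sequences averages codes, so barycenter
  values between 2 and 10 have no single-AOI interpretation — they are
  consensus intensities, exactly as in the source's Matrix C.
* The effect-partition formula is a reconstruction (see §5) and shares
  should be compared across fits, not read as variance decompositions.
* With 12 participants × 72 trials the LASSO's selection is unstable
  under the design collinearity; the unpenalised refit quantifies only
  the selected set.
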