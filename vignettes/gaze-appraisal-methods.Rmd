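---
title: "From raw gaze samples to appraised comprehensibility and interest: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw gaze samples to appraised comprehensibility and interest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazeappraisal turns raw 60 Hz binocular gaze recordings of people reading
news articles into per-session eye-behavior features, and relates those
features to subjective appraisals of how *comprehensible* and how
*interesting* each article was. This vignette explains the processing
model stage by stage, the tunable parameters and why their defaults are
what they are, what the bundled synthetic-data generator does and does
not emulate, and the numerical conventions that make the pipeline
reproducible.

## The processing model

The pipeline is a fixed chain. Each stage consumes the previous stage's
output and only ever *removes* information, so per-stage event counts
form an audit trail (recorded in the run manifest):

1. **Fixation detection (I-DT).** A fixation is a maximal run of
   consecutive samples whose bounding-box dispersion — the x-range plus
   the y-range of the binocular mean position — stays within a threshold
   (default 1.0 degree of visual angle), and whose temporal span is at
   least 80 ms. Runs grow greedily left to right; a sample that cannot
   seed a qualifying run is skipped. Blink samples, which the tracker
   encodes as position (0, 0), never join a fixation, and gaps longer
   than two nominal sample intervals break runs.
2. **Saccade derivation.** Each adjacent fixation pair defines one
   saccade spanning from the first fixation's offset to the second's
   onset. Displacement is taken between fixation centroids with screen
   coordinates (origin top-left, y growing downward). A saccade whose
   interval contains any blink sample is flagged and excluded from all
   feature sets. Kinematics: amplitude in pixels and degrees (see
   geometry below), and peak speed as the maximum angular
   sample-to-sample speed inside the interval.
3. **Regression classification.** A non-blink saccade is a regression
   when its displacement moves at least 20 px upward
   (`dy <= -20`) *or* at least 20 px against reading direction
   (`dx <= -20`). Twenty pixels is roughly the width of a short word, so
   progressive saccades and corrective microsaccades are excluded.
4. **Coefficient K.** For each fixation *i* followed by a retained
   saccade, `K_i = (d_i - mu_d)/sigma_d - (a_{i+1} - mu_a)/sigma_a`,
   where `d_i` is the fixation duration, `a_{i+1}` the following
   saccade's amplitude, and the four baselines are the participant's
   mean and standard deviation over their whole pool of such pairs.
   Positive K marks focal processing (long fixations, short saccades),
   negative K ambient scanning. Because the baselines come from the same
   pool, each participant's pooled K mean is zero by construction — a
   property the tests verify to 1e-9.
5. **Lenient IQR outlier removal.** For each event feature pool
   (fixation duration; saccade amplitude, duration, peak speed;
   regression versions of the same; pupil; K) values outside
   `[Q2 - 4*IQR, Q3 + 4*IQR]` are removed. The anchors are deliberately
   asymmetric (median below, third quartile above) and the 4x multiplier
   deliberately lenient, so heavily skewed oculomotor distributions
   survive intact. Regressions are filtered against their own pools, not
   the overall saccade pools: a line-return sweep is an extreme saccade
   but an ordinary regression.
6. **AOI filtering.** Fixations whose centroid lies outside both the
   article-title and the content rectangle are dropped (rectangles are
   half-open: a point exactly on the max edge is outside); saccades and
   regressions survive only if both bounding fixations survive.
7. **Session aggregation.** Per reading session: reading time (first
   fixation onset to last fixation offset, in seconds), event counts,
   and for each feature series the moments mean, variance, skewness
   (g1) and excess kurtosis (g2). Pupil size is the binocular mean
   diameter per fixation; its raw *level* is excluded because absolute
   pupil size is a personal trait, while its variance, skewness and
   kurtosis are kept.
8. **Baseline normalization.** Every non-count feature is additionally
   emitted re-centered on the participant's median over the whole
   experiment (`_a` suffix) and over the participant-block (`_b`), to
   strip stable inter- and intra-individual level differences. K is
   already standardized per participant, but its re-centered variants
   are still emitted so that the modeling stage sees the full variable
   family; the feature manifest is the authoritative enumeration
   (113 columns).
9. **Screening.** Sessions with any missing feature are dropped;
   near-zero-variance columns are flagged (frequency ratio >= 95/5 and
   unique fraction < 10%) but kept by default; of each column pair with
   |r| > .95 the member with the larger mean absolute correlation
   against the remaining columns is removed, greedily, worst pair
   first, with name-sorted tie-breaking over canonically sorted columns
   — so the result is order-independent and deterministic.
10. **Modeling.** Per appraisal, a linear model on all screened features
    is reduced by bidirectional stepwise search minimizing AIC
    (`MASS::stepAIC` from the full model). The other appraisal and all
    questionnaire items are barred from the predictor set. The selected
    set is then evaluated by leave-one-out cross-validation: every
    observation is predicted from a refit on the other N - 1 (computed
    via the PRESS identity, which is algebraically identical for OLS;
    an explicit refit loop in the tests confirms the equality).
    Performance is summarized as Pearson's r and nRMSE — RMSE divided
    by the observed response range. Predictions are not clipped to the
    1–7 scale: out-of-range predicted density is informative in the
    report plots.

## Geometry and units

Degree-scaled features need physical geometry: a 22-inch 5:4 panel at
1280 x 1024 gives a defaulted 433.6 x 346.9 mm active area, and the
default viewing distance is 650 mm, typical for a remote desk-mounted
tracker. A displacement of `s` pixels subtends
`2*atan(s*pitch / (2*distance))`. The viewing distance is not something
a gaze export records, so it is configurable; it affects degree-scaled
features monotonically and nothing else. Whether dispersion is
thresholded in pixels or degrees is likewise a convention: the package
states it in degrees (default 1.0) and converts through the geometry.

## The questionnaire model

Each appraisal is a three-item 7-point scale. Reverse-coded items (the
boring–exciting differential runs against the interest construct) are
flipped (`x -> 8 - x`) before averaging. Reliability is Cronbach's
alpha, `k/(k-1) * (1 - sum(var_items)/var(sum))`; for items with common
pairwise correlation rho the population value is
`k*rho / (1 + (k-1)*rho)`, which is how the package's alpha-recovery
checks derive their expected values (rho = 0.7356 implies alpha = .893,
rho = 0.7953 implies alpha = .921 for k = 3).

## What the synthetic generator emulates

No raw data are deposited with reading studies of this kind, so the
package ships a generator whose defaults *are* the emulated study
conditions: 30 participants x 18 articles in three counterbalanced
blocks (540 questionnaire records); exactly one participant's gaze
recording lost to a software failure (522 recorded sessions); and five
sessions whose pupil channel failed outright (recorded as NA), which is
the generator's defect model for missing feature values — those five
rows fall at screening, leaving 517. Latent comprehensibility and
interest are standardized bivariate normal per session with correlation
0.466 (about 21.7% shared variance). Questionnaire items load sqrt(rho)
on the latent and are discretized to 1–7.

Scanpaths are word-by-word: lognormal fixation durations (baseline
340 ms), per-word skipping (baseline probability 0.25), refixations
(0.12), Bernoulli backward regressions (0.08) jumping 2–9 words back,
within-line progressive saccades and line-return sweeps, rendered to
60 Hz samples with positional jitter, binocular disparity, a pupil
signal (personal baseline + slow drift + white noise), and Poisson
blinks (6/min, uniform 100–400 ms) written as (0, 0) runs. The latents
act only through session-level multipliers — shorter fixations (hence
shorter reading time), more skipping (hence longer saccades), damped
pupil variability and fewer regressions for higher appraisals, with
comprehensibility weighted roughly twice interest so that
comprehensibility models cross-validate better, mirroring the
asymmetry the analysis is meant to expose. All effect signs sit in
`effect_directions` and can be zeroed for null studies.

Deliberately *not* emulated: word-level lexical effects (frequency,
predictability, spill-over), article text itself, any participant- or
article-level variance decomposition of the latents (the generator is
purely session-level — the emulated design gives no basis for choosing
a split), smooth pursuit, calibration drift, and monocular loss.
Passing tests therefore show the pipeline is correct and calibrated on
data with this structure; they cannot show that real readers satisfy
the generator's assumptions.

## Numerical conventions and degenerate inputs

* Quantiles are linear-interpolation (type 7) everywhere; the IQR
  filter depends on this, so it is part of the contract.
* Moments use the g1/g2 conventions (no small-sample bias correction);
  variance uses n - 1. Slots below their minimum sample size (2 for
  variance, 3 for skewness, 4 for kurtosis) or with zero spread are NA.
* Fewer than four finite values pass the IQR filter untouched; an
  all-equal pool collapses the bounds to the common value and keeps
  everything.
* A participant whose K-pair pool has zero variance is excluded from K
  features with a warning.
* Sessions with no retained fixations produce all-NA feature rows
  rather than disappearing; screening removes them visibly.
* LOOCV folds with leverage 1 (a refit would be singular) are flagged
  and dropped from the error summaries.
* Ties in the correlation de-duplication are broken by column name
  after canonical sorting, making screening independent of input
  column order.

## Choices made where the design was open

* **Dispersion threshold.** Only the algorithm family and the 80 ms
  minimum are fixed by the processing contract; 1.0 degree is standard
  I-DT practice and is exposed in the configuration.
* **Regression rule.** "Upward and horizontal, minimum 20 px" is read
  as an OR of the two backward components: it captures same-line
  leftward regressions and upward inter-line regressions. Line-return
  sweeps (large leftward dx with downward dy) are *not* exempted — the
  literal rule counts them — and the tests therefore discount downward
  sweeps when checking that a zero-regression generator produces almost
  no other backward saccades.
* **K baseline scope.** The participant baselines for K come from the
  participant's post-filter pair pool across all sessions, matching the
  whole-experiment philosophy of the `_a` normalization.
* **Reading time** spans first-fixation onset to last-fixation offset
  (the offset convention makes a single 300 ms fixation read 0.3 s).
* **Stepwise search** runs bidirectionally from the full model under
  AIC — the conventional behavior of the standard stepwise routine.
  Novelty/complexity items are never offered to the search.
* **nRMSE denominator** is the range of the *actual* responses, the
  usual reading of min–max normalization; recorded in the model output.

## Validation design and a known limitation

The test suite validates every operation against independent oracles:
an O(n^2) brute-force dispersion grouper for fixation detection, a
longhand type-7 quantile filter, explicit refit loops for LOOCV, an
exhaustive minimal-subset search for correlation de-duplication, and
closed forms for alpha and K. Full-scale checks run the entire pipeline
at the emulated design size (522 sessions); sign recovery is checked
over five seeds, null calibration over three, and the
comprehensibility-over-interest cross-validation ordering over the same
five — sizes chosen to keep a complete run of the suite within a few
minutes while still exercising the full design.

One calibration property fails by design rather than by accident: under
a *null* generator (all effect directions zero) the cross-validated r
of the stepwise-selected models does not scatter around zero but sits
near +0.09 to +0.18. This is post-selection optimism: the predictor set
is selected on the full sample — including each observation later held
out — so leave-one-out refits inherit the selection's sample-specific
correlations. With ~60 screened candidate features at n = 517 the
stepwise search retains a dozen or more noise predictors, enough for a
visibly positive null r. The protocol (selection once, then LOOCV over
coefficients only) is exactly the one this package implements on
purpose, so the corresponding null expectation in the acceptance tests
is left failing with this explanation rather than silently weakened.
The practical reading: cross-validated r values produced by this
protocol carry an optimism of roughly +0.1 to +0.15 at this
feature-to-observation ratio, and differences *between* models (the
comprehensibility-versus-interest ordering) are more trustworthy than
absolute levels. Running selection inside every fold would remove the
bias at the price of no longer evaluating a single fixed model.

## Known limitations

* The generator's effect sizes are plausible but invented; only their
  signs and the comprehensibility-over-interest asymmetry are
  structural claims.
* Event detection is I-DT only; velocity-threshold detection, smooth
  pursuit and monocular analysis are out of scope.
* The feature manifest's 113 columns enumerate the implemented variable
  families exhaustively; other dialects of the same families (e.g.
  normalized counts) would change the count and are intentionally not
  emitted.
* Screening removes many more correlated columns on synthetic data
  (~50) than a human dataset would show, because raw and re-centered
  variants of the same feature are nearly collinear when personal
  baselines are weak; the greedy rule handles this deterministically.
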