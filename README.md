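# gazeappraisal

Reading is the one behavior where the eyes betray the mind most
directly: readers who find a text easy to follow, or worth their
attention, fixate, skip, and re-read differently from readers who are
lost or bored. **gazeappraisal** is an R package for analysts of
reading studies who want to go from a raw 60 Hz binocular gaze export
to an answer to the question: *how much of a reader's subjectively
rated comprehensibility and interest can eye behavior explain and
predict?*

The package implements the full chain as tested, composable stages:

* **Event detection** — dispersion-based (I-DT) fixation detection
  (bounding-box dispersion within 1.0°, minimum span 80 ms), saccades
  as the connection between adjacent fixations, blink exclusion via the
  tracker's (0, 0) convention, and regressions as backward saccades of
  at least 20 px against reading direction or upward.
* **Coefficient K** — the focal/ambient attention metric: per
  fixation–saccade pair, the participant-standardized fixation duration
  minus the participant-standardized amplitude of the following
  saccade, `K_i = (d_i − μ_d)/σ_d − (a_{i+1} − μ_a)/σ_a`.
* **Session features** — reading time, counts, and mean / variance /
  skewness (g1) / excess kurtosis (g2) per feature family, after a
  lenient pool-wide outlier filter (`[Q2 − 4·IQR, Q3 + 4·IQR]`) and
  area-of-interest filtering, each feature also re-centered on the
  participant median (`_a`) and the participant-block median (`_b`).
* **Screening** — missing-value rows out, near-zero-variance columns
  flagged, correlated columns (|r| > .95) greedily de-duplicated.
* **Models** — per appraisal, a stepwise (bidirectional AIC) linear
  model over the screened features, evaluated by leave-one-out
  cross-validation (Pearson r and min–max normalized RMSE), plus the
  feature–appraisal correlation table and a predicted-vs-actual report
  with loess trend, 95% prediction band and density margins.
* **Synthetic study generator** — because raw gaze data of this kind
  are rarely deposited, the package ships a word-by-word reading
  scanpath simulator that emulates a 30-participant × 18-article
  within-subjects study (540 questionnaire records, 522 recorded gaze
  sessions, 517 screened rows), with latent appraisals sharing ~21.7%
  variance and effect directions matching the published correlational
  structure. Every downstream stage is testable end to end without any
  download.

## Worked example

Simulate a mid-sized study and run the whole pipeline:

```r
library(gazeappraisal)

cfg <- gaze_config(n_participants = 15, n_articles = 12, n_blocks = 3,
                   rng_seed = 42)
res <- run_pipeline(cfg)

res$manifest$counts$events
#>      stage fixations saccades regressions k_samples
#> 1 detected     35662    33967        6383        NA
#> 2      iqr     35533    30197        6383     29982
#> 3      aoi     35533    29982        6332     29948

round(res$scores$alpha, 3)
#> comprehensibility          interest
#>             0.867             0.895

res$models$comprehensibility
#> Stepwise linear model for comprehensibility
#>   31 predictors selected from the screened feature set (n = 175)
#>   R^2 = 72.28%, F(31, 143) = 12.03, p = 1.41e-26

res$cv$comprehensibility
#> Leave-one-out CV for comprehensibility (n = 175)
#>   nRMSE = 0.135, Pearson r = 0.769

res$cv$interest
#> Leave-one-out CV for interest (n = 175)
#>   nRMSE = 0.182, Pearson r = 0.662

correlation_table(res$screening$table,
                  features = c("reading_time", "pupil_var"))
#>        feature         appraisal     r      p stars
#> 1 reading_time comprehensibility -0.24 0.0017    **
#> 2    pupil_var comprehensibility -0.21 0.0059    **
#> 3 reading_time          interest -0.16 0.0371     *
#> 4    pupil_var          interest -0.24 0.0015    **
```

Reading the output: the event ledger shows each filter stage only ever
shrinks the event pools; the questionnaire scales are internally
consistent (alpha near .9); the stepwise model explains 72% of
comprehensibility variance in-sample and predicts held-out sessions at
r = .77, better than interest (r = .66) — the asymmetry the generator
encodes; and reading time and pupil variance correlate negatively with
both appraisals: easier and more engaging articles are read faster and
with steadier pupils. `plot(res$cv$comprehensibility)` draws the
predicted-vs-actual scatter with trend, prediction band and density
margins. `chance_level(7)` (14.29%) is the uniform-guessing baseline
for a 7-point scale.

At the full emulated design size (`gaze_config()` defaults, ~20 s) the
same call reproduces the 540 / 522 / 517 record–session–row arithmetic.

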