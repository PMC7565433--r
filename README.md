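# iowattn

Attentional phenotyping from infant cued-attention eye tracking.

Infant spatial-cueing tasks (the IOWA task: valid / invalid / double / tone /
no-cue conditions, targets 11° left or right of fixation) measure orienting
speed, spatial attention and saccade inhibition from raw gaze. `iowattn`
implements the full analysis chain for such studies:

- **I-VT event detection** — 300 Hz binocular gaze → fixations and saccades
  (cyclopean averaging, ≤75 ms gap interpolation, 3-sample smoothing, 20 ms
  symmetric velocity window, 30 deg/s threshold, fixation merging, 60 ms
  minimum fixation).
- **Trial scoring** — central-fixation gating, first-fixation response
  coding in 15°×15° target areas, the 100 ms anticipatory cutoff, saccadic
  reaction time (SRT) to saccade onset, and six per-infant attention scores,
  normalized by the tone-condition baseline B:

  facilitation = (B − valid)/B, interference = (invalid − B)/B,
  competition = (double − valid)/B, mean SRT (all correct trials),
  task error = 1 − mean(double, invalid accuracy),
  baseline error = 1 − mean(valid, tone, no-cue accuracy).

- **Latent profile analysis** — diagonal-covariance Gaussian mixtures fit by
  EM on the observed-data likelihood (missing scores handled without
  imputation), with AIC/BIC, relative entropy, posterior classification, a
  model-selection table over K, and a parametric-bootstrap LRT.
- **Growth models** — random-intercept linear models per score (age coded
  0/1/2 for the 5/8/11-month visits, low-reactive reference), full ML via a
  profiled likelihood, and the m1 (time-only) vs m2 (time × profile)
  comparison: LR = 2(ℓ₂ − ℓ₁) against χ²₄.
- **Visual STM measures** — total looking and switch count over a 3000 ms
  change-detection test array, with Kruskal–Wallis (+ mean ranks),
  percentile-bootstrap Welch t, and 2×4 repeated-measures ANOVA with
  partial η² and simple effects.
- **Synthetic-data generator** — score cohorts, full IOWA gaze sessions
  (exactly invertible score encoding, truncated-normal latencies, noise and
  dropout) and STM sessions (Markov dwell/switch fixation chains with a
  capacity-limited change-detection knob), so the whole pipeline is testable
  without infant data.

See `vignettes/attentional-phenotyping.Rmd` for the models, assumptions,
parameter choices and limitations.

## Worked example

Simulate one infant's session from a known score vector, detect events,
score trials, and recover the scores:

```r
library(iowattn)
theta <- data.frame(facilitation = 0.356, interference = 0.068,
                    competition = 0.135, baseline_error = 0.065,
                    task_error = 0.411, mean_srt = 283.787)
sess     <- simulate_iowa_session(theta, iowa_trial_schedule(10, seed = 1), seed = 1)
events   <- detect_events(sess$stream)
outcomes <- score_iowa_session(events, sess$trial_log)
round(attention_scores(outcomes)[, 1:7], 3)
#>   facilitation interference competition mean_srt task_error baseline_error baseline_srt_ms
#> 1        0.373        0.119       0.138  280.549      0.325              0             297
```

One 100-trial session recovers the generating scores to within sampling
noise (facilitation 0.373 vs 0.356; mean SRT 280.5 ms vs 283.8 ms); across
a cohort the recovery is unbiased (see the test suite).

Phenotype discovery on a simulated 111-infant cohort:

```r
coh <- simulate_score_cohort(111, ages_mo = 11, seed = 4)
six <- c("facilitation", "interference", "competition",
         "baseline_error", "task_error", "mean_srt")
fit <- fit_mixture(coh[, six], K = 3, n_starts = 32, seed = 104)
fit
#> Latent profile model: K = 3, n = 111, logLik = -433.539
#> AIC = 943.08  BIC = 1046.04  entropy = 0.929  converged = TRUE
#> profile shares (%): 11.7 / 41.4 / 46.8
adjusted_rand_index(fit$assignment, coh$phenotype)
#> [1] 0.92
```

The three-profile fit assigns 92% of infants (chance-corrected) to their
generating phenotype; the shares track the realized draw of the
0.55 / 0.396 / 0.054 mixing weights. Growth-trajectory comparison on a
simulated longitudinal panel:

```r
d <- simulate_growth_dataset(111, "mean_srt", seed = 3)
compare_models(d)
#> m1 vs m2: L.Ratio = 67.46, df = 4, p < 0.001
```

i.e. age-by-phenotype structure explains developmental change in mean SRT
far beyond a time-only model, mirroring the analysis the package
implements.

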