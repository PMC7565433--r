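---
title: "Attentional phenotyping from infant cued-attention eye tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iowattn)
```

## The scientific problem

Infant visual orienting can be probed with a spatial-cueing task: on each
trial the infant fixates a central attention-getter, a brief peripheral
pre-cue appears (100 ms), and after a 100 ms blank a target appears 11
degrees left or right of fixation for 1000 ms. Five cue conditions — valid
(cue at the target location), invalid (cue opposite), double (cues on both
sides), tone (auditory cue only) and no-cue — dissociate spatial attention,
orienting speed and saccade inhibition. From the saccadic reaction times
(SRT) and accuracies, six per-infant scores are derived; a latent profile
analysis over those scores identifies *attentional phenotypes* (high
flexible, low reactive, high reactive), and random-intercept growth models
test whether phenotype membership predicts distinct developmental
trajectories from 5 to 11 months. A companion visual short-term-memory
(change detection) task supplies looking-based measures — total looking and
switch count over a 3000 ms test array — to test whether the phenotypes
generalize beyond cued orienting.

`iowattn` implements that entire analysis chain, plus a synthetic-data
generator so every stage can be exercised and validated without infant
data.

## Event detection (I-VT)

Raw 300 Hz binocular gaze is reduced with a velocity-threshold filter:

1. the valid eyes are averaged into a cyclopean trace (one eye suffices);
2. invalid runs of at most 75 ms are linearly interpolated between their
   flanking valid samples; longer runs stay gaps;
3. a centered 3-sample moving average smooths each valid span (the window
   truncates at span edges, so constants are preserved exactly);
4. angular speed at sample *t* is the displacement between the samples 10 ms
   before and after *t*, divided by their time difference (symmetric 20 ms
   window — an asymmetric trailing window would bias onset latencies late);
5. samples at or above 30 deg/s form saccade runs, the rest fixation runs;
   adjacent fixations separated by less than 75 ms and less than 0.5 deg
   (centroid distance) are merged; fixations shorter than 60 ms are
   discarded.

All parameters sit in `detection_config()`. Two deliberate choices:

* **Merge angle 0.5 deg.** Published parameter listings for this filter
  sometimes print "\<5 deg" for the merge angle, but 5 deg would merge
  fixations across distinct interest areas (targets sit at 11 deg, circles
  at 8 deg); 0.5 deg is the conventional value for this filter and is the
  default here, with any other value selectable.
* **Interpolate before smoothing.** The order is not fixed by convention;
  interpolation first means the smoother never bridges a gap it should not.

**Onset anticipation.** A symmetric velocity window flags the first sample
whose ±10 ms span already contains enough saccade displacement, so detected
saccade onsets *precede* the kinematic onset — by up to half the window plus
one sample of grid quantization (≈13 ms worst case; 3–6 ms for the
generator's 30 ms half-cosine ramps) — and can never be late by more than
one sample. This matters downstream: the baseline-normalized attention
scores cancel the anticipation (both numerator and denominator shift), while
the absolute mean SRT inherits it as a small early bias. The test suite
asserts exactly this asymmetric band rather than a symmetric one-sample
tolerance.

## Trial scoring and the six attention scores

A trial is included only if a fixation containing target onset lies in a
central area (half-width 3.5 deg by default — wide enough to absorb
calibration error, clear of the 11 deg targets; the configuration validator
rejects geometries in which central and target areas overlap). The response
is the first fixation starting within 1000 ms of target onset whose centroid
falls in either 15×15 deg target area; it is correct iff on the cued side.
SRT is measured from target onset to the onset of the saccade that precedes
the response fixation (the standard saccadic-latency convention; a
fixation-arrival anchor is available via `scoring_config(srt_anchor =
"fixation")`). Responses faster than 100 ms are discarded as anticipatory.
Trials with no target-area fixation in the window count as incorrect
non-responses.

With per-condition mean SRTs over correct trials and baseline B = tone-cue
mean SRT, the six scores are

* facilitation = (B − valid)/B
* interference = (invalid − B)/B
* competition = (double − valid)/B
* mean SRT = mean over *all* correct trials pooled (robust to unequal
  condition counts; a per-condition-then-average variant is available)
* task error = 1 − mean(double accuracy, invalid accuracy)
* baseline error = 1 − mean(valid, tone, no-cue accuracy)

Scores whose ingredients are empty are missing, never zero. In particular,
interference is missing when an infant has no *correct* invalid trials —
the operational reading of "made no errors, hence no interference score"
that is consistent with the formula — and missing interference propagates
into the mixture stage rather than being imputed. Cohort-level screening
uses Tukey fences (quartiles by linear interpolation, 1.5 IQR) to flag, but
never remove, outlying scores.

## Latent profile analysis

Profiles are mixtures of K diagonal-covariance Gaussians over the six
scores, fit by EM on the observed-data likelihood: a row with a missing
score contributes the product of univariate normal densities over its
observed columns only, and the M-step weights each coordinate's sufficient
statistics by the responsibilities of the rows observing that coordinate.
This is the standard maximum-likelihood treatment of ignorable missingness
and needs no imputation.

Diagonal, class-varying covariances are the default latent-profile
parameterization, giving 2·K·d + (K − 1) parameters; AIC = 2p − 2ℓ and
BIC = p·ln n − 2ℓ. Classification crispness is summarized by relative
entropy, E = 1 − Σᵢₖ(−pᵢₖ ln pᵢₖ)/(n ln K), which is 1 for one-hot
posteriors and 0 for uniform ones (undefined at K = 1).

Numerical choices: 32 k-means++-seeded random starts (seeding distances on
the standardized complete columns), relative log-likelihood tolerance 1e-8,
iteration cap 1000, and a variance floor of 1e-4 times the pooled column
variance. The floor is a mild, documented deviation from unconstrained
maximum likelihood that prevents single-row variance spikes, to which
likelihood-maximizing mixtures are otherwise prone. The EM trace is stored
and the suite asserts monotone likelihood on every fit; exact posterior ties
in hard assignment break toward the lower component index (a measure-zero
event). Likelihood-ratio testing between K − 1 and K profiles is provided
as a parametric-bootstrap LRT (`bootstrap_lrt()`), a standard construction;
the ad-hoc analytic approximation some commercial LPA software reports is
deliberately not reproduced.

## Growth models

Developmental change is modelled per score with random-intercept linear
models: visits coded 0/1/2 (5/8/11 months), low reactive as reference
profile — a coding recovered from the structure of the published fits, where
the constant matches the low-reactive 5-month mean and the age-by-high-
flexible slope matches the high-flexible mean-SRT trajectory. Model m1 has
age only (df = 4); m2 adds profile main effects and age-by-profile
interactions (df = 8; df counts fixed effects plus two variance components).

Estimation is full ML, not REML, because the m1-vs-m2 comparison differs in
fixed effects (REML likelihoods would not be comparable) and because the
published information criteria reproduce exactly under ML with df = #fixed
+ 2. The likelihood is profiled over θ = σ²_b/σ²_e: at each θ the GLS fixed
effects and σ²_e are closed-form, leaving a smooth one-dimensional criterion
in log θ optimized deterministically (bounded search, tolerance 1e-10, with
the θ = 0 boundary checked explicitly). Subjects with missing visits
contribute their observed rows' marginal likelihood, so unbalanced panels
are handled naturally. `compare_models()` reports LR = 2(ℓ₂ − ℓ₁) against
χ²₄, and also accepts two log-likelihoods directly so published fits can be
compared arithmetically.

## STM measures and tests

Test-interval fixations are assigned to the nearest occupied circle center
within a 3.5 deg capture radius (2.5 deg circle radius plus 1 deg
calibration slack; not a published value). Total looking sums assigned
fixation durations clipped to the 3000 ms window — fixations begun before
test onset contribute only their in-window part, a deliberate resolution of
an unspecified boundary case. Switch count tallies consecutive assigned
fixations on *different* circles; off-area fixations neither count as
switches nor terminate a run (A → center → B is one switch), a choice the
verbal definition of switching leaves open.

Group tests mirror the field's standard toolkit: tie-corrected
Kruskal–Wallis with per-group mean ranks; Welch t with percentile-bootstrap
confidence intervals and p-values over resampled subject-level group means
(5000 resamples, 95% intervals by default); and 2×4 within-subject ANOVA
(condition × set size) with each effect tested against its
subject-by-effect error stratum, partial η² = SS_eff/(SS_eff + SS_err), no
sphericity correction, and paired simple-effect contrasts of change vs
no-change at each set size. Subjects missing any of the eight cells are
dropped listwise and counted.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the downstream analyses assume.

**Score cohorts.** Each subject draws a phenotype from the mixing weights
(0.55/0.396/0.054) and its six scores from per-phenotype, per-age normals
(`phenotype_norms()` bundles the reference means and SDs). A per-subject
standard-normal effect shared across visits gives longitudinal correlation
with intraclass correlation 0.5 (a typical value for infant attention
measures; the marginal mean/SD at each visit match the parameter table
regardless). Interference goes missing completely at random at rate 7/111,
the observed rate of infants with no correct invalid trials. Parameter-mean
error rates are clipped to [0, 1]; draws are not truncated, keeping the
normal mixture exact for the LPA stage.

**IOWA sessions.** Latencies are drawn per condition from truncated normals
floored at 100 ms (the anticipatory cutoff) whose *location* is solved so
the truncated mean equals the designed condition mean — without this the
floor would bias the round trip. Condition means invert the score formulas
exactly: B = 5·meanSRT/(5 − 2F + I + C), valid = B(1 − F), invalid =
B(1 + I), double = valid + C·B, tone = no-cue = B. Within-subject
trial-to-trial SRT spread defaults to 80 ms, a realistic figure for infant
saccadic latency. Errors send the saccade to the wrong side with the
subject's condition-class error probability; the no-response probability
defaults to 0 so that scored accuracies equal the designed error rates
exactly (the generator's invertibility principle). Eyes move along 30 ms
half-cosine ramps (any profile exceeding 30 deg/s mid-flight is detectable;
realistic main-sequence kinematics are out of scope), with per-eye Gaussian
noise (0.2 deg), contiguous binocular dropout runs (geometric lengths, mean
40 ms) that exercise the interpolation logic, and occasional single-eye
invalidity that exercises cyclopean averaging. One master seed drives
everything; per-subject substreams are derived from seed + subject index.

**STM sessions.** Test-interval fixation sequences follow a Markov
dwell/switch chain over the occupied circle slots: shifted-exponential
dwells (floor 120 ms so simulated fixations survive detection), a dwell
mean that shrinks with set size (rate factor 1 + 0.35·(s − 1), so switching
intensifies on denser arrays), and off-circle looks with probability 0.1.
With the floor and off-looks disabled the chain's AOI transitions form a
Poisson process — the closed form the tests check against. Change detection
is a per-subject dwell-prolongation knob on the changed item, applied with
probability max(0, 1 − (s − 1)/capacity), capacity 2: a deliberately
capacity-limited detector, which is what makes the qualitative signature —
change preference at set sizes 1–2 only — generable at all.

**What the generator does not emulate:** pupillometry, head movement,
calibration drift, fatigue dynamics (trial counts are a truncation knob,
not a fussiness model), main-sequence saccade kinematics, and any
non-Gaussian structure in real score distributions. Passing round-trip
tests therefore demonstrates internal consistency of detection, scoring and
modelling — not that real infant data meet these assumptions.

## Validation strategy and problem sizes

The suite validates each stage against an independent oracle: a per-sample
brute-force labeler for the I-VT filter (100 random traces, ±1 sample), a
direct marginal multivariate-normal density for the growth likelihood
(1e-6), an external mixture implementation's E-step for the LPA likelihood
(1e-6), a direct sum-of-squares computation for the RM-ANOVA (1e-8), and
closed forms for velocities, entropy and rank statistics. Cohort-scale
checks use 111-subject cohorts (100 replicates) for profile recovery,
500 replicates for growth-coefficient recovery, 200 subjects × 100 trials
for the full simulate–detect–score round trip, and 1000-replicate null
simulations for test calibration (rejection rates at α = 0.05 within
(0.03, 0.07); bootstrap coverage within (0.93, 0.97)). These sizes keep
Monte-Carlo error well below the effects being checked while the whole
suite runs in a few minutes.

## Known limitations

* The variance floor makes the mixture likelihood a constrained ML; with
  very small profiles (a 5% profile in n = 111 is ~6 infants) the smallest
  component's parameters are inherently noisy, and component recovery is
  assessed by matched shares and adjusted Rand index rather than raw
  parameter error.
* Growth models fit random intercepts only; random slopes and small-sample
  df corrections (Satterthwaite, Kenward–Roger) are out of scope, matching
  the ML/LRT analysis they mirror.
* Detected absolute latencies carry the symmetric-window anticipation
  described above; comparisons of absolute SRT across detectors with
  different window conventions require care.
* The CLI is a thin dispatcher over the package functions; the package is
  primarily a library, and the functions plus this vignette are its main
  interface.
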