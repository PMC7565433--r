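## Synthetic gaze-stream generation for IOWA and STM sessions.
##
## The eye is modelled as a sequence of fixation keyframes; between
## keyframes the position ramps along a half-cosine over the saccade
## duration (30 ms by default), which comfortably exceeds the 30 deg/s I-VT
## threshold mid-flight for any saccade larger than a fraction of a degree.
## Per-condition saccade latencies are truncated-normal draws (floor 100 ms,
## the anticipatory cutoff) whose location parameter is solved so that the
## *truncated* mean equals the designed condition mean: the scoring formulas
## are then exactly invertible and the round trip is unbiased.

#' Gaze-simulation parameters
#'
#' @param sample_rate_hz sampling rate (nominal 300 Hz).
#' @param noise_sd_deg per-eye, per-sample Gaussian position noise (deg).
#' @param dropout_prob probability a binocular dropout starts at any sample.
#' @param dropout_mean_ms mean dropout length (geometric run lengths).
#' @param eye_invalid_prob independent per-eye single-sample invalidity.
#' @param saccade_dur_ms saccade flight duration.
#' @param srt_sd_ms within-subject trial-to-trial SRT standard deviation.
#' @param target_ecc_deg target eccentricity (deg).
#' @return list of class `gaze_sim_spec`.
#' @export
gaze_sim_spec <- function(sample_rate_hz = 300, noise_sd_deg = 0.2,
                          dropout_prob = 0.001, dropout_mean_ms = 40,
                          eye_invalid_prob = 0.005,
                          saccade_dur_ms = 30, srt_sd_ms = 80,
                          target_ecc_deg = 11) {
  if (sample_rate_hz <= 0) fail("gaze_sim_spec: sample rate must be > 0")
  if (target_ecc_deg > SCREEN_HALF_W) fail("gaze_sim_spec: target off screen")
  spec <- list(sample_rate_hz = sample_rate_hz, noise_sd_deg = noise_sd_deg,
               dropout_prob = dropout_prob, dropout_mean_ms = dropout_mean_ms,
               eye_invalid_prob = eye_invalid_prob,
               saccade_dur_ms = saccade_dur_ms, srt_sd_ms = srt_sd_ms,
               target_ecc_deg = target_ecc_deg)
  class(spec) <- "gaze_sim_spec"
  spec
}

## Truncated normal with matched mean: location solved so that the mean of
## the >= floor truncation equals `mean`. Draws by inverse CDF (exact).
rtnorm_matched <- function(n, mean, sd, floor = 100) {
  if (mean <= floor + 1e-6)
    fail("rtnorm_matched: designed mean %.1f not above the %.0f ms floor", mean, floor)
  mu <- tnorm_location(mean, sd, floor)
  a <- stats::pnorm((floor - mu) / sd)
  mu + sd * stats::qnorm(a + stats::runif(n) * (1 - a))
}

tnorm_location <- function(mean, sd, floor) {
  f <- function(mu) {
    a <- (floor - mu) / sd
    mu + sd * exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)) - mean
  }
  stats::uniroot(f, lower = mean - 8 * sd, upper = mean, extendInt = "upX",
                 tol = 1e-10)$root
}

## Half-cosine keyframe path: eye starts at (key_x[1], key_y[1]); from
## key_t[k] it ramps to keyframe k over `dur` ms, then holds.
gaze_path <- function(times, key_t, key_x, key_y, dur) {
  seg <- findInterval(times, key_t)
  seg[seg < 1L] <- 1L
  prev <- pmax(seg - 1L, 1L)
  frac <- pmin((times - key_t[seg]) / dur, 1)
  frac[seg == 1L] <- 1
  r <- (1 - cos(pi * frac)) / 2
  list(x = key_x[prev] + (key_x[seg] - key_x[prev]) * r,
       y = key_y[prev] + (key_y[seg] - key_y[prev]) * r)
}

## add noise/dropout and wrap as a gaze_stream
assemble_stream <- function(times, x, y, spec) {
  n <- length(times)
  clamp <- function(v, lim) pmin(pmax(v, -lim), lim)
  lx <- clamp(x + stats::rnorm(n, 0, spec$noise_sd_deg), SCREEN_HALF_W)
  ly <- clamp(y + stats::rnorm(n, 0, spec$noise_sd_deg), SCREEN_HALF_H)
  rx <- clamp(x + stats::rnorm(n, 0, spec$noise_sd_deg), SCREEN_HALF_W)
  ry <- clamp(y + stats::rnorm(n, 0, spec$noise_sd_deg), SCREEN_HALF_H)
  lv <- rep(TRUE, n); rv <- rep(TRUE, n)
  ## binocular dropout: contiguous invalid runs with geometric lengths
  if (spec$dropout_prob > 0) {
    dt <- 1000 / spec$sample_rate_hz
    starts <- which(stats::runif(n) < spec$dropout_prob)
    if (length(starts)) {
      lens <- 1L + stats::rgeom(length(starts),
                                pmin(1, dt / max(spec$dropout_mean_ms, dt)))
      drop <- unique(unlist(mapply(function(s, l) s:min(s + l - 1L, n),
                                   starts, lens, SIMPLIFY = FALSE)))
      lv[drop] <- FALSE; rv[drop] <- FALSE
    }
  }
  if (spec$eye_invalid_prob > 0) {
    lv[stats::runif(n) < spec$eye_invalid_prob] <- FALSE
    rv[stats::runif(n) < spec$eye_invalid_prob] <- FALSE
  }
  gaze_stream(times, lx, ly, rx, ry, lv, rv)
}

IOWA_TRIAL_MS <- 1800
IOWA_CUE_MS <- 400          # cue onset within trial
IOWA_TARGET_MS <- 600       # target onset within trial (100 cue + 100 blank)
IOWA_RETURN_MS <- 1680      # return saccade to the attention-getter

#' Build an IOWA trial schedule
#'
#' Blocks of ten trials: two of each cue condition, one with the target left
#' and one right, in random order within block.
#'
#' @param n_blocks number of blocks (12 blocks = 120 trials max in the task).
#' @param seed integer seed for the within-block shuffles.
#' @return IOWA trial-log data frame (absolute onsets, ms).
#' @export
iowa_trial_schedule <- function(n_blocks = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- expand.grid(condition = IOWA_CONDITIONS,
                      target_side = c("left", "right"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    base[sample(nrow(base)), , drop = FALSE]))
  n <- nrow(rows)
  t0 <- (seq_len(n) - 1) * IOWA_TRIAL_MS
  data.frame(trial_id = seq_len(n), condition = rows$condition,
             target_side = rows$target_side,
             cue_onset_ms = t0 + IOWA_CUE_MS,
             target_onset_ms = t0 + IOWA_TARGET_MS,
             stringsAsFactors = FALSE)
}

## condition-mean SRTs implied by a score vector; exactly invertible
condition_means <- function(scores) {
  F <- scores$facilitation; I <- scores$interference; C <- scores$competition
  B <- 5 * scores$mean_srt / (5 - 2 * F + I + C)
  c(tone = B, no_cue = B, valid = B * (1 - F), invalid = B * (1 + I),
    double = B * (1 - F) + C * B)
}

#' Simulate one IOWA session
#'
#' Generates a gaze stream in which the subject holds central fixation
#' through target onset on every trial, then saccades to the correct side
#' (or, with the subject's condition-wise error probability, the wrong side)
#' with a latency drawn from that condition's truncated-normal distribution.
#' Latencies encode the subject's facilitation, interference and competition
#' relative to the tone-condition baseline, so downstream scoring recovers
#' the generating scores. Noise and dropout are injected per `spec`.
#'
#' @param scores one-row data frame (or list) with the six attention scores.
#' @param schedule an [iowa_trial_schedule()].
#' @param spec a [gaze_sim_spec()].
#' @param p_no_response probability of withholding any target saccade.
#' @param seed integer seed.
#' @return list with `stream` (a [gaze_stream()]), `trial_log`, and `truth`
#'   (the generating per-condition latency means and error rates).
#' @export
simulate_iowa_session <- function(scores, schedule = iowa_trial_schedule(),
                                  spec = gaze_sim_spec(),
                                  p_no_response = 0, seed = NULL) {
  bad <- setdiff(unique(schedule$condition), IOWA_CONDITIONS)
  if (length(bad))
    fail("simulate_iowa_session: unknown condition label(s): %s",
         paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  cm <- condition_means(scores)
  err <- c(tone = scores$baseline_error, no_cue = scores$baseline_error,
           valid = scores$baseline_error, invalid = scores$task_error,
           double = scores$task_error)

  n_tr <- nrow(schedule)
  dt <- 1000 / spec$sample_rate_hz
  total <- n_tr * IOWA_TRIAL_MS
  times <- seq(0, total - dt / 2, by = dt)

  lat <- vapply(seq_len(n_tr), function(i)
    rtnorm_matched(1, cm[[schedule$condition[i]]], spec$srt_sd_ms), numeric(1))
  lat <- pmin(lat, IOWA_RETURN_MS - IOWA_TARGET_MS - spec$saccade_dur_ms - 10)
  wrong <- stats::runif(n_tr) < err[schedule$condition]
  respond <- stats::runif(n_tr) >= p_no_response
  side <- ifelse(schedule$target_side == "left", -1, 1) * ifelse(wrong, -1, 1)

  ## keyframes: trial start at center; saccade to the (possibly wrong)
  ## target; return to center late in the trial
  t0 <- (seq_len(n_tr) - 1) * IOWA_TRIAL_MS
  key_t <- c(0, rbind(t0 + IOWA_TARGET_MS + lat, t0 + IOWA_RETURN_MS))
  key_x <- c(0, rbind(ifelse(respond, side * spec$target_ecc_deg, 0), 0))
  key_y <- c(0, rbind(0 * lat, 0))
  ord <- order(key_t)
  p <- gaze_path(times, key_t[ord], key_x[ord], key_y[ord], spec$saccade_dur_ms)

  stream <- assemble_stream(times, p$x, p$y, spec)
  list(stream = stream, trial_log = schedule,
       truth = list(condition_means = cm, error = err, latency = lat,
                    responded = respond, wrong_side = wrong))
}

#' Simulate, detect and score a whole IOWA cohort
#'
#' Round-trip driver: for each row of `subjects` (one score vector per
#' subject) it simulates a session, runs I-VT detection and trial scoring,
#' and returns the recovered six-score vector next to the generating one.
#' Per-subject RNG substreams are derived from `seed` plus the subject index.
#'
#' @param subjects data frame with columns `subject` and the six scores.
#' @param n_blocks blocks per session.
#' @param spec a [gaze_sim_spec()].
#' @param dcfg a [detection_config()].
#' @param scfg a [scoring_config()].
#' @param seed master integer seed.
#' @return data frame with recovered scores and `gen_*` generating values.
#' @export
score_simulated_cohort <- function(subjects, n_blocks = 10,
                                   spec = gaze_sim_spec(),
                                   dcfg = detection_config(),
                                   scfg = scoring_config(), seed = 1) {
  out <- lapply(seq_len(nrow(subjects)), function(i) {
    si <- substream_seed(seed, i)
    set.seed(si)
    sess <- simulate_iowa_session(subjects[i, ],
                                  schedule = iowa_trial_schedule(n_blocks),
                                  spec = spec)
    ev <- detect_events(sess$stream, dcfg)
    outc <- score_iowa_session(ev, sess$trial_log, scfg)
    sc <- attention_scores(outc, scfg)
    gen <- subjects[i, SCORE_COLS]
    names(gen) <- paste0("gen_", SCORE_COLS)
    cbind(data.frame(subject = subjects$subject[i]), sc, gen)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---------------------------------------------------------------------------
## STM (change-detection) sessions

STM_TRIAL_MS <- 5500
STM_TEST_ONSET_MS <- 2000   # 500 fixation + 1000 sample + 500 retention
STM_TEST_MS <- 3000

stm_aoi_centers <- function() {
  ang <- c(45, 135, 225, 315) * pi / 180
  data.frame(aoi = 1:4, x = 8 * cos(ang), y = 8 * sin(ang))
}

#' Build an STM trial schedule
#'
#' Blocks cross set size 1-4 with change/no-change (8 trial types per block,
#' randomized within block). Circle slots for each trial are sampled from the
#' four positions at 8 deg eccentricity; on change trials one occupied slot
#' is marked as changed.
#'
#' @param n_blocks number of blocks (12 blocks = 96 trials max).
#' @param seed integer seed.
#' @return STM trial-log data frame.
#' @export
stm_trial_schedule <- function(n_blocks = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- expand.grid(set_size = 1:4, condition = STM_CONDITIONS,
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    base[sample(nrow(base)), , drop = FALSE]))
  n <- nrow(rows)
  aois <- vapply(rows$set_size, function(s)
    paste(sort(sample(1:4, s)), collapse = ","), character(1))
  changed <- rep(NA_integer_, n)
  is_ch <- rows$condition == "change"
  changed[is_ch] <- vapply(which(is_ch), function(i) {
    slots <- as.integer(strsplit(aois[i], ",")[[1]])
    if (length(slots) == 1) slots else sample(slots, 1)
  }, integer(1))
  data.frame(trial_id = seq_len(n), condition = rows$condition,
             set_size = rows$set_size,
             test_onset_ms = (seq_len(n) - 1) * STM_TRIAL_MS + STM_TEST_ONSET_MS,
             changed_aoi = changed, aois = aois, stringsAsFactors = FALSE)
}

#' STM looking-behavior parameters
#'
#' Test-interval fixation sequences follow a Markov dwell/switch process over
#' the occupied circle slots: dwell times are shifted-exponential
#' (`min_dwell_ms` plus an exponential tail), the dwell mean shrinks with set
#' size (`1 + size_gain * (set_size - 1)` rate multiplier, so switching
#' intensifies on denser arrays), and with probability `p_off` a fixation
#' lands off the circles (screen center) without interrupting an AOI run.
#' `detection` is the per-subject change-detection knob: on change trials the
#' dwell on the changed item is prolonged by `1 + detection`, applied with
#' probability `max(0, 1 - (set_size - 1)/capacity)` — a capacity-limited
#' detector (default capacity 2).
#'
#' @param dwell_mean_ms mean dwell at set size 1 (ms).
#' @param size_gain per-item switch-rate gain.
#' @param detection dwell-prolongation knob for the changed item (>= 0).
#' @param capacity set-size capacity of the detector.
#' @param p_off probability a fixation is off-AOI.
#' @param min_dwell_ms dwell floor (keeps fixations detectable).
#' @return list of class `stm_params`.
#' @export
stm_params <- function(dwell_mean_ms = 450, size_gain = 0.35, detection = 0,
                       capacity = 2, p_off = 0.1, min_dwell_ms = 120) {
  p <- list(dwell_mean_ms = dwell_mean_ms, size_gain = size_gain,
            detection = detection, capacity = capacity, p_off = p_off,
            min_dwell_ms = min_dwell_ms)
  class(p) <- "stm_params"
  p
}

## One test-interval fixation sequence; aoi = 0 marks an off-AOI fixation.
## Pure-exponential dwells (min_dwell_ms = 0, p_off = 0) make AOI
## transitions a Poisson process with rate 1/dwell mean.
simulate_stm_fixation_seq <- function(set_size, condition, changed_aoi, aois,
                                      params, window_ms = STM_TEST_MS) {
  if (set_size < 1 || set_size > 4)
    fail("simulate_stm_fixation_seq: set size outside 1-4")
  m_s <- params$dwell_mean_ms / (1 + params$size_gain * (set_size - 1))
  tail_mean <- max(m_s - params$min_dwell_ms, 1)
  detect <- condition == "change" && params$detection > 0 &&
    stats::runif(1) < max(0, 1 - (set_size - 1) / params$capacity)
  pick <- function(v) v[sample.int(length(v), 1)]   # safe for length-1 vectors
  cur <- pick(aois)
  t <- 0
  rows <- list()
  while (t < window_ms) {
    dwell <- params$min_dwell_ms + stats::rexp(1, 1 / tail_mean)
    if (detect && !is.na(changed_aoi) && cur == changed_aoi)
      dwell <- dwell * (1 + params$detection)
    off <- t + dwell
    rows[[length(rows) + 1]] <- c(cur, t, min(off, window_ms))
    t <- off
    if (t >= window_ms) break
    nxt <- if (stats::runif(1) < params$p_off) 0L else if (set_size == 1) {
      aois
    } else pick(setdiff(aois, cur))
    cur <- nxt
  }
  m <- do.call(rbind, rows)
  data.frame(aoi = as.integer(m[, 1]), onset_ms = m[, 2], offset_ms = m[, 3])
}

#' Simulate one STM session
#'
#' Generates the gaze stream of a change-detection session: central fixation
#' through the sample and retention intervals, then a Markov dwell/switch
#' fixation sequence over the occupied circle slots during the 3000 ms test
#' interval (see [stm_params()]).
#'
#' @param params an [stm_params()].
#' @param schedule an [stm_trial_schedule()].
#' @param spec a [gaze_sim_spec()].
#' @param seed integer seed.
#' @return list with `stream`, `trial_log` and `fixation_truth` (the
#'   generating per-trial fixation sequences).
#' @export
simulate_stm_session <- function(params = stm_params(),
                                 schedule = stm_trial_schedule(),
                                 spec = gaze_sim_spec(), seed = NULL) {
  if (any(schedule$set_size < 1 | schedule$set_size > 4))
    fail("simulate_stm_session: set size outside 1-4")
  if (!is.null(seed)) set.seed(seed)
  centers <- stm_aoi_centers()
  n_tr <- nrow(schedule)
  dt <- 1000 / spec$sample_rate_hz
  total <- n_tr * STM_TRIAL_MS
  times <- seq(0, total - dt / 2, by = dt)

  key_t <- 0; key_x <- 0; key_y <- 0
  truth <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- schedule[i, ]
    slots <- as.integer(strsplit(tr$aois, ",")[[1]])
    fx <- simulate_stm_fixation_seq(tr$set_size, tr$condition, tr$changed_aoi,
                                    slots, params)
    truth[[i]] <- fx
    px <- ifelse(fx$aoi == 0, 0, centers$x[match(fx$aoi, centers$aoi)])
    py <- ifelse(fx$aoi == 0, 0, centers$y[match(fx$aoi, centers$aoi)])
    key_t <- c(key_t, tr$test_onset_ms + fx$onset_ms,
               tr$test_onset_ms + STM_TEST_MS + 100)
    key_x <- c(key_x, px, 0)
    key_y <- c(key_y, py, 0)
  }
  p <- gaze_path(times, key_t, key_x, key_y, spec$saccade_dur_ms)
  stream <- assemble_stream(times, p$x, p$y, spec)
  list(stream = stream, trial_log = schedule, fixation_truth = truth)
}
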