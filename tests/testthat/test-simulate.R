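test_that("degenerate zero-noise cohorts reproduce the phenotype means exactly", {
  params <- phenotype_norms(11)
  params[grep("_sd$", names(params))] <- 0
  w <- c(high_flexible = 1 / 3, low_reactive = 1 / 3, high_reactive = 1 / 3)
  coh <- simulate_score_cohort(3, ages_mo = 11, params = params, weights = w,
                               missing_interference = 0, seed = 4)
  for (i in seq_len(nrow(coh))) {
    row <- params[params$phenotype == coh$phenotype[i], ]
    expect_equal(unlist(coh[i, SIX]), unlist(row[SIX]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("invalid cohort specs are rejected", {
  params <- phenotype_norms(11)
  params$facilitation_sd[1] <- -1
  expect_error(simulate_score_cohort(10, params = params), "sds")
  expect_error(simulate_score_cohort(10, weights = c(a = 0.6, b = 0.6)),
               "sum to 1")
  expect_error(simulate_score_cohort(2), "one subject per phenotype")
})

test_that("cohort generation is bitwise reproducible under a seed", {
  a <- simulate_score_cohort(50, ages_mo = c(5, 8, 11), seed = 77)
  b <- simulate_score_cohort(50, ages_mo = c(5, 8, 11), seed = 77)
  expect_identical(a, b)
})

test_that("cohort group means approach the generating means (3 SE)", {
  coh <- simulate_score_cohort(111 * 6, ages_mo = 11, missing_interference = 0,
                               seed = 13)
  params <- phenotype_norms(11)
  for (ph in unique(coh$phenotype)) {
    g <- coh[coh$phenotype == ph, ]
    row <- params[params$phenotype == ph, ]
    for (sc in SIX) {
      se <- row[[paste0(sc, "_sd")]] / sqrt(nrow(g))
      expect_lt(abs(mean(g[[sc]]) - row[[sc]]), 3 * se + 1e-12)
    }
  }
})

test_that("mixing proportions converge to the spec weights", {
  coh <- simulate_score_cohort(10000, ages_mo = 11, seed = 99)
  w <- phenotype_weights()
  tab <- table(coh$phenotype) / nrow(coh)
  for (ph in names(w)) {
    se <- sqrt(w[[ph]] * (1 - w[[ph]]) / 10000)
    expect_lt(abs(tab[[ph]] - w[[ph]]), 3 * se)
  }
})

test_that("interference goes missing at the requested rate", {
  coh <- simulate_score_cohort(4000, ages_mo = 11,
                               missing_interference = 7 / 111, seed = 5)
  rate <- mean(is.na(coh$interference))
  expect_lt(abs(rate - 7 / 111), 3 * sqrt(7 / 111 * (1 - 7 / 111) / 4000))
  expect_true(all(!is.na(coh$facilitation)))
})

iowa_theta <- data.frame(facilitation = 0.356, interference = 0.068,
                         competition = 0.135, baseline_error = 0.065,
                         task_error = 0.411, mean_srt = 283.787)

test_that("noise-free programmed latency is detected within the velocity half-window", {
  ## A symmetric velocity window flags the first sample whose +/- 10 ms
  ## span already contains enough of the saccade ramp, so detected onsets
  ## precede the programmed kinematic onset by up to half the window plus
  ## one sample of grid quantization; they can never be late by more than
  ## one sample. That asymmetric band is the exact property of the filter.
  spec <- gaze_sim_spec(noise_sd_deg = 0, dropout_prob = 0,
                        eye_invalid_prob = 0, srt_sd_ms = 1e-6)
  th <- iowa_theta
  th$baseline_error <- 0; th$task_error <- 0
  ## a single-condition schedule: all tone trials so every latency is the
  ## baseline; with srt_sd ~ 0 the programmed latency is the condition mean
  sched <- iowa_trial_schedule(2, seed = 1)
  sess <- simulate_iowa_session(th, sched, spec, seed = 2)
  ev <- detect_events(sess$stream)
  out <- score_iowa_session(ev, sess$trial_log)
  B <- 5 * th$mean_srt / (5 - 2 * th$facilitation + th$interference + th$competition)
  expected <- c(tone = B, no_cue = B, valid = B * (1 - th$facilitation),
                invalid = B * (1 + th$interference),
                double = B * (1 - th$facilitation) + th$competition * B)
  ok <- out[out$included & out$correct, ]
  expect_gt(nrow(ok), 15)
  w_half <- detection_config()$velocity_window_ms / 2
  err <- ok$srt_ms - vapply(ok$condition, function(cc) expected[[cc]], numeric(1))
  expect_true(all(err <= DT300 + 1e-6))
  expect_true(all(err >= -(w_half + DT300) - 1e-6))
})

test_that("zero error probabilities force zero scored error", {
  spec <- gaze_sim_spec(noise_sd_deg = 0.05, dropout_prob = 0)
  th <- iowa_theta
  th$baseline_error <- 0; th$task_error <- 0
  sess <- simulate_iowa_session(th, iowa_trial_schedule(4, seed = 3), spec,
                                seed = 6)
  sc <- attention_scores(score_iowa_session(detect_events(sess$stream),
                                            sess$trial_log))
  expect_equal(sc$task_error, 0)
  expect_equal(sc$baseline_error, 0)
})

test_that("unknown schedule conditions are rejected", {
  sched <- iowa_trial_schedule(1)
  sched$condition[1] <- "mystery"
  expect_error(simulate_iowa_session(iowa_theta, sched), "unknown condition")
})

test_that("simulated sessions honour gaze-stream invariants", {
  sess <- simulate_iowa_session(iowa_theta, iowa_trial_schedule(2), seed = 10)
  expect_s3_class(sess$stream, "gaze_stream")      # constructor validates
  expect_true(all(diff(sess$stream$time_ms) > 0))
  st <- simulate_stm_session(seed = 11)
  expect_true(all(diff(st$stream$time_ms) > 0))
})

test_that("session generation is reproducible under a seed", {
  a <- simulate_iowa_session(iowa_theta, iowa_trial_schedule(2, seed = 5), seed = 21)
  b <- simulate_iowa_session(iowa_theta, iowa_trial_schedule(2, seed = 5), seed = 21)
  expect_identical(a$stream, b$stream)
  sa <- simulate_stm_session(stm_params(), stm_trial_schedule(2, seed = 5), seed = 31)
  sb <- simulate_stm_session(stm_params(), stm_trial_schedule(2, seed = 5), seed = 31)
  expect_identical(sa$stream, sb$stream)
  expect_identical(sa$fixation_truth, sb$fixation_truth)
})

test_that("STM fixation chains: detection off is change-symmetric, set size drives switching", {
  chain_switches <- function(set_size, condition, n, params) {
    vapply(seq_len(n), function(i) {
      fx <- iowattn:::simulate_stm_fixation_seq(set_size, condition, 1L,
                                                seq_len(set_size), params)
      on_aoi <- fx$aoi != 0
      sum(diff(fx$aoi[on_aoi]) != 0)
    }, numeric(1))
  }
  p0 <- stm_params(detection = 0)
  set.seed(55)
  s_ch <- chain_switches(2, "change", 500, p0)
  s_nc <- chain_switches(2, "no_change", 500, p0)
  se <- sqrt(stats::var(s_ch) / 500 + stats::var(s_nc) / 500)
  expect_lt(abs(mean(s_ch) - mean(s_nc)), 3 * se + 0.2)

  s1 <- chain_switches(1, "no_change", 500, p0)
  s4 <- chain_switches(4, "no_change", 500, p0)
  expect_gt(mean(s4), mean(s1))
  expect_equal(mean(s1), 0)      # a single circle admits no switches

  expect_error(iowattn:::simulate_stm_fixation_seq(5, "change", 1L, 1:4, p0),
               "set size")
})
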