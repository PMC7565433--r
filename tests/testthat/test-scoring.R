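## Constructed event-list scoring tests. The canonical trial: central
## fixation through target onset at 600 ms, a saccade, then a fixation in
## the right-target area.
trial_spec <- function(cond = "valid", side = "right") {
  data.frame(trial_id = 1, condition = cond, target_side = side,
             cue_onset_ms = 400, target_onset_ms = 600,
             stringsAsFactors = FALSE)
}

make_trial_events <- function(srt = 250, land_x = 11, land_y = 0) {
  rbind(ev_row("fixation", 0, 600 + srt, 0, 0),
        ev_row("saccade", 600 + srt, 600 + srt + 30, pv = 300),
        ev_row("fixation", 600 + srt + 30, 2000, land_x, land_y))
}

test_that("a clean correct trial scores SRT to saccade onset", {
  out <- score_iowa_trial(make_trial_events(250), trial_spec())
  expect_true(out$included)
  expect_true(out$correct)
  expect_equal(out$srt_ms, 250)
})

test_that("responses under 100 ms are excluded as anticipatory", {
  out <- score_iowa_trial(make_trial_events(80), trial_spec())
  expect_false(out$included)
  expect_equal(out$exclusion_reason, "anticipatory")
})

test_that("wrong-side first fixation is an included error without SRT", {
  out <- score_iowa_trial(make_trial_events(250, land_x = -11), trial_spec())
  expect_true(out$included)
  expect_false(out$correct)
  expect_true(is.na(out$srt_ms))
})

test_that("trials without central fixation at target onset are excluded", {
  ev <- rbind(ev_row("fixation", 0, 900, 8, 0),   # parked off-center
              ev_row("fixation", 900, 2000, 11, 0))
  out <- score_iowa_trial(ev, trial_spec())
  expect_false(out$included)
  expect_equal(out$exclusion_reason, "not_fixating_center")
})

test_that("no target fixation within 1000 ms counts as a non-response", {
  ev <- rbind(ev_row("fixation", 0, 2000, 0, 0))
  out <- score_iowa_trial(ev, trial_spec())
  expect_true(out$included)
  expect_false(out$correct)
  expect_equal(out$exclusion_reason, "no_response")
})

test_that("fixation-arrival anchor is available by config", {
  out <- score_iowa_trial(make_trial_events(250), trial_spec(),
                          scoring_config(srt_anchor = "fixation"))
  expect_equal(out$srt_ms, 280)
})

## synthetic outcome tables for the score formulas
mk_outcomes <- function(cond, srt, correct, included = TRUE) {
  data.frame(trial_id = seq_along(cond), condition = cond,
             included = included, exclusion_reason = "none",
             correct = correct, srt_ms = ifelse(correct, srt, NA),
             stringsAsFactors = FALSE)
}

test_that("the six score formulas compute as printed", {
  ## facilitation: baseline 300, valid 210 -> 0.30
  oc <- mk_outcomes(c("tone", "valid", "invalid", "double", "no_cue"),
                    c(300, 210, 300, 250, 280), rep(TRUE, 5))
  sc <- attention_scores(oc)
  expect_equal(sc$facilitation, 0.30)
  expect_equal(sc$interference, 0)                 # invalid == baseline
  expect_equal(sc$competition, (250 - 210) / 300)
  expect_equal(sc$mean_srt, mean(c(300, 210, 300, 250, 280)))
  expect_equal(sc$baseline_srt_ms, 300)

  ## task error 0.55 from double 40% / invalid 50% correct; baseline error 0
  cond <- c(rep("double", 5), rep("invalid", 4), "valid", "tone", "no_cue")
  corr <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
            TRUE, TRUE, TRUE)
  oc <- mk_outcomes(cond, 250, corr)
  sc <- attention_scores(oc)
  expect_equal(sc$task_error, 1 - mean(c(2 / 5, 2 / 4)))
  expect_equal(sc$baseline_error, 0)
})

test_that("scores with empty ingredients are missing, not zero", {
  oc <- mk_outcomes(c("tone", "valid", "double"), c(300, 210, 250), TRUE)
  sc <- attention_scores(oc)
  expect_true(is.na(sc$interference))       # no invalid trials at all
  expect_true(is.na(sc$task_error))         # invalid accuracy undefined

  ## all invalid trials wrong: interference missing (no correct invalid SRTs)
  oc2 <- mk_outcomes(c("tone", "valid", "invalid", "invalid"),
                     c(300, 250, 320, 320), c(TRUE, TRUE, FALSE, FALSE))
  sc2 <- attention_scores(oc2)
  expect_true(is.na(sc2$interference))
  expect_equal(sc2$`n_invalid`, 2)

  ## no correct tone trials: all cueing scores missing, with a warning
  oc3 <- mk_outcomes(c("tone", "valid", "invalid"), c(300, 250, 340),
                     c(FALSE, TRUE, TRUE))
  expect_warning(sc3 <- attention_scores(oc3), "tone")
  expect_true(all(is.na(c(sc3$facilitation, sc3$interference, sc3$competition))))
})

test_that("cueing scores are invariant under SRT rescaling", {
  set.seed(42)
  cond <- sample(c("tone", "valid", "invalid", "double", "no_cue"), 60, TRUE)
  srt <- runif(60, 150, 450)
  corr <- runif(60) > 0.2
  oc <- mk_outcomes(cond, srt, corr)
  sc1 <- attention_scores(oc)
  for (c_scale in c(0.5, 2, 3.7)) {
    oc2 <- oc
    oc2$srt_ms <- oc$srt_ms * c_scale
    sc2 <- attention_scores(oc2)
    expect_equal(sc2$facilitation, sc1$facilitation)
    expect_equal(sc2$interference, sc1$interference)
    expect_equal(sc2$competition, sc1$competition)
    expect_equal(sc2$mean_srt, sc1$mean_srt * c_scale)
    expect_equal(sc2$task_error, sc1$task_error)
  }
})

test_that("Tukey fences flag implanted extremes and nothing else", {
  d <- data.frame(facilitation = c(1, 2, 3, 4, 100))
  fl <- flag_outliers(d, "facilitation")
  expect_equal(unname(which(fl$flags[, 1])), 5)
  expect_equal(unname(fl$fences["high", 1]), 4 + 1.5 * 2)

  same <- data.frame(facilitation = rep(2, 10))
  expect_equal(sum(flag_outliers(same, "facilitation")$flags), 0)

  ## implanted extreme subject in a simulated cohort
  coh <- simulate_score_cohort(40, ages_mo = 11, missing_interference = 0,
                               seed = 8)
  coh[40, SIX] <- coh[40, SIX] + 50 * vapply(coh[SIX], stats::sd, numeric(1))
  fl <- flag_outliers(coh)
  expect_true(all(fl$flags[40, ]))
  expect_equal(sum(fl$n_outliers[-40] == 6), 0)
})
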