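stm_trial <- function(cond = "change", set_size = 2, aois = "1,2",
                      changed = 1L) {
  data.frame(trial_id = 1, condition = cond, set_size = set_size,
             test_onset_ms = 0, changed_aoi = changed, aois = aois,
             stringsAsFactors = FALSE)
}

aoi_xy <- function(k) {
  cc <- iowattn:::stm_aoi_centers()
  unlist(cc[cc$aoi == k, c("x", "y")])
}

test_that("total look and switch count follow their definitions", {
  a <- aoi_xy(1); b <- aoi_xy(2)
  ev <- rbind(ev_row("fixation", 0, 400, a[1], a[2]),
              ev_row("fixation", 420, 720, a[1], a[2]),
              ev_row("fixation", 750, 1250, b[1], b[2]))
  m <- score_stm_trial(ev, stm_trial())
  expect_equal(m$total_look_ms, 1200)
  expect_equal(m$switch_count, 1)

  ## fixations at screen center score nothing
  ev0 <- ev_row("fixation", 0, 3000, 0, 0)
  m0 <- score_stm_trial(ev0, stm_trial())
  expect_equal(m0$total_look_ms, 0)
  expect_equal(m0$switch_count, 0)
})

test_that("off-AOI fixations are transparent to switch runs", {
  a <- aoi_xy(1); b <- aoi_xy(2)
  ev <- rbind(ev_row("fixation", 0, 400, a[1], a[2]),
              ev_row("fixation", 420, 800, 0, 0),          # center interlude
              ev_row("fixation", 820, 1300, b[1], b[2]),
              ev_row("fixation", 1320, 1800, b[1], b[2]))
  m <- score_stm_trial(ev, stm_trial())
  expect_equal(m$switch_count, 1)        # A -> (center) -> B -> B
})

test_that("looks are clipped to the test window", {
  a <- aoi_xy(1)
  ev <- rbind(ev_row("fixation", -500, 500, a[1], a[2]),
              ev_row("fixation", 2800, 3600, a[1], a[2]))
  m <- score_stm_trial(ev, stm_trial())
  expect_equal(m$total_look_ms, 500 + 200)
})

test_that("AOI slots must match the set size", {
  expect_error(score_stm_trial(ev_row("fixation", 0, 100, 0, 0),
                               stm_trial(set_size = 3, aois = "1,2")),
               "set size")
})

test_that("Markov chain switch counts match the analytic renewal expectation", {
  ## pure-exponential dwells with no off-looks: AOI transitions form a
  ## Poisson process with rate 1/mean dwell, so E[switches] = T / m
  p <- stm_params(dwell_mean_ms = 500, size_gain = 0, detection = 0,
                  p_off = 0, min_dwell_ms = 0)
  set.seed(77)
  sw <- vapply(1:1000, function(i) {
    fx <- iowattn:::simulate_stm_fixation_seq(3, "no_change", NA, 1:3, p)
    sum(diff(fx$aoi) != 0)
  }, numeric(1))
  expected <- 3000 / 500
  se <- stats::sd(sw) / sqrt(1000)
  expect_lt(abs(mean(sw) - expected), 3 * se)
})

test_that("scored sessions respect the measure invariants", {
  sess <- simulate_stm_session(stm_params(detection = 0.5),
                               stm_trial_schedule(2, seed = 1), seed = 2)
  m <- score_stm_session(detect_events(sess$stream), sess$trial_log)
  expect_true(all(m$total_look_ms <= 3000 + 1e-9))
  expect_true(all(m$total_look_ms >= 0))
  expect_true(all(m$switch_count >= 0))
  expect_true(all(m$switch_count <= pmax(m$n_fixations - 1, 0)))
})

test_that("Kruskal-Wallis matches the hand-ranked example and edge cases", {
  kw <- stm_kruskal(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7, tolerance = 1e-9)
  expect_equal(kw$df, 1)
  expect_equal(unname(kw$mean_ranks), c(2, 5))

  flat <- stm_kruskal(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)

  set.seed(3)
  far <- stm_kruskal(c(rnorm(20), rnorm(20) + 10), rep(c("a", "b"), each = 20))
  expect_lt(far$p_value, 0.001)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(4)
  v <- rexp(30); g <- rep(c("a", "b", "c"), 10)
  h0 <- stm_kruskal(v, g)$H
  expect_equal(stm_kruskal(log(v), g)$H, h0)
  expect_equal(stm_kruskal(v^3, g)$H, h0)
  expect_equal(stm_kruskal(rank(v), g)$H, h0)
})

test_that("bootstrap t behaves at the extremes", {
  set.seed(5)
  a <- rnorm(30)
  bt <- bootstrap_ttest(a, a, n_boot = 2000, seed = 6)
  expect_true(bt$ci[1] <= 0 && bt$ci[2] >= 0)

  b <- rnorm(30, 5)
  bt2 <- bootstrap_ttest(a, b, n_boot = 2000, seed = 7)
  expect_lt(bt2$p_boot, 0.001 + 2 / 2000)
  expect_true(bt2$ci[2] < 0)

  expect_warning(bootstrap_ttest(c(1, 1), c(1, 1), n_boot = 100, seed = 8),
                 "degenerate")
})

STM_chr <- c("change", "no_change")

test_that("RM-ANOVA agrees with the direct sum-of-squares oracle", {
  set.seed(9)
  d <- expand.grid(subject = 1:5, condition = STM_chr, set_size = 1:4,
                   stringsAsFactors = FALSE)
  d$total_look_ms <- 1000 + 100 * (d$subject %% 3) + 150 * d$set_size +
    80 * (d$condition == "change") + rnorm(40, 0, 50)
  a <- rm_anova_stm(d, "total_look_ms")
  b <- rm_anova_brute(d, "total_look_ms")
  expect_equal(a$effects$F, unname(b$F), tolerance = 1e-8)
  expect_equal(a$effects$partial_eta2,
               unname(b$ss / (b$ss + b$ss_err)), tolerance = 1e-8)
})

test_that("all-equal cells give zero F throughout", {
  d <- expand.grid(subject = 1:4, condition = STM_chr, set_size = 1:4,
                   stringsAsFactors = FALSE)
  d$total_look_ms <- 1500
  a <- rm_anova_stm(d, "total_look_ms")
  expect_equal(a$effects$F, c(0, 0, 0))
  expect_equal(a$effects$p, c(1, 1, 1))
})

test_that("implanted set-size effects are detected; null condition effects are not inflated", {
  set.seed(10)
  d <- expand.grid(subject = 1:20, condition = STM_chr, set_size = 1:4,
                   stringsAsFactors = FALSE)
  d$total_look_ms <- 1000 + 50 * (d$subject %% 5) + 120 * d$set_size +
    rnorm(nrow(d), 0, 60)
  a <- rm_anova_stm(d, "total_look_ms")
  eff <- a$effects
  expect_lt(eff$p[eff$effect == "set_size"], 0.001)
  expect_gt(eff$p[eff$effect == "condition"], 0.01)
  ## incomplete subjects are dropped listwise
  d2 <- d[-1, ]
  a2 <- rm_anova_stm(d2, "total_look_ms")
  expect_equal(a2$n_subjects, 19)
  expect_equal(a2$n_dropped, 1)
})

test_that("capacity-limited detectors show change preference at small set sizes only", {
  set.seed(11)
  p_det <- stm_params(detection = 1.2)
  sched <- stm_trial_schedule(8, seed = 12)
  look <- function(params, n_subj, seed0) {
    do.call(rbind, lapply(seq_len(n_subj), function(s) {
      sess <- simulate_stm_session(params, sched, seed = seed0 + s)
      m <- score_stm_session(detect_events(sess$stream), sess$trial_log)
      m$subject <- s
      m
    }))
  }
  m <- look(p_det, 6, 100)
  cm <- stats::aggregate(total_look_ms ~ condition + set_size, m, mean)
  small <- cm[cm$set_size %in% 1:2, ]
  pref_small <- with(small, mean(total_look_ms[condition == "change"]) -
                       mean(total_look_ms[condition == "no_change"]))
  expect_gt(pref_small, 0)

  m0 <- look(stm_params(detection = 0), 6, 200)
  cm0 <- stats::aggregate(total_look_ms ~ condition, m0[m0$set_size <= 2, ], mean)
  pref0 <- diff(rev(cm0$total_look_ms))
  expect_lt(abs(pref0), pref_small)
})
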