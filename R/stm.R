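## Visual short-term-memory (change-detection) looking measures and tests.
##
## Per-trial measures over the 3000 ms test interval: total look duration
## (sum of fixation time on the circle interest areas, clipped to the
## window) and switch count (transitions between distinct circle areas;
## off-area fixations neither count as switches nor terminate a run).

#' STM scoring options
#'
#' @param capture_radius_deg fixations within this distance of an occupied
#'   circle center are assigned to it (circle radius 2.5 deg plus 1 deg
#'   calibration slack by default).
#' @param test_window_ms duration of the test interval.
#' @return list of class `stm_scoring_config`.
#' @export
stm_scoring_config <- function(capture_radius_deg = 3.5,
                               test_window_ms = 3000) {
  cfg <- list(capture_radius_deg = capture_radius_deg,
              test_window_ms = test_window_ms)
  class(cfg) <- "stm_scoring_config"
  cfg
}

#' Score one STM trial
#'
#' Fixations overlapping the test window are clipped to it and assigned to
#' the nearest occupied circle center within the capture radius. Total look
#' sums assigned fixation durations; switches count consecutive assigned
#' fixations on different circles (unassigned fixations are transparent).
#'
#' @param events event data frame covering the test interval.
#' @param trial one-row STM trial record (`test_onset_ms`, `set_size`,
#'   `aois` as comma-separated slot indices).
#' @param cfg an [stm_scoring_config()].
#' @return one-row data frame `trial_id, condition, set_size, total_look_ms,
#'   switch_count, n_fixations`.
#' @export
score_stm_trial <- function(events, trial, cfg = stm_scoring_config()) {
  slots <- as.integer(strsplit(trial$aois, ",")[[1]])
  if (length(slots) != trial$set_size || any(!slots %in% 1:4))
    fail("score_stm_trial: AOI slots inconsistent with set size (trial %s)",
         trial$trial_id)
  centers <- stm_aoi_centers()
  centers <- centers[centers$aoi %in% slots, , drop = FALSE]
  t0 <- trial$test_onset_ms; t1 <- t0 + cfg$test_window_ms

  fix <- events[events$kind == "fixation" & events$offset_ms > t0 &
                  events$onset_ms < t1, , drop = FALSE]
  total <- 0; switches <- 0L; last_aoi <- NA_integer_; nfix <- 0L
  if (nrow(fix)) {
    for (i in seq_len(nrow(fix))) {
      d2 <- (fix$x_deg[i] - centers$x)^2 + (fix$y_deg[i] - centers$y)^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > cfg$capture_radius_deg) next
      aoi <- centers$aoi[j]
      dur <- min(fix$offset_ms[i], t1) - max(fix$onset_ms[i], t0)
      total <- total + dur
      nfix <- nfix + 1L
      if (!is.na(last_aoi) && aoi != last_aoi) switches <- switches + 1L
      last_aoi <- aoi
    }
  }
  data.frame(trial_id = trial$trial_id, condition = trial$condition,
             set_size = trial$set_size, total_look_ms = total,
             switch_count = switches, n_fixations = nfix,
             stringsAsFactors = FALSE)
}

#' Score every trial of an STM session
#'
#' @param events event data frame for the session.
#' @param trial_log STM trial log.
#' @param cfg an [stm_scoring_config()].
#' @return data frame of per-trial measures.
#' @export
score_stm_session <- function(events, trial_log, cfg = stm_scoring_config()) {
  out <- lapply(seq_len(nrow(trial_log)), function(i) {
    tr <- trial_log[i, ]
    ev <- events[events$offset_ms > tr$test_onset_ms &
                   events$onset_ms < tr$test_onset_ms + cfg$test_window_ms, ,
                 drop = FALSE]
    score_stm_trial(ev, tr, cfg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average trial measures into subject cells
#'
#' One record per subject x condition x set size (each participant
#' contributes one sample per cell), the observation unit of the group
#' tests.
#'
#' @param measures per-trial measures with a `subject` column.
#' @return data frame of cell means of `total_look_ms` and `switch_count`.
#' @export
stm_cell_means <- function(measures) {
  agg <- stats::aggregate(measures[, c("total_look_ms", "switch_count")],
                          by = list(subject = measures$subject,
                                    condition = measures$condition,
                                    set_size = measures$set_size),
                          FUN = mean)
  agg[order(agg$subject, agg$condition, agg$set_size), ]
}

#' Kruskal-Wallis test with per-group mean ranks
#'
#' Tie-corrected H against a chi-square with (groups - 1) df, via
#' [stats::kruskal.test()], plus per-group mean ranks of the pooled sample.
#'
#' @param values numeric observations (one per subject cell).
#' @param groups group labels (e.g., phenotype).
#' @return list `H, df, p_value, mean_ranks`.
#' @export
stm_kruskal <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) fail("stm_kruskal: need >= 2 groups")
  mr <- c(tapply(rank(values), groups, mean))
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p_value = 1, mean_ranks = mr))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, mean_ranks = mr)
}

#' Welch t-test with percentile-bootstrap inference
#'
#' The observed statistic is the Welch t; the confidence interval and
#' two-sided p-value come from a percentile bootstrap over the difference of
#' resampled group means (groups resampled independently with replacement).
#'
#' @param a,b numeric samples (subject-level means).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list `t, df, mean_diff, ci, p_boot, degenerate`.
#' @export
bootstrap_ttest <- function(a, b, n_boot = 5000, conf = 0.95, seed = NULL) {
  if (length(a) < 2 || length(b) < 2)
    fail("bootstrap_ttest: each group needs n >= 2")
  if (!is.null(seed)) set.seed(seed)
  tt <- if (stats::sd(a) + stats::sd(b) < 1e-12) {
    list(statistic = NA_real_, parameter = NA_real_)   # constant groups
  } else stats::t.test(a, b)
  am <- colMeans(matrix(sample(a, length(a) * n_boot, replace = TRUE), length(a)))
  bm <- colMeans(matrix(sample(b, length(b) * n_boot, replace = TRUE), length(b)))
  diffs <- am - bm
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha)))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(max(p, 2 / n_boot), 1)
  degenerate <- ci[1] == ci[2]
  if (degenerate) warning("bootstrap_ttest: degenerate groups; CI collapsed")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       mean_diff = mean(a) - mean(b), ci = ci, p_boot = p,
       degenerate = degenerate)
}

#' Two-by-four repeated-measures ANOVA on STM cell means
#'
#' Classical within-subject decomposition with condition (change/no-change),
#' set size (1-4) and their interaction, each tested against its
#' subject-by-effect error stratum; no sphericity correction. Partial
#' eta-squared is `SS_effect / (SS_effect + SS_error)`. Simple main effects
#' are paired change vs no-change contrasts at each set size. Subjects
#' missing any of the eight cells are dropped listwise (reported in
#' `n_dropped`).
#'
#' @param cells cell-mean data frame (`subject, condition, set_size`, and
#'   the measure column).
#' @param measure `"total_look_ms"` or `"switch_count"`.
#' @return list with `effects` (data frame: SS, df, F, p, partial eta^2),
#'   `simple_effects`, `n_subjects`, `n_dropped`.
#' @export
rm_anova_stm <- function(cells, measure = c("total_look_ms", "switch_count")) {
  measure <- match.arg(measure)
  d <- data.frame(subject = factor(cells$subject),
                  condition = factor(cells$condition, levels = STM_CONDITIONS),
                  set_size = factor(cells$set_size, levels = 1:4),
                  value = cells[[measure]])
  ncell <- table(d$subject)
  complete <- names(ncell)[ncell == 8]
  n_dropped <- nlevels(d$subject) - length(complete)
  if (length(complete) < 2) fail("rm_anova_stm: need >= 2 complete subjects")
  d <- droplevels(d[d$subject %in% complete, , drop = FALSE])

  fit <- stats::aov(value ~ condition * set_size +
                      Error(subject / (condition * set_size)), data = d)
  s <- summary(fit)
  grab <- function(stratum, effect) {
    tab <- s[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn); j <- match("Residuals", rn)
    ss <- tab$`Sum Sq`[i]; ss_err <- tab$`Sum Sq`[j]
    Fv <- tab$`F value`[i]; pv <- tab$`Pr(>F)`[i]
    eta <- ss / (ss + ss_err)
    if (ss < 1e-12) {            # degenerate stratum (e.g., all cells equal)
      Fv <- 0; pv <- 1; eta <- 0
    }
    data.frame(effect = effect, ss = ss, df = tab$Df[i],
               ss_err = ss_err, df_err = tab$Df[j],
               F = Fv, p = pv, partial_eta2 = eta,
               stringsAsFactors = FALSE)
  }
  effects <- rbind(
    grab("Error: subject:condition", "condition"),
    grab("Error: subject:set_size", "set_size"),
    grab("Error: subject:condition:set_size", "condition:set_size"))

  simple <- do.call(rbind, lapply(levels(d$set_size), function(ss) {
    w <- d[d$set_size == ss, ]
    w <- w[order(w$subject, w$condition), ]
    ch <- w$value[w$condition == "change"]
    nc <- w$value[w$condition == "no_change"]
    if (stats::sd(ch - nc) < 1e-12) {
      tt <- list(statistic = if (mean(ch - nc) == 0) 0 else Inf,
                 parameter = length(ch) - 1,
                 p.value = if (mean(ch - nc) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(ch, nc, paired = TRUE)
    }
    data.frame(set_size = as.integer(ss), mean_change = mean(ch),
               mean_no_change = mean(nc), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(effects = effects, simple_effects = simple,
       n_subjects = length(complete), n_dropped = n_dropped)
}
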