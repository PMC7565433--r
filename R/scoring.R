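## IOWA trial scoring and the six per-subject attention scores.
##
## Conditions: valid, invalid, double (cued trials), tone and no_cue
## (baselines). The tone condition provides each infant's baseline orienting
## speed used to normalize the three cueing scores.

#' Scoring options for the IOWA task
#'
#' Geometry and conventions for turning ocular events plus a trial log into
#' trial outcomes. Target interest areas are 15 x 15 deg squares centered
#' 11 deg left/right of screen center; the central area is a square of
#' configurable half-width (default 3.5 deg, wide enough to absorb
#' calibration error while staying clear of the targets). Overlapping
#' central/target areas are rejected at validation.
#'
#' @param central_half_deg half-width of the central fixation area (deg).
#' @param target_ecc_deg target eccentricity (deg).
#' @param target_half_deg half-width of the target interest areas (deg).
#' @param response_window_ms window after target onset in which the first
#'   target-area fixation counts as the response.
#' @param anticipatory_ms latencies below this are discarded as anticipatory.
#' @param srt_anchor `"saccade"` (default: latency measured to the onset of
#'   the saccade that precedes the response fixation, the standard saccadic-
#'   latency convention) or `"fixation"` (fixation arrival).
#' @param mean_srt `"pooled"` (default: unweighted mean over all correct
#'   trials) or `"by_condition"` (mean of per-condition means).
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(central_half_deg = 3.5, target_ecc_deg = 11,
                           target_half_deg = 7.5, response_window_ms = 1000,
                           anticipatory_ms = 100,
                           srt_anchor = c("saccade", "fixation"),
                           mean_srt = c("pooled", "by_condition")) {
  srt_anchor <- match.arg(srt_anchor)
  mean_srt <- match.arg(mean_srt)
  if (central_half_deg > target_ecc_deg - target_half_deg)
    fail("scoring_config: central area overlaps the target areas")
  cfg <- list(central_half_deg = central_half_deg,
              target_ecc_deg = target_ecc_deg,
              target_half_deg = target_half_deg,
              response_window_ms = response_window_ms,
              anticipatory_ms = anticipatory_ms,
              srt_anchor = srt_anchor, mean_srt = mean_srt)
  class(cfg) <- "scoring_config"
  cfg
}

in_square <- function(x, y, cx, cy, half) {
  abs(x - cx) <= half & abs(y - cy) <= half
}

#' Score a single IOWA trial
#'
#' A trial is included only if a fixation containing target onset lies in the
#' central area. The response is the first fixation starting within the
#' response window whose centroid falls in either target area; it is correct
#' iff it falls on the cued-target side. SRT is measured from target onset to
#' the onset of the saccade preceding the response fixation (see
#' [scoring_config()]); responses faster than the anticipatory cutoff are
#' excluded. Trials with no target-area fixation in the window are included
#' and counted as incorrect non-responses.
#'
#' @param events event data frame covering the trial window.
#' @param trial one-row trial record with `trial_id`, `condition`,
#'   `target_side` (`"left"`/`"right"`) and `target_onset_ms`.
#' @param cfg a [scoring_config()].
#' @return one-row data frame: `trial_id, condition, included,
#'   exclusion_reason, correct, srt_ms`.
#' @export
score_iowa_trial <- function(events, trial, cfg = scoring_config()) {
  t_on <- trial$target_onset_ms
  win_end <- t_on + cfg$response_window_ms
  if (nrow(events) == 0 || min(events$onset_ms) > t_on ||
      max(events$offset_ms) < t_on)
    fail("score_iowa_trial: events do not cover the trial window (trial %s)",
         trial$trial_id)
  out <- data.frame(trial_id = trial$trial_id, condition = trial$condition,
                    included = FALSE, exclusion_reason = "none",
                    correct = FALSE, srt_ms = NA_real_,
                    stringsAsFactors = FALSE)

  fix <- events[events$kind == "fixation", , drop = FALSE]
  ## central-fixation gate at target onset
  at_onset <- fix$onset_ms <= t_on & fix$offset_ms > t_on
  central <- at_onset & in_square(fix$x_deg, fix$y_deg, 0, 0, cfg$central_half_deg)
  if (!any(central)) {
    out$exclusion_reason <- "not_fixating_center"
    return(out)
  }

  sgn <- if (trial$target_side == "left") -1 else 1
  cand <- fix[fix$onset_ms > t_on & fix$onset_ms <= win_end, , drop = FALSE]
  on_left <- in_square(cand$x_deg, cand$y_deg, -cfg$target_ecc_deg, 0, cfg$target_half_deg)
  on_right <- in_square(cand$x_deg, cand$y_deg, cfg$target_ecc_deg, 0, cfg$target_half_deg)
  hit <- which(on_left | on_right)
  if (!length(hit)) {
    out$included <- TRUE
    out$exclusion_reason <- "no_response"
    return(out)
  }
  resp <- cand[hit[1], ]
  resp_side <- if (on_left[hit[1]]) -1 else 1

  ## latency anchor: onset of the saccade immediately preceding the response
  anchor <- resp$onset_ms
  if (cfg$srt_anchor == "saccade") {
    sac <- events[events$kind == "saccade" & events$offset_ms <= resp$onset_ms + 1e-9, ,
                  drop = FALSE]
    if (nrow(sac)) anchor <- sac$onset_ms[nrow(sac)]
  }
  srt <- anchor - t_on
  if (srt < cfg$anticipatory_ms) {
    out$exclusion_reason <- "anticipatory"
    return(out)
  }
  out$included <- TRUE
  out$correct <- resp_side == sgn
  if (out$correct) out$srt_ms <- srt
  out
}

#' Score every trial of an IOWA session
#'
#' Splits a session's event list by trial window and scores each trial.
#'
#' @param events event data frame for the whole session.
#' @param trial_log IOWA trial log (see [read_trial_log()]).
#' @param cfg a [scoring_config()].
#' @return data frame of per-trial outcomes.
#' @export
score_iowa_session <- function(events, trial_log, cfg = scoring_config()) {
  out <- lapply(seq_len(nrow(trial_log)), function(i) {
    tr <- trial_log[i, ]
    lo <- tr$target_onset_ms - 600
    hi <- tr$target_onset_ms + cfg$response_window_ms + 100
    ev <- events[events$offset_ms > lo & events$onset_ms < hi, , drop = FALSE]
    score_iowa_trial(ev, tr, cfg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Six attention scores for one subject-visit
#'
#' Per-condition mean SRT is taken over correct included trials. The scores:
#' facilitation `(baseline - valid)/baseline`, interference
#' `(invalid - baseline)/baseline`, competition `(double - valid)/baseline`
#' (baseline = tone-condition mean SRT); mean SRT over all correct trials;
#' task error `1 - mean(double, invalid accuracy)`; baseline error
#' `1 - mean(valid, tone, no-cue accuracy)`. Scores whose ingredients are
#' empty are `NA`, never zero — in particular interference is missing when
#' there are no correct invalid trials.
#'
#' @param outcomes per-trial outcomes from [score_iowa_session()].
#' @param cfg a [scoring_config()].
#' @return one-row data frame with the six scores, `baseline_srt_ms`, and
#'   per-condition correct/included counts.
#' @export
attention_scores <- function(outcomes, cfg = scoring_config()) {
  inc <- outcomes[outcomes$included, , drop = FALSE]
  conds <- IOWA_CONDITIONS
  n_inc <- vapply(conds, function(cc) sum(inc$condition == cc), numeric(1))
  n_cor <- vapply(conds, function(cc) sum(inc$condition == cc & inc$correct), numeric(1))
  msrt <- vapply(conds, function(cc) {
    v <- inc$srt_ms[inc$condition == cc & inc$correct]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  acc <- ifelse(n_inc > 0, n_cor / n_inc, NA_real_)

  base <- msrt[["tone"]]
  if (is.na(base))
    warning("attention_scores: no correct tone trials; cueing scores missing")
  facilitation <- (base - msrt[["valid"]]) / base
  interference <- (msrt[["invalid"]] - base) / base
  competition <- (msrt[["double"]] - msrt[["valid"]]) / base

  mean_srt <- if (cfg$mean_srt == "pooled") {
    v <- inc$srt_ms[inc$correct]
    if (length(v)) mean(v) else NA_real_
  } else {
    mean(msrt, na.rm = FALSE)
  }
  task_error <- 1 - mean(acc[c("double", "invalid")])
  baseline_error <- 1 - mean(acc[c("valid", "tone", "no_cue")])

  res <- data.frame(facilitation = facilitation, interference = interference,
                    competition = competition, mean_srt = mean_srt,
                    task_error = task_error, baseline_error = baseline_error,
                    baseline_srt_ms = base)
  for (cc in conds) {
    res[[paste0("n_", cc)]] <- n_inc[[cc]]
    res[[paste0("n_correct_", cc)]] <- n_cor[[cc]]
  }
  res
}

SCORE_COLS <- c("facilitation", "interference", "competition",
                "baseline_error", "task_error", "mean_srt")

#' Tukey-fence outlier flags for a cohort score table
#'
#' Flags values beyond `Q3 + 1.5 IQR` or below `Q1 - 1.5 IQR` per score
#' column (quartiles by linear interpolation) and annotates each subject with
#' its outlier count. No subject is removed.
#'
#' @param scores data frame containing the six score columns (plus any id
#'   columns, which are preserved).
#' @param score_cols columns to screen.
#' @return list with `flags` (logical matrix), `n_outliers` (per row) and
#'   `fences` (per column low/high).
#' @export
flag_outliers <- function(scores, score_cols = SCORE_COLS) {
  score_cols <- intersect(score_cols, names(scores))
  flags <- matrix(FALSE, nrow(scores), length(score_cols),
                  dimnames = list(NULL, score_cols))
  fences <- matrix(NA_real_, 2, length(score_cols),
                   dimnames = list(c("low", "high"), score_cols))
  for (sc in score_cols) {
    v <- scores[[sc]]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning(sprintf("flag_outliers: column %s all missing; skipped", sc))
      next
    }
    if (sum(ok) < 4)
      fail("flag_outliers: need >= 4 non-missing values in %s", sc)
    q <- stats::quantile(v[ok], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    fences[, sc] <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
    flags[ok, sc] <- v[ok] < fences["low", sc] | v[ok] > fences["high", sc]
  }
  list(flags = flags, n_outliers = rowSums(flags), fences = fences)
}
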