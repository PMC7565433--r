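## I-VT velocity-threshold parsing of gaze streams into fixations/saccades.
##
## Pipeline: average the two eyes into a cyclopean trace, interpolate short
## invalid gaps, smooth with a centered moving average, compute angular speed
## over a symmetric window, threshold into saccade/fixation runs, merge
## nearby fixations, discard too-short fixations.

#' Detection parameters for the I-VT filter
#'
#' Defaults follow the standard I-VT parameterization for 300 Hz infant data:
#' gaps of at most 75 ms are interpolated, positions are smoothed with a
#' 3-sample moving average, angular speed is computed over a symmetric 20 ms
#' window, samples at or above 30 deg/s are saccadic, adjacent fixations
#' closer than 75 ms and 0.5 deg are merged, and fixations shorter than 60 ms
#' are discarded.
#'
#' The merge angle defaults to the conventional 0.5 deg; larger values (which
#' would merge across distinct interest areas) remain selectable.
#'
#' @param max_gap_ms longest invalid run (ms) interpolated across.
#' @param smooth_window moving-average width in samples (odd).
#' @param velocity_window_ms symmetric velocity window (ms).
#' @param saccade_threshold_dps saccade velocity threshold (deg/s).
#' @param merge_max_ms,merge_max_deg limits for merging adjacent fixations.
#' @param min_fixation_ms shortest fixation retained (ms).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(max_gap_ms = 75, smooth_window = 3,
                             velocity_window_ms = 20,
                             saccade_threshold_dps = 30,
                             merge_max_ms = 75, merge_max_deg = 0.5,
                             min_fixation_ms = 60) {
  cfg <- list(max_gap_ms = max_gap_ms, smooth_window = smooth_window,
              velocity_window_ms = velocity_window_ms,
              saccade_threshold_dps = saccade_threshold_dps,
              merge_max_ms = merge_max_ms, merge_max_deg = merge_max_deg,
              min_fixation_ms = min_fixation_ms)
  if (any(unlist(cfg) <= 0)) fail("detection_config: all parameters must be > 0")
  if (smooth_window %% 2 != 1) fail("detection_config: smooth_window must be odd")
  class(cfg) <- "detection_config"
  cfg
}

#' Preprocess a gaze stream into a cyclopean trace
#'
#' Averages the valid eyes sample-wise (single eye when only one is valid,
#' invalid when both are), linearly interpolates invalid runs no longer than
#' `max_gap_ms` between their flanking valid samples, then applies a centered
#' moving average within each contiguous valid span (window truncated at span
#' edges).
#'
#' @param stream a [gaze_stream()].
#' @param cfg a [detection_config()].
#' @return data frame `time_ms, x_deg, y_deg, valid`.
#' @export
preprocess_gaze <- function(stream, cfg = detection_config()) {
  if (nrow(stream) == 0) fail("preprocess_gaze: empty stream")
  lv <- stream$l_valid; rv <- stream$r_valid
  n <- nrow(stream)
  x <- ifelse(lv & rv, (stream$lx_deg + stream$rx_deg) / 2,
              ifelse(lv, stream$lx_deg, stream$rx_deg))
  y <- ifelse(lv & rv, (stream$ly_deg + stream$ry_deg) / 2,
              ifelse(lv, stream$ly_deg, stream$ry_deg))
  valid <- lv | rv
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  t <- stream$time_ms

  ## interpolate interior invalid runs whose duration <= max gap
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next               # edge gaps stay gaps
    gap_ms <- t[i1 + 1L] - t[i0 - 1L]            # span between flanking valids
    ## duration of missing data: time covered by the invalid samples
    miss_ms <- t[i1] - t[i0] + (t[i1 + 1L] - t[i1])
    if (miss_ms > cfg$max_gap_ms) next
    w <- (t[i0:i1] - t[i0 - 1L]) / gap_ms
    x[i0:i1] <- x[i0 - 1L] + w * (x[i1 + 1L] - x[i0 - 1L])
    y[i0:i1] <- y[i0 - 1L] + w * (y[i1 + 1L] - y[i0 - 1L])
    valid[i0:i1] <- TRUE
  }

  ## centered moving average within valid spans
  half <- (cfg$smooth_window - 1L) %/% 2L
  if (half > 0) {
    r <- rle(valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    xs <- x; ys <- y
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      idx <- starts[k]:ends[k]
      m <- length(idx)
      if (m == 1L) next
      cx <- cumsum(c(0, x[idx])); cy <- cumsum(c(0, y[idx]))
      lo <- pmax(seq_len(m) - half, 1L); hi <- pmin(seq_len(m) + half, m)
      xs[idx] <- (cx[hi + 1L] - cx[lo]) / (hi - lo + 1L)
      ys[idx] <- (cy[hi + 1L] - cy[lo]) / (hi - lo + 1L)
    }
    x <- xs; y <- ys
  }
  data.frame(time_ms = t, x_deg = x, y_deg = y, valid = valid)
}

#' Angular speed of a preprocessed trace
#'
#' Speed at sample `t` is the Euclidean angular displacement between the
#' samples half a window before and after `t`, divided by their time
#' difference. Undefined (`NA`) inside gaps and where the window would leave
#' the sample's valid span.
#'
#' @param trace output of [preprocess_gaze()].
#' @param cfg a [detection_config()].
#' @return numeric vector of speeds (deg/s), `NA` where undefined.
#' @export
gaze_velocity <- function(trace, cfg = detection_config()) {
  t <- trace$time_ms
  n <- length(t)
  dt <- stats::median(diff(t))
  k <- round((cfg$velocity_window_ms / 2) / dt)
  if (k < 1) fail("gaze_velocity: velocity window shorter than 2 sample periods")
  v <- rep(NA_real_, n)
  if (n <= 2 * k) return(v)
  i <- (k + 1L):(n - k)
  lo <- i - k; hi <- i + k
  ok <- trace$valid[i] & trace$valid[lo] & trace$valid[hi]
  ## window must not span a gap: require all samples in between valid
  run <- cumsum(!trace$valid)          # constant across an all-valid stretch
  ok <- ok & (run[hi] == run[lo])
  disp <- sqrt((trace$x_deg[hi] - trace$x_deg[lo])^2 +
               (trace$y_deg[hi] - trace$y_deg[lo])^2)
  v[i][ok] <- 1000 * disp[ok] / (t[hi] - t[lo])[ok]
  v
}

## run table helper: data.frame of runs of `lab` with start/end indices
label_runs <- function(lab) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L, end = ends,
             stringsAsFactors = FALSE)
}

#' Classify a preprocessed trace into ocular events
#'
#' Samples at or above the saccade threshold become saccade runs, samples
#' below become fixation runs. Edge samples with undefined velocity inherit
#' the nearest interior classification within their valid span. Adjacent
#' fixations separated by less than `merge_max_ms` and whose centroids are
#' closer than `merge_max_deg` are merged (the intervening samples join the
#' fixation); fixations shorter than `min_fixation_ms` are then reclassified
#' as gaps. Events tile the valid trace.
#'
#' @param trace output of [preprocess_gaze()].
#' @param velocity output of [gaze_velocity()].
#' @param cfg a [detection_config()].
#' @return data frame `kind, onset_ms, offset_ms, x_deg, y_deg, peak_vel_dps`
#'   ordered by onset; `kind` is `"fixation"`, `"saccade"` or `"gap"`.
#' @export
classify_events <- function(trace, velocity, cfg = detection_config()) {
  n <- nrow(trace)
  t <- trace$time_ms
  dt <- if (n > 1) stats::median(diff(t)) else 0
  lab <- rep("gap", n)
  lab[trace$valid & !is.na(velocity)] <-
    ifelse(velocity[trace$valid & !is.na(velocity)] >= cfg$saccade_threshold_dps,
           "saccade", "fixation")

  ## valid samples with undefined velocity inherit nearest interior label
  und <- which(trace$valid & is.na(velocity))
  if (length(und)) {
    def <- which(trace$valid & !is.na(velocity))
    gapcount <- cumsum(!trace$valid)
    for (i in und) {
      if (!length(def)) { lab[i] <- "fixation"; next }
      cand <- def[gapcount[def] == gapcount[i]]   # same valid span
      if (!length(cand)) { lab[i] <- "fixation"; next }
      lab[i] <- lab[cand[which.min(abs(cand - i))]]
    }
  }

  runs <- label_runs(lab)

  centroid <- function(i0, i1) {
    idx <- i0:i1
    c(mean(trace$x_deg[idx]), mean(trace$y_deg[idx]))
  }

  ## merge adjacent fixations: separation shorter than merge_max_ms and
  ## centroids closer than merge_max_deg; intervening samples join
  repeat {
    fix <- which(runs$label == "fixation")
    merged <- FALSE
    if (length(fix) >= 2) {
      for (j in seq_len(length(fix) - 1L)) {
        a <- fix[j]; b <- fix[j + 1L]
        sep_ms <- t[runs$start[b]] - (t[runs$end[a]] + dt)
        if (sep_ms >= cfg$merge_max_ms) next
        ca <- centroid(runs$start[a], runs$end[a])
        cb <- centroid(runs$start[b], runs$end[b])
        if (sqrt(sum((ca - cb)^2)) >= cfg$merge_max_deg) next
        runs$end[a] <- runs$end[b]
        runs <- runs[-((a + 1L):b), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  ## drop short fixations
  dur <- t[runs$end] - t[runs$start] + dt
  short <- runs$label == "fixation" & dur < cfg$min_fixation_ms
  runs$label[short] <- "gap"

  ## coalesce adjacent same-label runs created by merging/dropping
  if (nrow(runs) > 1) {
    keep <- c(TRUE, runs$label[-1] != runs$label[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(label = runs$label[keep],
                       start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max),
                       stringsAsFactors = FALSE)
  }

  out <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    kind <- runs$label[k]
    idx <- i0:i1
    if (kind == "fixation") {
      cc <- centroid(i0, i1)
      data.frame(kind = kind, onset_ms = t[i0], offset_ms = t[i1] + dt,
                 x_deg = cc[1], y_deg = cc[2], peak_vel_dps = NA_real_)
    } else if (kind == "saccade") {
      pv <- suppressWarnings(max(velocity[idx], na.rm = TRUE))
      if (!is.finite(pv)) pv <- NA_real_
      data.frame(kind = kind, onset_ms = t[i0], offset_ms = t[i1] + dt,
                 x_deg = NA_real_, y_deg = NA_real_, peak_vel_dps = pv)
    } else {
      data.frame(kind = "gap", onset_ms = t[i0], offset_ms = t[i1] + dt,
                 x_deg = NA_real_, y_deg = NA_real_, peak_vel_dps = NA_real_)
    }
  })
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' One-shot I-VT event detection
#'
#' Convenience wrapper running [preprocess_gaze()], [gaze_velocity()] and
#' [classify_events()].
#'
#' @inheritParams preprocess_gaze
#' @return event data frame (see [classify_events()]).
#' @export
detect_events <- function(stream, cfg = detection_config()) {
  trace <- preprocess_gaze(stream, cfg)
  v <- gaze_velocity(trace, cfg)
  classify_events(trace, v, cfg)
}
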