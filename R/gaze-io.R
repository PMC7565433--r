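## Gaze stream container and flat-file formats.
##
## All angles are degrees of visual angle in a screen-centered frame
## (x rightward positive, y upward positive); all times are ms from stream
## start. Trial logs reference the same clock.

SCREEN_HALF_W <- 22.75
SCREEN_HALF_H <- 13.38

#' Construct a binocular gaze stream
#'
#' A `gaze_stream` is a data frame of timestamped binocular samples with
#' per-eye validity flags. Invalid samples carry `NA` positions. Timestamps
#' must be strictly increasing and valid positions must lie on the screen
#' (+/-22.75 deg horizontally, +/-13.38 deg vertically).
#'
#' @param time_ms numeric timestamps, ms.
#' @param lx,ly,rx,ry per-eye gaze positions, degrees of visual angle.
#' @param l_valid,r_valid logical validity flags.
#' @return a `data.frame` of class `gaze_stream` with columns
#'   `time_ms, lx_deg, ly_deg, rx_deg, ry_deg, l_valid, r_valid`.
#' @export
gaze_stream <- function(time_ms, lx, ly, rx, ry, l_valid, r_valid) {
  s <- data.frame(time_ms = as.numeric(time_ms),
                  lx_deg = as.numeric(lx), ly_deg = as.numeric(ly),
                  rx_deg = as.numeric(rx), ry_deg = as.numeric(ry),
                  l_valid = as.logical(l_valid), r_valid = as.logical(r_valid))
  s$lx_deg[!s$l_valid] <- NA_real_
  s$ly_deg[!s$l_valid] <- NA_real_
  s$rx_deg[!s$r_valid] <- NA_real_
  s$ry_deg[!s$r_valid] <- NA_real_
  validate_gaze_stream(s)
  class(s) <- c("gaze_stream", "data.frame")
  s
}

validate_gaze_stream <- function(s, where = "gaze stream") {
  if (nrow(s) == 0) return(invisible(s))
  dt <- diff(s$time_ms)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    fail("%s: timestamps not strictly increasing at row %d", where, bad)
  }
  for (eye in list(c("lx_deg", "ly_deg", "l_valid"),
                   c("rx_deg", "ry_deg", "r_valid"))) {
    v <- s[[eye[3]]]
    x <- s[[eye[1]]][v]; y <- s[[eye[2]]][v]
    if (any(is.na(x)) || any(is.na(y)))
      fail("%s: valid samples with missing %s positions", where, eye[1])
    if (any(abs(x) > SCREEN_HALF_W + 1e-9) || any(abs(y) > SCREEN_HALF_H + 1e-9))
      fail("%s: valid gaze positions off screen", where)
  }
  invisible(s)
}

provenance_header <- function(what, config = NULL) {
  ver <- as.character(utils::packageVersion("iowattn"))
  # config hash: weighted sum of char codes of the serialized config, hex-coded
  hash <- if (is.null(config)) "none" else {
    txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
    sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 4294967296)
  }
  sprintf("# iowattn %s %s config=%s", ver, what, hash)
}

#' Read and write gaze CSV files
#'
#' The gaze dialect is a CSV with header
#' `time_ms,lx_deg,ly_deg,rx_deg,ry_deg,l_valid,r_valid`; invalid samples
#' carry empty position fields. Lines starting with `#` are provenance
#' comments and are skipped on read. `write_gaze()` then `read_gaze()` is
#' lossless.
#'
#' @param path file path.
#' @param stream a [gaze_stream()].
#' @return `read_gaze()` returns a `gaze_stream`; `write_gaze()` returns
#'   `path` invisibly.
#' @export
read_gaze <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(rep("numeric", 5), "logical", "logical"),
                       na.strings = "")
  need <- c("time_ms", "lx_deg", "ly_deg", "rx_deg", "ry_deg", "l_valid", "r_valid")
  if (!identical(names(d), need))
    fail("%s: expected gaze header %s", path, paste(need, collapse = ","))
  if (nrow(d) > 0) {
    dt <- diff(d$time_ms)
    if (any(dt <= 0))
      fail("%s: time goes backwards at data line %d", path, which(dt <= 0)[1] + 1L)
  }
  s <- gaze_stream(d$time_ms, d$lx_deg, d$ly_deg, d$rx_deg, d$ry_deg,
                   d$l_valid, d$r_valid)
  s
}

#' @rdname read_gaze
#' @export
write_gaze <- function(stream, path) {
  validate_gaze_stream(stream)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("gaze"), con)
  out <- stream
  class(out) <- "data.frame"
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

IOWA_CONDITIONS <- c("valid", "invalid", "double", "tone", "no_cue")
STM_CONDITIONS <- c("change", "no_change")

#' Read and write trial-log TSV files
#'
#' IOWA trial logs have columns
#' `trial_id, condition, target_side, cue_onset_ms, target_onset_ms`;
#' STM trial logs have
#' `trial_id, condition, set_size, test_onset_ms, changed_aoi` plus the AOI
#' slots used on the trial (`aois`, comma-separated indices 1-4). Condition
#' vocabularies are closed and validated on read.
#'
#' @param path file path.
#' @param log a trial-log data frame.
#' @param kind `"iowa"` or `"stm"`.
#' @return `read_trial_log()` returns the trial-log data frame.
#' @export
read_trial_log <- function(path, kind = c("iowa", "stm")) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vocab <- if (kind == "iowa") IOWA_CONDITIONS else STM_CONDITIONS
  bad <- setdiff(unique(d$condition), vocab)
  if (length(bad))
    fail("%s: unknown condition label(s): %s", path, paste(bad, collapse = ", "))
  if (kind == "iowa") {
    need <- c("trial_id", "condition", "target_side", "cue_onset_ms", "target_onset_ms")
    if (!all(need %in% names(d))) fail("%s: missing trial-log columns", path)
    if (any(d$target_onset_ms <= d$cue_onset_ms))
      fail("%s: target onset not after cue onset", path)
  } else {
    need <- c("trial_id", "condition", "set_size", "test_onset_ms", "changed_aoi", "aois")
    if (!all(need %in% names(d))) fail("%s: missing STM trial-log columns", path)
    if (any(d$set_size < 1 | d$set_size > 4))
      fail("%s: set size outside 1-4", path)
  }
  d
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("trial-log"), con)
  utils::write.table(log, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write ocular-event TSV files
#'
#' Events are written as `kind, onset_ms, offset_ms, x_deg, y_deg,
#' peak_vel_dps` (centroids for fixations, peak velocity for saccades).
#'
#' @param path file path.
#' @param events an event data frame as produced by [detect_events()].
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("kind", "onset_ms", "offset_ms", "x_deg", "y_deg", "peak_vel_dps")
  if (!all(need %in% names(d))) fail("%s: missing event columns", path)
  d
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("events"), con)
  utils::write.table(events, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
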