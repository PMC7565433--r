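## Shared fixtures and independent oracles for the test suite.

SIX <- c("facilitation", "interference", "competition",
         "baseline_error", "task_error", "mean_srt")

DT300 <- 1000 / 300

## Build a clean binocular stream from a cyclopean path (both eyes identical).
make_stream <- function(t, x, y = rep(0, length(t)), valid = rep(TRUE, length(t))) {
  gaze_stream(t, x, y, x, y, valid, valid)
}

## ---------------------------------------------------------------------------
## Brute-force I-VT labeler: per-sample state machine applying the same rules
## as classify_events (threshold, fixation merging, minimum duration) by
## explicit scanning, independent of the run-length implementation.
brute_force_ivt <- function(trace, vel, cfg = detection_config()) {
  n <- nrow(trace)
  t <- trace$time_ms
  dt <- stats::median(diff(t))
  lab <- character(n)
  for (i in seq_len(n)) {
    if (!trace$valid[i]) { lab[i] <- "gap"; next }
    if (!is.na(vel[i])) {
      lab[i] <- if (vel[i] >= cfg$saccade_threshold_dps) "saccade" else "fixation"
    } else lab[i] <- "defer"
  }
  ## deferred samples take the nearest defined label within their valid span
  span <- cumsum(!trace$valid)
  for (i in which(lab == "defer")) {
    best <- NA; bestd <- Inf
    for (j in seq_len(n)) {
      if (lab[j] %in% c("fixation", "saccade") && span[j] == span[i] &&
          abs(j - i) < bestd) { bestd <- abs(j - i); best <- j }
    }
    lab[i] <- if (is.na(best)) "fixation" else lab[best]
  }
  ## collect events by scanning
  events <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && lab[j + 1] == lab[i]) j <- j + 1
    events[[length(events) + 1]] <- list(kind = lab[i], from = i, to = j)
    i <- j + 1
  }
  centroid <- function(e) c(mean(trace$x_deg[e$from:e$to]),
                            mean(trace$y_deg[e$from:e$to]))
  ## merge pass, repeated until stable
  repeat {
    done <- TRUE
    k <- 1
    while (k < length(events)) {
      a <- events[[k]]
      if (a$kind != "fixation") { k <- k + 1; next }
      m <- k + 1
      while (m <= length(events) && events[[m]]$kind != "fixation") m <- m + 1
      if (m > length(events)) break
      b <- events[[m]]
      sep <- t[b$from] - (t[a$to] + dt)
      dd <- sqrt(sum((centroid(a) - centroid(b))^2))
      if (sep < cfg$merge_max_ms && dd < cfg$merge_max_deg) {
        events[[k]] <- list(kind = "fixation", from = a$from, to = b$to)
        events <- events[-((k + 1):m)]
        done <- FALSE
      } else k <- k + 1
    }
    if (done) break
  }
  ## discard short fixations
  for (k in seq_along(events)) {
    e <- events[[k]]
    if (e$kind == "fixation" && (t[e$to] - t[e$from] + dt) < cfg$min_fixation_ms)
      events[[k]]$kind <- "gap"
  }
  ## coalesce same-kind neighbours
  out <- list()
  for (e in events) {
    L <- length(out)
    if (L && out[[L]]$kind == e$kind) out[[L]]$to <- e$to
    else out[[L + 1]] <- e
  }
  do.call(rbind, lapply(out, function(e)
    data.frame(kind = e$kind, onset_ms = t[e$from], offset_ms = t[e$to] + dt)))
}

## A random synthetic trace: a few fixation plateaus joined by steps, with
## optional gaps and mild noise. Returns list(stream, cfg-ready).
random_trace <- function(seed) {
  set.seed(seed)
  n_seg <- sample(2:5, 1)
  pos <- cbind(runif(n_seg, -15, 15), runif(n_seg, -8, 8))
  durs <- sample(seq(80, 400, by = 20), n_seg, replace = TRUE)
  t <- numeric(0); x <- numeric(0); y <- numeric(0)
  cur <- 0
  for (k in seq_len(n_seg)) {
    tk <- seq(cur, cur + durs[k] - DT300 / 2, by = DT300)
    t <- c(t, tk)
    x <- c(x, rep(pos[k, 1], length(tk)))
    y <- c(y, rep(pos[k, 2], length(tk)))
    cur <- cur + durs[k]
  }
  x <- x + rnorm(length(x), 0, 0.05)
  y <- y + rnorm(length(y), 0, 0.05)
  valid <- rep(TRUE, length(t))
  if (runif(1) < 0.5) {
    g0 <- sample(seq_along(t), 1)
    valid[g0:min(g0 + sample(5:40, 1), length(t))] <- FALSE
  }
  make_stream(t, pmin(pmax(x, -22), 22), pmin(pmax(y, -13), 13), valid)
}

## ---------------------------------------------------------------------------
## Brute-force marginal multivariate-normal log-likelihood of a
## random-intercept model at given parameters.
lmm_loglik_brute <- function(data, beta, X, sigma_b, sigma_e) {
  mu <- as.vector(X %*% beta)
  ll <- 0
  for (s in unique(data$subject)) {
    idx <- which(data$subject == s)
    m <- length(idx)
    V <- diag(sigma_e^2, m) + matrix(sigma_b^2, m, m)
    r <- data$value[idx] - mu[idx]
    ch <- chol(V)
    z <- backsolve(ch, r, transpose = TRUE)
    ll <- ll - 0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

growth_design_matrix <- function(data, formula) {
  if (formula == "m1") return(cbind(1, data$age_code))
  hf <- as.numeric(data$phenotype == "high_flexible")
  hr <- as.numeric(data$phenotype == "high_reactive")
  cbind(1, data$age_code, hf, hr, data$age_code * hf, data$age_code * hr)
}

## balanced random growth dataset with guaranteed non-empty profile cells
random_growth_data <- function(seed, n_per = c(8, 8, 4), beta = rep(0, 6),
                               sigma_b = 1, sigma_e = 1) {
  set.seed(seed)
  phen <- rep(c("low_reactive", "high_flexible", "high_reactive"), n_per)
  n <- length(phen)
  d <- expand.grid(subject = seq_len(n), age_code = 0:2)
  d$phenotype <- phen[d$subject]
  X <- growth_design_matrix(d, "m2")
  b <- rnorm(n, 0, sigma_b)
  d$value <- as.vector(X %*% beta) + b[d$subject] + rnorm(nrow(d), 0, sigma_e)
  d[order(d$subject, d$age_code), ]
}

## ---------------------------------------------------------------------------
## Direct sum-of-squares computation for the 2x4 within-subject ANOVA
## (balanced, complete cells), independent of aov().
rm_anova_brute <- function(cells, measure) {
  d <- cells
  d$value <- d[[measure]]
  subj <- factor(d$subject); cond <- factor(d$condition); size <- factor(d$set_size)
  N <- nrow(d); a <- nlevels(cond); b <- nlevels(size); s <- nlevels(subj)
  g <- mean(d$value)
  m_s <- tapply(d$value, subj, mean)
  m_a <- tapply(d$value, cond, mean)
  m_b <- tapply(d$value, size, mean)
  m_ab <- tapply(d$value, list(cond, size), mean)
  m_sa <- tapply(d$value, list(subj, cond), mean)
  m_sb <- tapply(d$value, list(subj, size), mean)
  ss_a <- b * s * sum((m_a - g)^2)
  ss_b <- a * s * sum((m_b - g)^2)
  ss_ab <- s * sum((m_ab - outer(m_a - g, m_b - g, "+") - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_sa <- b * sum((m_sa - outer(m_s - g, m_a - g, "+") - g)^2)
  ss_sb <- a * sum((m_sb - outer(m_s - g, m_b - g, "+") - g)^2)
  ss_tot <- sum((d$value - g)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  F_a <- (ss_a / (a - 1)) / (ss_sa / ((a - 1) * (s - 1)))
  F_b <- (ss_b / (b - 1)) / (ss_sb / ((b - 1) * (s - 1)))
  F_ab <- (ss_ab / ((a - 1) * (b - 1))) / (ss_sab / ((a - 1) * (b - 1) * (s - 1)))
  list(F = c(condition = F_a, set_size = F_b, interaction = F_ab),
       ss = c(ss_a, ss_b, ss_ab), ss_err = c(ss_sa, ss_sb, ss_sab))
}

## fixation/saccade event-list builder for scoring tests
ev_row <- function(kind, onset, offset, x = NA, y = NA, pv = NA) {
  data.frame(kind = kind, onset_ms = onset, offset_ms = offset,
             x_deg = x, y_deg = y, peak_vel_dps = pv)
}
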