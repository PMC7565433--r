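## Latent profile analysis: diagonal-covariance Gaussian mixtures fit by EM
## on the observed-data likelihood. Each row's component density is the
## product of univariate normal densities over its *observed* score columns
## only, the maximum-likelihood treatment of ignorable missingness; the
## M-step weights each coordinate's sufficient statistics by the
## responsibilities of the rows observing that coordinate.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## k-means++-style seeding on the complete (no-NA) columns, standardized
seed_centers <- function(x, K) {
  comp <- which(colSums(is.na(x)) == 0)
  if (!length(comp)) comp <- which.min(colSums(is.na(x)))
  z <- scale(x[, comp, drop = FALSE])
  z[is.na(z)] <- 0
  n <- nrow(z)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums((z - z[rep(centers[1], n), , drop = FALSE])^2)
    for (k in 2:K) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[k] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums((z - z[rep(centers[k], n), , drop = FALSE])^2))
    }
  }
  ## hard-assign to nearest center
  dist_to <- vapply(centers, function(c0)
    rowSums((z - z[rep(c0, n), , drop = FALSE])^2), numeric(n))
  max.col(-matrix(dist_to, n), ties.method = "first")
}

## component log-densities over observed coordinates: n x K matrix
obs_logdens <- function(x, mask, mu, sigma2) {
  n <- nrow(x); K <- nrow(mu)
  x0 <- x; x0[!mask] <- 0
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lp <- -0.5 * (log(2 * pi * rep(sigma2[k, ], each = n)) +
                  (x0 - rep(mu[k, ], each = n))^2 / rep(sigma2[k, ], each = n))
    lp[!mask] <- 0
    out[, k] <- rowSums(lp)
  }
  out
}

em_once <- function(x, mask, K, w, mu, sigma2, floor_j, tol, max_iter) {
  n <- nrow(x)
  x0 <- x; x0[!mask] <- 0
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- obs_logdens(x, mask, mu, sigma2)
    lj <- sweep(ld, 2, log(w), "+")
    ll_row <- logsumexp_rows(lj)
    ll <- sum(ll_row)
    trace <- c(trace, ll)
    if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev)))
      warning("fit_mixture: log-likelihood decreased (numerical)")
    if (it > 1 && (ll - ll_prev) <= tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    r <- exp(lj - ll_row)
    w <- colMeans(r)
    w <- pmax(w, 1e-12); w <- w / sum(w)
    for (k in seq_len(K)) {
      rk <- r[, k] * mask                 # n x d, zero where unobserved
      denom <- colSums(rk)
      denom[denom < 1e-12] <- 1e-12
      mu[k, ] <- colSums(rk * x0) / denom
      sigma2[k, ] <- pmax(colSums(rk * (x0 - rep(mu[k, ], each = n))^2) / denom,
                          floor_j)
    }
  }
  ld <- obs_logdens(x, mask, mu, sigma2)
  lj <- sweep(ld, 2, log(w), "+")
  ll_row <- logsumexp_rows(lj)
  list(w = w, mu = mu, sigma2 = sigma2, logLik = sum(ll_row),
       post = exp(lj - ll_row), n_iter = length(trace), trace = trace,
       converged = converged)
}

#' Fit a K-profile latent profile model
#'
#' EM for a mixture of K diagonal-covariance Gaussians over the score
#' columns, on the observed-data likelihood (rows with missing scores
#' contribute the density of their observed coordinates only). The best of
#' `n_starts` k-means++-seeded random initializations by final log-likelihood
#' is returned. Parameter count is `K*d` means + `K*d` variances + `K-1`
#' weights; AIC and BIC follow [information_criteria()]. Component variances
#' are floored at `var_floor_frac` times the pooled column variance, a guard
#' against degenerate single-row spikes (a mild deviation from unconstrained
#' maximum likelihood).
#'
#' @param x numeric matrix or data frame of indicators (rows = subjects);
#'   `NA` entries allowed.
#' @param K number of profiles (>= 1).
#' @param n_starts random initializations.
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param var_floor_frac variance floor as a fraction of pooled column
#'   variance.
#' @return object of class `lpa_fit`: weights, means, variances, `logLik`,
#'   `AIC`, `BIC`, `entropy`, posteriors, hard `assignment`, `n_params`,
#'   `converged`, iteration trace.
#' @export
fit_mixture <- function(x, K, n_starts = 32, seed = NULL, tol = 1e-8,
                        max_iter = 1000, var_floor_frac = 1e-4) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (K < 1) fail("fit_mixture: K must be >= 1")
  if (K > n) fail("fit_mixture: K (%d) exceeds number of rows (%d)", K, n)
  if (any(rowSums(!is.na(x)) == 0)) fail("fit_mixture: row with no observed scores")
  mask <- !is.na(x)
  floor_j <- vapply(seq_len(d), function(j)
    var_floor_frac * stats::var(x[mask[, j], j]), numeric(1))
  floor_j[!is.finite(floor_j) | floor_j <= 0] <- 1e-10
  if (!is.null(seed)) set.seed(seed)

  init_from_assign <- function(hard) {
    mu <- matrix(0, K, d); s2 <- matrix(0, K, d)
    pooled <- vapply(seq_len(d), function(j) stats::var(x[mask[, j], j]), numeric(1))
    for (k in seq_len(K)) {
      idx <- which(hard == k)
      for (j in seq_len(d)) {
        v <- x[idx, j]; v <- v[!is.na(v)]
        mu[k, j] <- if (length(v)) mean(v) else mean(x[mask[, j], j])
        s2[k, j] <- if (length(v) > 1) stats::var(v) else pooled[j]
      }
    }
    s2 <- pmax(s2, rep(floor_j, each = K))
    w <- tabulate(hard, K) / n
    w <- pmax(w, 1e-3); w <- w / sum(w)
    list(w = w, mu = mu, s2 = s2)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    hard <- if (K == 1) rep(1L, n) else seed_centers(x, K)
    ini <- init_from_assign(hard)
    fit <- em_once(x, mask, K, ini$w, ini$mu, ini$s2, floor_j, tol, max_iter)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
    if (K == 1) break                    # closed form; no restarts needed
  }

  n_params <- 2 * K * d + (K - 1)
  ic <- information_criteria(best$logLik, n_params, n)
  ent <- if (K >= 2) relative_entropy(best$post) else NA_real_
  assignment <- max.col(best$post, ties.method = "first")
  structure(list(K = K, weights = best$w, means = best$mu,
                 variances = best$sigma2, logLik = best$logLik,
                 AIC = ic[["AIC"]], BIC = ic[["BIC"]], entropy = ent,
                 posteriors = best$post, assignment = assignment,
                 n_params = n_params, converged = best$converged,
                 n_iter = best$n_iter, logLik_trace = best$trace,
                 var_floor = floor_j, n = n, d = d,
                 colnames = colnames(x)),
            class = "lpa_fit")
}

#' @export
print.lpa_fit <- function(x, ...) {
  cat(sprintf("Latent profile model: K = %d, n = %d, logLik = %.3f\n",
              x$K, x$n, x$logLik))
  cat(sprintf("AIC = %.2f  BIC = %.2f  entropy = %s  converged = %s\n",
              x$AIC, x$BIC,
              if (is.na(x$entropy)) "-" else sprintf("%.3f", x$entropy),
              x$converged))
  cat("profile shares (%):",
      paste(percent1(tabulate(x$assignment, x$K) / x$n), collapse = " / "), "\n")
  invisible(x)
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - sum(-p*log(p)) / (n*log(K))`, with `0*log(0) = 0`; 1 for one-hot
#' posteriors (perfectly crisp assignment), 0 for uniform posteriors.
#' Undefined for K = 1.
#'
#' @param posteriors n x K matrix of posterior probabilities (rows sum to 1).
#' @return scalar in `[0, 1]`.
#' @export
relative_entropy <- function(posteriors) {
  p <- as.matrix(posteriors)
  K <- ncol(p)
  if (K < 2) fail("relative_entropy: undefined for K = 1")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    fail("relative_entropy: posterior rows must sum to 1")
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 - sum(-plogp) / (nrow(p) * log(K))
}

#' Hard-assignment profile shares
#'
#' @param assignment vector of hard profile labels.
#' @return list with `shares_pct` (percent per profile, 1 decimal, as the
#'   selection table prints them) and `smallest_pct`.
#' @export
profile_shares <- function(assignment) {
  tab <- table(assignment)
  shares <- percent1(as.numeric(tab) / length(assignment))
  names(shares) <- names(tab)
  list(shares_pct = shares, smallest_pct = min(shares))
}

#' Model-selection table over a range of profile counts
#'
#' Fits one latent profile model per K and tabulates log-likelihood, AIC,
#' BIC, relative entropy and the smallest-profile share.
#'
#' @inheritParams fit_mixture
#' @param K_range integer vector of profile counts.
#' @return data frame with one row per K; fitted models in
#'   `attr(, "fits")`.
#' @export
model_selection_table <- function(x, K_range = 1:5, n_starts = 32,
                                  seed = NULL, tol = 1e-8, max_iter = 1000) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(K_range, function(k)
    fit_mixture(x, k, n_starts = n_starts, tol = tol, max_iter = max_iter))
  tab <- data.frame(
    K = K_range,
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    entropy = vapply(fits, `[[`, numeric(1), "entropy"),
    smallest_profile_pct = vapply(fits, function(f)
      profile_shares(f$assignment)$smallest_pct, numeric(1)))
  attr(tab, "fits") <- fits
  tab
}

#' Draw from a fitted latent profile model
#'
#' @param n number of rows.
#' @param fit an `lpa_fit`.
#' @return numeric matrix with `n` rows.
#' @export
simulate_lpa <- function(n, fit) {
  comp <- sample.int(fit$K, n, replace = TRUE, prob = fit$weights)
  out <- fit$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * fit$d), n) *
    sqrt(fit$variances[comp, , drop = FALSE])
  colnames(out) <- fit$colnames
  out
}

#' Parametric-bootstrap likelihood-ratio test for K vs K-1 profiles
#'
#' Simulates `B` datasets from the fitted (K-1)-profile model, refits both
#' models on each, and returns the bootstrap p-value of the observed
#' `2*(logLik_K - logLik_{K-1})`. This is a standard parametric-bootstrap
#' LRT, not the ad-hoc analytic approximation some commercial LPA software
#' reports.
#'
#' @inheritParams fit_mixture
#' @param B bootstrap replicates.
#' @param n_starts restarts per (re)fit.
#' @return list with `LR`, `p_value`, `null_LR` draws.
#' @export
bootstrap_lrt <- function(x, K, B = 50, n_starts = 8, seed = NULL) {
  if (K < 2) fail("bootstrap_lrt: K must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  f0 <- fit_mixture(x, K - 1, n_starts = n_starts)
  f1 <- fit_mixture(x, K, n_starts = n_starts)
  LR <- 2 * (f1$logLik - f0$logLik)
  n <- nrow(as.matrix(x))
  null_LR <- vapply(seq_len(B), function(b) {
    xb <- simulate_lpa(n, f0)
    2 * (fit_mixture(xb, K, n_starts = n_starts)$logLik -
         fit_mixture(xb, K - 1, n_starts = n_starts)$logLik)
  }, numeric(1))
  list(LR = LR, p_value = (1 + sum(null_LR >= LR)) / (B + 1), null_LR = null_LR)
}
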