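## Random-intercept growth models fit by maximum likelihood.
##
## Marginally, each subject's rows are multivariate normal with covariance
## sigma_e^2 * (I + theta * J), theta = sigma_b^2 / sigma_e^2. The
## log-likelihood is profiled over theta: at each theta the GLS fixed
## effects and sigma_e^2 are closed-form, leaving a smooth 1-D criterion in
## log(theta) optimized deterministically. ML (not REML) is used throughout
## so that likelihood-ratio tests between models differing in fixed effects
## are valid and AIC/BIC follow df = #fixed + 2.

growth_design <- function(data, formula = c("m1", "m2")) {
  formula <- match.arg(formula)
  need <- c("subject", "age_code", "value")
  if (!all(need %in% names(data))) fail("fit_growth: missing columns")
  if (formula == "m2") {
    if (!"phenotype" %in% names(data)) fail("fit_growth: missing phenotype column")
    hf <- as.numeric(data$phenotype == "high_flexible")
    hr <- as.numeric(data$phenotype == "high_reactive")
    X <- cbind(intercept = 1, age = data$age_code,
               high_flexible = hf, high_reactive = hr,
               age_x_high_flexible = data$age_code * hf,
               age_x_high_reactive = data$age_code * hr)
    for (ph in c("high_flexible", "high_reactive", "low_reactive"))
      if (!any(data$phenotype == ph))
        fail("fit_growth: empty profile cell: %s", ph)
  } else {
    X <- cbind(intercept = 1, age = data$age_code)
  }
  X
}

## profiled quantities at a given theta
gls_at_theta <- function(theta, X, y, subj) {
  n <- length(y)
  ni <- as.vector(table(subj))
  c_i <- theta / (1 + theta * ni)            # per subject
  ## X'WX = X'X - sum_i c_i (X_i'1)(1'X_i); same for X'Wy
  Sx <- rowsum(X, subj)                      # subject sums of columns
  Sy <- rowsum(y, subj)
  XtX <- crossprod(X) - crossprod(Sx * sqrt(c_i))
  Xty <- crossprod(X, y) - crossprod(Sx, Sy * c_i)
  beta <- solve(XtX, Xty)
  r <- y - X %*% beta
  Sr <- rowsum(as.vector(r), subj)
  rss <- sum(r^2) - sum(c_i * Sr^2)
  logdet <- sum(log1p(theta * ni))
  sigma2e <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2e) + logdet + n)
  list(beta = beta, sigma2e = sigma2e, logLik = ll, XtX = XtX)
}

#' Fit a random-intercept growth model
#'
#' Model `m1` regresses the score on age only (visit codes 0/1/2); `m2` adds
#' phenotype main effects and age-by-phenotype interactions, with low
#' reactive as the reference profile. Both include a subject random
#' intercept and are estimated by full maximum likelihood (profiled over the
#' variance ratio; bounded deterministic 1-D search on the log scale,
#' boundary theta = 0 checked explicitly).
#'
#' @param data data frame with columns `subject`, `age_code` (0/1/2),
#'   `value`, and `phenotype` for `m2`.
#' @param formula `"m1"` (time only) or `"m2"` (time-by-profile).
#' @return object of class `growth_fit`: `coefficients`, `se`,
#'   `sigma_b`, `sigma_e`, `logLik`, `df`, `AIC`, `BIC`, `n_obs`,
#'   `n_subjects`, `formula`.
#' @export
fit_growth <- function(data, formula = c("m1", "m2")) {
  formula <- match.arg(formula)
  data <- data[!is.na(data$value), , drop = FALSE]
  X <- growth_design(data, formula)
  y <- data$value
  if (stats::var(y) == 0) fail("fit_growth: zero-variance response")
  subj <- factor(data$subject)
  if (sum(table(subj) >= 2) < 2)
    fail("fit_growth: need >= 2 subjects with >= 2 visits")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) fail("fit_growth: singular fixed-effect design")

  obj <- function(lt) -gls_at_theta(exp(lt), X, y, subj)$logLik
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-10)
  theta <- exp(opt$minimum)
  cand <- gls_at_theta(theta, X, y, subj)
  at0 <- gls_at_theta(0, X, y, subj)
  if (at0$logLik >= cand$logLik) {        # boundary: no between-subject variance
    theta <- 0
    cand <- at0
  }
  beta <- as.vector(cand$beta)
  names(beta) <- colnames(X)
  vc <- cand$sigma2e * solve(cand$XtX)
  se <- sqrt(diag(vc))
  names(se) <- colnames(X)
  df <- ncol(X) + 2
  ic <- information_criteria(cand$logLik, df, length(y))
  structure(list(coefficients = beta, se = se,
                 sigma_b = sqrt(theta * cand$sigma2e),
                 sigma_e = sqrt(cand$sigma2e),
                 logLik = cand$logLik, df = df,
                 AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                 n_obs = length(y), n_subjects = nlevels(subj),
                 formula = formula),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Random-intercept growth model (%s), ML\n", x$formula))
  cat(sprintf("n_obs = %d, subjects = %d, logLik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$n_obs, x$n_subjects, x$logLik, x$AIC, x$BIC))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat(sprintf("sigma_b = %.3f, sigma_e = %.3f\n", x$sigma_b, x$sigma_e))
  invisible(x)
}

#' Likelihood-ratio comparison of the time-only and time-by-profile models
#'
#' Fits `m1` and `m2` on the same rows and reports
#' `LR = 2*(logLik_m2 - logLik_m1)` against a chi-square with 4 df.
#' Alternatively pass two log-likelihoods directly via `logLik_m1` /
#' `logLik_m2` (the models' printed fits) to reproduce the arithmetic.
#'
#' @param data growth dataset (see [fit_growth()]); ignored when both
#'   log-likelihoods are supplied.
#' @param logLik_m1,logLik_m2 optional log-likelihoods of pre-computed fits.
#' @param df_diff degrees-of-freedom difference (4: two main effects plus
#'   two interactions).
#' @return object of class `growth_comparison` with the two fits (when
#'   computed), `LR`, `df_diff`, `p_value`.
#' @export
compare_models <- function(data = NULL, logLik_m1 = NULL, logLik_m2 = NULL,
                           df_diff = 4) {
  if (is.null(logLik_m1) || is.null(logLik_m2)) {
    if (is.null(data)) fail("compare_models: supply data or two log-likelihoods")
    f1 <- fit_growth(data, "m1")
    f2 <- fit_growth(data, "m2")
    logLik_m1 <- f1$logLik
    logLik_m2 <- f2$logLik
  } else {
    f1 <- f2 <- NULL
  }
  LR <- 2 * (logLik_m2 - logLik_m1)
  structure(list(m1 = f1, m2 = f2, logLik_m1 = logLik_m1,
                 logLik_m2 = logLik_m2, LR = LR, df_diff = df_diff,
                 p_value = stats::pchisq(LR, df_diff, lower.tail = FALSE)),
            class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf("m1 vs m2: L.Ratio = %.2f, df = %d, p %s\n", x$LR, x$df_diff,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}
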