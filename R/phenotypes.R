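## Bundled phenotype parameter sets.
##
## Three empirically motivated infant attentional phenotypes -- high flexible
## (fast, selective, adaptive orienting), low reactive (slow, cue-insensitive
## orienting, low error) and high reactive (fast, unselective orienting, high
## error) -- each described by means and SDs of the six attention scores at
## 5, 8 and 11 months, with cohort mixing weights 0.55 / 0.396 / 0.054.

PHENOTYPES <- c("high_flexible", "low_reactive", "high_reactive")

.phenotype_norms <- local({
  g <- function(age, phen, fac, fac_sd, int, int_sd, comp, comp_sd,
                berr, berr_sd, terr, terr_sd, srt, srt_sd)
    data.frame(age_mo = age, phenotype = phen,
               facilitation = fac, facilitation_sd = fac_sd,
               interference = int, interference_sd = int_sd,
               competition = comp, competition_sd = comp_sd,
               baseline_error = berr, baseline_error_sd = berr_sd,
               task_error = terr, task_error_sd = terr_sd,
               mean_srt = srt, mean_srt_sd = srt_sd,
               stringsAsFactors = FALSE)
  rbind(
    g(5, "high_flexible", 0.356, 0.307, 0.068, 0.699, 0.135, 0.350,
      0.065, 0.070, 0.411, 0.157, 283.787, 77.912),
    g(5, "high_reactive", 0.449, 0.502, 0.618, 0.326, -0.060, 0.410,
      0.091, 0.053, 0.611, 0.152, 259.137, 89.947),
    g(5, "low_reactive", 0.248, 0.252, 0.175, 0.291, 0.196, 0.168,
      0.062, 0.066, 0.283, 0.201, 310.570, 69.786),
    g(8, "high_flexible", 0.581, 0.321, 0.328, 0.865, 0.283, 0.208,
      0.062, 0.067, 0.544, 0.118, 243.302, 59.068),
    g(8, "high_reactive", 0.563, 0.187, 0.705, 0.599, 0.730, 0.782,
      0.030, 0.026, 0.586, 0.143, 267.673, 110.289),
    g(8, "low_reactive", 0.315, 0.365, 0.223, 0.308, 0.202, 0.239,
      0.047, 0.058, 0.361, 0.213, 314.393, 106.944),
    g(11, "high_flexible", 0.725, 0.297, -0.013, 0.386, 0.328, 0.292,
      0.066, 0.053, 0.593, 0.087, 204.490, 38.350),
    g(11, "high_reactive", 0.756, 0.256, 1.725, 0.568, 0.267, 0.250,
      0.059, 0.075, 0.641, 0.062, 283.817, 32.826),
    g(11, "low_reactive", 0.318, 0.160, 0.160, 0.327, 0.254, 0.200,
      0.042, 0.043, 0.321, 0.128, 310.912, 72.211))
})

#' Reference attention-score distributions by phenotype and age
#'
#' Means and standard deviations of the six attention scores for the three
#' bundled attentional phenotypes at 5, 8 and 11 months, together with the
#' default cohort mixing weights (high flexible 0.55, low reactive 0.396,
#' high reactive 0.054). These parameter sets drive the synthetic cohort and
#' session generators.
#'
#' @param age_mo optionally restrict to one visit age (5, 8 or 11).
#' @return data frame of per-phenotype score means and SDs.
#' @export
phenotype_norms <- function(age_mo = NULL) {
  d <- .phenotype_norms
  if (!is.null(age_mo)) {
    if (!age_mo %in% c(5, 8, 11)) fail("phenotype_norms: age must be 5, 8 or 11")
    d <- d[d$age_mo == age_mo, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' @rdname phenotype_norms
#' @export
phenotype_weights <- function() {
  c(high_flexible = 0.55, low_reactive = 0.396, high_reactive = 0.054)
}

## Default growth-curve coefficients (score units per visit; age coded
## 0/1/2 for 5/8/11 months, low reactive as reference level).
.growth_coefs <- local({
  m <- rbind(
    facilitation   = c(0.238,  0.029, -0.055,  0.034,  0.155,  0.130),
    interference   = c(0.219, -0.016,  0.016, -0.309, -0.039,  0.601),
    competition    = c(0.164,  0.030, -0.100, -0.179,  0.063,  0.104),
    baseline_error = c(0.070, -0.010, -0.004,  0.017,  0.010, -0.003),
    task_error     = c(0.301,  0.010,  0.037,  0.267,  0.078,  0.011),
    mean_srt       = c(309.477, 0.677, -13.147, -63.875, -40.032, 12.373))
  colnames(m) <- c("intercept", "age", "high_flexible", "high_reactive",
                   "age_x_high_flexible", "age_x_high_reactive")
  m
})

## Plausible variance-component splits per score (between-subject sd,
## residual sd), on the score's own scale; see the methods vignette.
.growth_sigmas <- rbind(
  facilitation   = c(sigma_b = 0.18, sigma_e = 0.20),
  interference   = c(sigma_b = 0.30, sigma_e = 0.35),
  competition    = c(sigma_b = 0.18, sigma_e = 0.20),
  baseline_error = c(sigma_b = 0.04, sigma_e = 0.04),
  task_error     = c(sigma_b = 0.10, sigma_e = 0.10),
  mean_srt       = c(sigma_b = 55,   sigma_e = 45))

#' Default growth-model coefficients per attention score
#'
#' Fixed-effect coefficients (intercept, age slope, phenotype offsets,
#' age-by-phenotype slopes; age coded 0/1/2 for the 5/8/11-month visits,
#' low reactive as reference) and default variance components used by
#' [simulate_growth_dataset()].
#'
#' @param score one of the six score names.
#' @return list with `beta` (named length-6 vector), `sigma_b`, `sigma_e`.
#' @export
growth_defaults <- function(score = rownames(.growth_coefs)) {
  score <- match.arg(score)
  list(beta = .growth_coefs[score, ],
       sigma_b = .growth_sigmas[score, "sigma_b"],
       sigma_e = .growth_sigmas[score, "sigma_e"])
}
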