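## Synthetic score cohorts and longitudinal growth datasets.
##
## The score generator draws the six attention scores per phenotype/age from
## independent normals at the bundled (or user-supplied) means and SDs. A
## per-subject standard-normal effect shared across visits induces
## longitudinal correlation: at every visit the value is
## mean + sd * (sqrt(icc) * u_subject + sqrt(1-icc) * noise), so the marginal
## mean/SD at each visit match the parameter table exactly while subjects
## correlate across visits with intraclass correlation `icc`.

check_params <- function(params) {
  sds <- unlist(params[, grep("_sd$", names(params))])
  if (any(sds < 0)) fail("simulate_score_cohort: sds must be non-negative")
  for (col in c("baseline_error", "task_error"))
    params[[col]] <- pmin(pmax(params[[col]], 0), 1)
  params
}

#' Simulate a cohort score table
#'
#' Assigns each subject a phenotype by the mixing weights, then draws the six
#' attention scores at each requested age from the per-phenotype normal
#' distributions. Interference is set missing completely at random at rate
#' `missing_interference` (default 7/111, the rate at which infants
#' contribute no correct invalid trials). Reproducible under `seed`.
#'
#' @param n_subjects cohort size.
#' @param ages_mo visit ages, subset of 5/8/11.
#' @param params parameter table in the layout of [phenotype_norms()].
#' @param weights named phenotype mixing weights summing to 1.
#' @param icc intraclass correlation of a score across visits.
#' @param missing_interference probability an interference score is missing.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return data frame `(subject, age_mo, age_code, phenotype, six scores)`.
#' @export
simulate_score_cohort <- function(n_subjects, ages_mo = 11,
                                  params = phenotype_norms(),
                                  weights = phenotype_weights(),
                                  icc = 0.5,
                                  missing_interference = 7 / 111,
                                  seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-8)
    fail("simulate_score_cohort: mixing weights must sum to 1")
  if (n_subjects < length(weights))
    fail("simulate_score_cohort: need at least one subject per phenotype")
  if (!all(ages_mo %in% c(5, 8, 11)) || is.unsorted(ages_mo, strictly = TRUE))
    fail("simulate_score_cohort: ages must be strictly increasing among 5, 8, 11")
  params <- check_params(params)
  if (!is.null(seed)) set.seed(seed)

  phen <- sample(names(weights), n_subjects, replace = TRUE, prob = weights)
  u <- matrix(stats::rnorm(n_subjects * length(SCORE_COLS)), n_subjects,
              dimnames = list(NULL, SCORE_COLS))
  rows <- list()
  for (a in ages_mo) {
    pa <- params[params$age_mo == a, , drop = FALSE]
    if (nrow(pa) == 0) fail("simulate_score_cohort: no parameters for age %s", a)
    idx <- match(phen, pa$phenotype)
    d <- data.frame(subject = seq_len(n_subjects), age_mo = a,
                    age_code = match(a, c(5, 8, 11)) - 1L,
                    phenotype = phen, stringsAsFactors = FALSE)
    for (sc in SCORE_COLS) {
      mu <- pa[[sc]][idx]
      sd <- pa[[paste0(sc, "_sd")]][idx]
      eps <- stats::rnorm(n_subjects)
      d[[sc]] <- mu + sd * (sqrt(icc) * u[, sc] + sqrt(1 - icc) * eps)
    }
    rows[[as.character(a)]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (missing_interference > 0) {
    miss <- stats::runif(nrow(out)) < missing_interference
    out$interference[miss] <- NA_real_
  }
  out
}

#' Simulate a longitudinal growth dataset
#'
#' Generates subject-by-visit values of one attention score under the
#' random-intercept growth model
#' `y = X beta + b_subject + e`, with `b ~ N(0, sigma_b^2)`,
#' `e ~ N(0, sigma_e^2)`, age coded 0/1/2 for the 5/8/11-month visits and
#' low reactive as reference phenotype. Earlier visits are retained with the
#' given probabilities (the final visit is always observed), producing the
#' unbalanced panels typical of infant longitudinal studies. Phenotype draws
#' are conditioned on every phenotype appearing at least once, since the
#' profile design is singular otherwise.
#'
#' @param n_subjects cohort size.
#' @param score score name selecting default coefficients, or supply `beta`.
#' @param beta named length-6 coefficient vector (see [growth_defaults()]).
#' @param sigma_b,sigma_e variance components (sds) on the score scale.
#' @param weights phenotype mixing weights.
#' @param retention probability each of the three visits is observed.
#' @param seed integer seed.
#' @return data frame `(subject, age_code, phenotype, value)`.
#' @export
simulate_growth_dataset <- function(n_subjects = 111, score = "mean_srt",
                                    beta = NULL, sigma_b = NULL, sigma_e = NULL,
                                    weights = phenotype_weights(),
                                    retention = c(69 / 111, 79 / 111, 1),
                                    seed = NULL) {
  defs <- growth_defaults(score)
  if (is.null(beta)) beta <- defs$beta
  if (is.null(sigma_b)) sigma_b <- defs$sigma_b
  if (is.null(sigma_e)) sigma_e <- defs$sigma_e
  if (!is.null(seed)) set.seed(seed)

  ## condition on a non-degenerate cohort: every phenotype must appear, or
  ## the profile design is singular (rejection draw keeps the conditional
  ## multinomial distribution)
  repeat {
    phen <- sample(names(weights), n_subjects, replace = TRUE, prob = weights)
    if (length(unique(phen)) == length(weights)) break
  }
  b <- stats::rnorm(n_subjects, 0, sigma_b)
  rows <- list()
  for (v in 0:2) {
    keep <- stats::runif(n_subjects) < retention[v + 1]
    if (!any(keep)) next
    hf <- as.numeric(phen[keep] == "high_flexible")
    hr <- as.numeric(phen[keep] == "high_reactive")
    mu <- beta[["intercept"]] + beta[["age"]] * v +
      beta[["high_flexible"]] * hf + beta[["high_reactive"]] * hr +
      beta[["age_x_high_flexible"]] * v * hf +
      beta[["age_x_high_reactive"]] * v * hr
    rows[[v + 1]] <- data.frame(subject = which(keep), age_code = v,
                                phenotype = phen[keep],
                                value = mu + b[keep] +
                                  stats::rnorm(sum(keep), 0, sigma_e),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$age_code), ]
  rownames(out) <- NULL
  out
}
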