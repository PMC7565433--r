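## small shared helpers

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2*df - 2*logLik`, `BIC = df*log(n_obs) - 2*logLik`, the maximum-
#' likelihood convention used throughout the package (mixtures and growth
#' models alike).
#'
#' @param logLik maximized log-likelihood (nats).
#' @param df number of freely estimated parameters.
#' @param n_obs number of observations entering the likelihood.
#' @return named numeric vector with elements `AIC` and `BIC`.
#' @examples
#' information_criteria(-38.277, 8, 240)
#' @export
information_criteria <- function(logLik, df, n_obs) {
  stopifnot(is.numeric(logLik), length(logLik) == 1L,
            df >= 1, n_obs >= 1)
  c(AIC = 2 * df - 2 * logLik,
    BIC = df * log(n_obs) - 2 * logLik)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), approximately 0 for independent
#' ones. Used to compare mixture hard assignments with generating labels.
#'
#' @param a,b vectors of class labels, same length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

## stop() wrapper with sprintf formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## derive a per-unit seed from a master seed, kept within 32-bit integer range
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% .Machine$integer.max)
}

## proportion helper: x/n as percent rounded the way the selection table prints
percent1 <- function(x) round(100 * x, 1)
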