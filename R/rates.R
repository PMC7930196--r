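#' Pairwise substitution-rate estimation
#'
#' The period rate estimator divides the total modern-ancient difference
#' count by the number of pairs and the period age:
#' `theta_genome = sum(d_ij) / (n * T)` per genome per year, and
#' `theta_site = theta_genome / L` per site per year. Counts are Poisson
#' under the underlying mutation model, so the confidence interval is the
#' exact (Garwood) Poisson interval on `sum(d_ij)` scaled by the exposure
#' `n * T * L`.
#'
#' @name rates
NULL

#' Period rate estimate
#'
#' @param sum_d total number of pairwise differences in the period.
#' @param n_pairs number of modern-ancient pairs compared.
#' @param T_years the period age in years (mean calibrated age of its
#'   ancient samples).
#' @param L number of sites in the denominator (default the full
#'   16,569-bp mitogenome).
#' @param conf confidence level for the Poisson interval.
#' @return an object of class `rate_estimate` with fields `theta_site`,
#'   `theta_genome`, `ci_low`, `ci_high` (per site per year), `sum_d`,
#'   `n_pairs`, `T_years`, `L`, `conf`.
#' @export
theta <- function(sum_d, n_pairs, T_years, L = MITO_LENGTH, conf = 0.95) {
  if (n_pairs < 1) {
    stop("n_pairs must be >= 1")
  }
  if (T_years <= 0) {
    stop("T_years must be > 0")
  }
  if (L < 1) {
    stop("L must be >= 1")
  }
  if (sum_d < 0) {
    stop("sum_d must be non-negative")
  }
  exposure <- n_pairs * T_years * L
  ci <- poisson_rate_ci(sum_d, exposure, conf)
  structure(list(theta_site = sum_d / exposure,
                 theta_genome = sum_d / (n_pairs * T_years),
                 ci_low = ci[[1]], ci_high = ci[[2]],
                 sum_d = sum_d, n_pairs = n_pairs, T_years = T_years,
                 L = L, conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(paste0("<rate_estimate> %.3e /site/yr (%d%% CI %.3e-%.3e), ",
                     "%.3e /genome/yr\n  sum_d = %g over %d pairs, T = %g ",
                     "yr, L = %d sites\n"),
              x$theta_site, round(100 * x$conf), x$ci_low, x$ci_high,
              x$theta_genome, x$sum_d, x$n_pairs, x$T_years, x$L))
  invisible(x)
}

#' Exact Poisson (Garwood) interval for a rate
#'
#' @param count observed event count.
#' @param exposure total exposure (the rate is `count / exposure`).
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`; `low = 0` when `count = 0`.
#' @export
poisson_rate_ci <- function(count, exposure, conf = 0.95) {
  stopifnot(count >= 0, exposure > 0)
  alpha <- 1 - conf
  low <- if (count == 0) 0 else stats::qgamma(alpha / 2, count) / exposure
  high <- stats::qgamma(1 - alpha / 2, count + 1) / exposure
  c(low = low, high = high)
}

#' Period rate from a paired period bin
#'
#' @param bin a paired `period_bin` (see [build_pairs()]).
#' @param profiles named list of all profiles.
#' @param policy an [exclusion_policy()].
#' @inheritParams theta
#' @return a `rate_estimate`.
#' @export
theta_from_bin <- function(bin, profiles, policy = exclusion_policy(),
                           L = MITO_LENGTH, conf = 0.95) {
  pd <- pair_differences(bin, profiles, policy)
  theta(sum(pd$d), nrow(pd), bin$mean_age, L = L, conf = conf)
}

#' Published germline per-site mutation rates
#'
#' The two recent pedigree-based germline mtDNA mutation-rate estimates
#' used as comparison points, in substitutions per site per year.
#'
#' @return named numeric vector `c(low = 1.30e-8, high = 1.89e-8)`.
#' @export
germline_rates <- function() {
  c(low = 1.30e-8, high = 1.89e-8)
}

#' Fold change between two rates
#'
#' @param rate_a,rate_b rates in the same units; `rate_b > 0`.
#' @return `rate_a / rate_b`.
#' @export
fold_change <- function(rate_a, rate_b) {
  if (any(rate_b == 0)) {
    stop("rate_b must be non-zero")
  }
  rate_a / rate_b
}

#' Time dependency of the substitution rate
#'
#' Ordinary least-squares regression of the per-period rate estimate on
#' the period mean age; a significantly negative slope indicates that
#' younger calibration windows yield faster apparent rates.
#'
#' @param T_years per-period mean ages (years BP).
#' @param theta_values per-period rate estimates (same units across
#'   periods).
#' @return list with `slope`, `intercept`, `r` (Pearson correlation,
#'   signed), `p_value` (two-sided, for slope != 0), and `model` (the
#'   underlying `lm` fit).
#' @export
time_dependency_regression <- function(T_years, theta_values) {
  stopifnot(length(T_years) == length(theta_values))
  if (length(T_years) < 3) {
    stop("need at least 3 periods")
  }
  if (stats::var(T_years) == 0) {
    stop("period ages are all identical; regression undefined")
  }
  fit <- stats::lm(theta_values ~ T_years)
  coefs <- summary(fit)$coefficients
  p <- if (nrow(coefs) < 2 || stats::var(theta_values) == 0) {
    1.0
  } else {
    coefs["T_years", "Pr(>|t|)"]
  }
  list(slope = unname(stats::coef(fit)[["T_years"]]),
       intercept = unname(stats::coef(fit)[[1]]),
       r = stats::cor(T_years, theta_values),
       p_value = p,
       model = fit)
}

#' Combine group rates into a pooled rate
#'
#' The pooled estimator equals the pair-count-weighted average of the
#' per-group estimators, `sum(n_g * theta_g) / sum(n_g)`, because all
#' groups in a period share the same age and site count.
#'
#' @param thetas per-group rate values.
#' @param ns per-group pair counts.
#' @return weighted-average rate.
#' @export
weighted_rate <- function(thetas, ns) {
  pooled_mean(thetas, ns)
}
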