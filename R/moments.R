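# Closed-form distribution and moments of the uptake gains driven by a
# Poisson contraction process, and exponential rate estimation from
# observed inter-contraction intervals.

#' Density of the per-interval excess uptake under Poisson contractions
#'
#' With inter-contraction intervals `Ti ~ Exponential(lambda)`, the excess
#' uptake accrued over one interval, expressed in seconds of steady-state
#' uptake `y = (2/sqrt(pi)) * sqrt(tau * Ti)`, follows a Rayleigh law:
#' `P(y) = (2 lambda y / alpha^2) exp(-lambda y^2 / alpha^2)` with
#' `alpha = 2 sqrt(tau / pi)`. Its mode sits at `alpha / sqrt(2 lambda)`
#' (lambda in per-second units).
#'
#' Note on normalizations: the same Rayleigh law (and the moments below)
#' describes the excess scaled by `Iss` (units of seconds). The *relative*
#' per-interval gain `(2/sqrt(pi)) * sqrt(tau/Ti)` is a different random
#' variable (heavy-tailed in `1/sqrt(Ti)`) and is exposed separately by
#' [interval_uptake()] as `gain_rel`.
#'
#' @param x evaluation points, s; non-negative.
#' @param rate_per_hr contraction rate, events per hour; positive.
#' @param tau_s diffusion time `tau = a^2/D`, s; positive.
#' @return Density values, per second.
#' @export
incremental_gain_pdf <- function(x, rate_per_hr, tau_s) {
  stopifnot(is.numeric(x), all(x >= 0))
  lam <- rate_to_per_s(rate_per_hr)
  if (lam <= 0 || tau_s <= 0) stop("rate and tau must be positive")
  a2 <- 4 * tau_s / pi # alpha^2
  2 * lam * x / a2 * exp(-lam * x^2 / a2)
}

rate_to_per_s <- function(rate_per_hr) {
  stopifnot(is.numeric(rate_per_hr), length(rate_per_hr) == 1L,
            is.finite(rate_per_hr))
  rate_per_hr / 3600
}

#' Analytic moments of the per-interval excess uptake
#'
#' Mean `sqrt(tau/lambda)` and variance `(4 - pi) * tau / (pi * lambda)` of the
#' Rayleigh-distributed excess `y = (2/sqrt(pi)) sqrt(tau * Ti)` (in seconds of
#' steady-state uptake), with `lambda` converted internally to per-second.
#'
#' @inheritParams incremental_gain_pdf
#' @return Mean in s ([expected_incremental()]) or variance in s^2
#'   ([variance_incremental()]).
#' @export
expected_incremental <- function(rate_per_hr, tau_s) {
  lam <- rate_to_per_s(rate_per_hr)
  if (lam <= 0 || tau_s <= 0) stop("rate and tau must be positive")
  sqrt(tau_s / lam)
}

#' @rdname expected_incremental
#' @export
variance_incremental <- function(rate_per_hr, tau_s) {
  lam <- rate_to_per_s(rate_per_hr)
  if (lam <= 0 || tau_s <= 0) stop("rate and tau must be positive")
  (4 - pi) * tau_s / (pi * lam)
}

#' Analytic moments of the cumulative uptake gain over a horizon
#'
#' Over a horizon `T` containing on average `lambda * T` contraction events,
#' the normalized cumulative excess `dJ/Jss` has mean `sqrt(lambda * tau)` and
#' variance `(4 - pi) * tau / (pi * T)` (both dimensionless once `lambda`,
#' `tau` and `T` share units; conversion is internal). At `lambda = 0` the mean
#' formula gives 0 -- the small single-interval transient `(2/sqrt(pi))
#' sqrt(tau/T)` is what a simulation reports there.
#'
#' @inheritParams incremental_gain_pdf
#' @param horizon_hr horizon `T`, hours; positive.
#' @return Dimensionless mean / variance of `dJ/Jss`.
#' @export
expected_cumulative <- function(rate_per_hr, tau_s) {
  lam <- rate_to_per_s(rate_per_hr)
  if (lam < 0 || tau_s <= 0) stop("invalid rate or tau")
  sqrt(lam * tau_s)
}

#' @rdname expected_cumulative
#' @export
variance_cumulative <- function(tau_s, horizon_hr) {
  if (tau_s <= 0 || horizon_hr <= 0) stop("tau and horizon must be positive")
  (4 - pi) * tau_s / (pi * horizon_hr * 3600)
}

#' Exponential rate estimate from inter-contraction intervals
#'
#' Maximum-likelihood rate of an exponential interval distribution,
#' `lambda-hat = 1/mean(Ti)`, reported per hour with its large-sample standard
#' error `lambda-hat / sqrt(n)`, plus a Kolmogorov-Smirnov statistic against
#' the fitted exponential as a goodness-of-fit descriptor (a large statistic
#' flags clearly non-exponential spacing, e.g. metronomic contractions).
#' Optionally compares the exponential fit against gamma and lognormal
#' alternatives by AIC.
#'
#' @param intervals_s observed inter-contraction intervals, s; at least 2.
#' @param compare_alternatives if `TRUE`, also fit gamma (via
#'   [MASS::fitdistr()]) and lognormal models and report AICs.
#' @return A list with `rate_per_hr`, `se_per_hr`, `n`, `ks_stat`, `ks_p`, and
#'   (optionally) `aic` (named vector: exponential, gamma, lognormal).
#' @export
fit_rate_mle <- function(intervals_s, compare_alternatives = FALSE) {
  intervals_s <- as.numeric(intervals_s)
  if (length(intervals_s) < 2L) stop("need at least 2 intervals")
  if (any(!is.finite(intervals_s)) || any(intervals_s <= 0))
    stop("intervals must be positive and finite")
  lam_s <- 1 / mean(intervals_s)
  n <- length(intervals_s)
  ks <- suppressWarnings(stats::ks.test(intervals_s, stats::pexp, rate = lam_s))
  out <- list(rate_per_hr = lam_s * 3600,
              se_per_hr = lam_s * 3600 / sqrt(n),
              n = n,
              ks_stat = unname(ks$statistic),
              ks_p = ks$p.value)
  if (compare_alternatives) {
    # fit on rescaled intervals: AIC differences are invariant under a common
    # change of units, and O(1) data keeps the gamma optimizer stable
    x <- intervals_s / mean(intervals_s)
    ll_exp <- sum(stats::dexp(x, 1 / mean(x), log = TRUE))
    lx <- log(x)
    mu <- mean(lx); sd0 <- sqrt(mean((lx - mu)^2)) # lognormal MLE, closed form
    ll_ln <- sum(stats::dlnorm(x, mu, sd0, log = TRUE))
    ll_ga <- tryCatch({
      fg <- suppressWarnings(MASS::fitdistr(x, "gamma",
                                            start = list(shape = 1, rate = 1),
                                            lower = c(1e-3, 1e-3)))
      fg$loglik
    }, error = function(e) NA_real_)
    out$aic <- c(exponential = 2 * 1 - 2 * ll_exp,
                 gamma = 2 * 2 - 2 * ll_ga,
                 lognormal = 2 * 2 - 2 * ll_ln)
  }
  out
}
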