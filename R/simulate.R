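# Monte-Carlo experiments coupling contraction schedules to the transport
# closed form: single realizations, rate sweeps, budget caps, and the
# regular-vs-stochastic comparison.
#
# Realizations follow the model's bookkeeping for a horizon T: the number of
# contraction events N (the reset at t = 0 counted among them) is drawn from
# Poisson(lambda * T) and the remaining N - 1 reset times are uniform on
# (0, T), so the N inter-contraction intervals partition the horizon exactly,
# the last one censored at T. This is the construction whose mean and variance
# of dJ/Jss equal sqrt(lambda * tau) and (4 - pi) * tau / (pi * T); a renewal
# draw with a censored tail overshoots the mean by a factor 1 + 1/(2*lambda*T).
# N = 0 degenerates to the single pure-diffusion transient interval [0, T].

# vectorised batch of dJ/Jss realizations; cap = max post-zero events
sim_gain_batch <- function(n, rate_per_hr, horizon_hr, tau_s,
                           cap = NULL, mode = c("poisson", "regular")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, rate_per_hr >= 0, horizon_hr > 0, tau_s > 0)
  T_s <- horizon_hr * 3600
  if (mode == "regular" || rate_per_hr == 0)
    return(rep.int(regular_gain(rate_per_hr, horizon_hr, tau_s, cap), n))

  n_int <- pmax(stats::rpois(n, rate_per_hr * horizon_hr) - 1L, 0L) # interior resets
  id <- rep.int(seq_len(n), n_int)
  u <- stats::runif(length(id), 0, T_s)
  o <- order(id, u, method = "radix")
  id <- id[o]; u <- u[o]
  if (!is.null(cap) && length(id)) {
    keep <- sequence(n_int[n_int > 0L]) <= cap
    id <- id[keep]; u <- u[keep]
  }
  s_sum <- numeric(n)
  last_u <- numeric(n)
  if (length(id)) {
    first <- !duplicated(id)
    prev <- c(0, u[-length(u)])
    prev[first] <- 0
    sums <- rowsum(sqrt(u - prev), id, reorder = FALSE)
    s_sum[as.integer(rownames(sums))] <- sums[, 1L]
    is_last <- rev(!duplicated(rev(id)))
    last_u[id[is_last]] <- u[is_last]
  }
  s_sum <- s_sum + sqrt(T_s - last_u) # censored tail interval
  (2 / sqrt(pi)) * sqrt(tau_s) * s_sum / T_s
}

#' Closed-form uptake gain of a metronomic contraction schedule
#'
#' With events at multiples of `1/lambda` (and the reset at `t = 0`), the
#' horizon splits into `floor(lambda T)` equal intervals plus a remainder, and
#' `dJ/Jss` follows directly from the per-interval closed form. When
#' `lambda T` is an integer and no cap binds this equals
#' `(2/sqrt(pi)) * sqrt(lambda * tau)`. At `lambda = 0` the single censored
#' interval gives the pure-diffusion transient `(2/sqrt(pi)) * sqrt(tau/T)`.
#'
#' @param rate_per_hr contraction rate, events/hour; non-negative.
#' @param horizon_hr horizon `T`, hours.
#' @param tau_s diffusion time, s.
#' @param cap optional budget of post-zero events.
#' @return Dimensionless `dJ/Jss`.
#' @export
regular_gain <- function(rate_per_hr, horizon_hr, tau_s, cap = NULL) {
  stopifnot(rate_per_hr >= 0, horizon_hr > 0, tau_s > 0)
  T_s <- horizon_hr * 3600
  if (rate_per_hr == 0) return((2 / sqrt(pi)) * sqrt(tau_s / T_s))
  gap_s <- 3600 / rate_per_hr
  n_ev <- floor(rate_per_hr * horizon_hr + 1e-9)
  if (!is.null(cap)) n_ev <- min(n_ev, cap)
  rem <- max(T_s - n_ev * gap_s, 0)
  (2 / sqrt(pi)) * sqrt(tau_s) * (n_ev * sqrt(gap_s) + sqrt(rem)) / T_s
}

#' Simulate one realization of the cumulative uptake gain
#'
#' Samples one contraction schedule under `spec` and evaluates the normalized
#' cumulative excess uptake `dJ/Jss` over the horizon, all intervals included
#' (the censored tail among them).
#'
#' @param spec a [process_spec()]; its `seed`, if set, seeds the draw.
#' @param tau_s diffusion time `tau = a^2/D`, s.
#' @return Dimensionless `dJ/Jss`.
#' @export
run_realization <- function(spec, tau_s) {
  stopifnot(inherits(spec, "process_spec"), tau_s > 0)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sim_gain_batch(1L, spec$rate_per_hr, spec$horizon_hr, tau_s,
                 cap = spec$cap, mode = spec$mode)
}

# derived substream seed per (seed, lambda index); kept below 2^31
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003 + 1) * 1009 + 7919 * k) %% 2147483647L
}

#' Monte-Carlo sweep of cumulative uptake gain over contraction rates
#'
#' For each rate on the grid, draws `n_reps` independent realizations of the
#' contraction process over the horizon and summarises the normalized
#' cumulative excess uptake `dJ/Jss`. Fully reproducible: each rate uses an RNG
#' substream derived from (`seed`, rate index), so results are bit-identical
#' for identical inputs.
#'
#' @param lambdas_per_hr vector of contraction rates, events/hour.
#' @param n_reps realizations per rate.
#' @param horizon_hr horizon `T`, hours (default the 48 hr experiment length).
#' @param tau_s diffusion time, s (default 40 s, an oxygen-like value for a
#'   quarter-millimetre head).
#' @param mode `"poisson"` or `"regular"` contraction timing.
#' @param cap optional contraction budget (max post-zero events per horizon).
#' @param seed integer seed for the sweep.
#' @return A data.frame of class `sweep_result` with one row per rate:
#'   `rate_per_hr`, `mode`, `cap`, `n_reps`, `mean_gain`, `sd_gain`,
#'   `mean_gain_pct` (= 100 * mean_gain, the percent-of-steady-state scale).
#' @export
sweep_uptake <- function(lambdas_per_hr, n_reps, horizon_hr = 48, tau_s = 40,
                         mode = c("poisson", "regular"), cap = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lambdas_per_hr), length(lambdas_per_hr) >= 1L,
            all(lambdas_per_hr >= 0), n_reps >= 1)
  rows <- lapply(seq_along(lambdas_per_hr), function(k) {
    set.seed(substream_seed(seed, k))
    g <- sim_gain_batch(n_reps, lambdas_per_hr[k], horizon_hr, tau_s,
                        cap = cap, mode = mode)
    data.frame(rate_per_hr = lambdas_per_hr[k], mode = mode,
               cap = if (is.null(cap)) NA_integer_ else as.integer(cap),
               n_reps = as.integer(n_reps),
               mean_gain = mean(g), sd_gain = stats::sd(g))
  })
  out <- do.call(rbind, rows)
  out$mean_gain_pct <- 100 * out$mean_gain
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Compare stochastic and metronomic contraction strategies
#'
#' Tabulates, per rate: the Monte-Carlo mean gain of the Poisson process, the
#' closed-form gain of the regular schedule, both repeated under a contraction
#' budget, and the regular/stochastic ratio. For `lambda T >> 1` the ratio
#' approaches `2/sqrt(pi) ~ 1.128`: a precise rhythm buys only a ~13% edge
#' over Poisson-timed contractions.
#'
#' @inheritParams sweep_uptake
#' @param cap contraction budget used for the capped columns.
#' @return A data.frame with columns `rate_per_hr`, `mean_gain_poisson`,
#'   `gain_regular`, `mean_gain_capped`, `gain_regular_capped`,
#'   `ratio_regular_poisson`.
#' @export
compare_modes <- function(lambdas_per_hr, n_reps, horizon_hr = 48, tau_s = 40,
                          cap = NULL, seed = 1L) {
  po <- sweep_uptake(lambdas_per_hr, n_reps, horizon_hr, tau_s,
                     mode = "poisson", cap = NULL, seed = seed)
  pc <- sweep_uptake(lambdas_per_hr, n_reps, horizon_hr, tau_s,
                     mode = "poisson", cap = cap, seed = seed)
  data.frame(
    rate_per_hr = lambdas_per_hr,
    mean_gain_poisson = po$mean_gain,
    gain_regular = vapply(lambdas_per_hr, regular_gain, numeric(1),
                          horizon_hr = horizon_hr, tau_s = tau_s),
    mean_gain_capped = pc$mean_gain,
    gain_regular_capped = vapply(lambdas_per_hr, regular_gain, numeric(1),
                                 horizon_hr = horizon_hr, tau_s = tau_s,
                                 cap = cap),
    ratio_regular_poisson = vapply(lambdas_per_hr, regular_gain, numeric(1),
                                   horizon_hr = horizon_hr, tau_s = tau_s) /
      po$mean_gain)
}

#' Rate maximising the mean uptake gain of a sweep
#'
#' Argmax of `mean_gain` over the swept rates with a plateau-aware tie-break:
#' among rates whose mean lies within one Monte-Carlo standard error of the
#' maximum, the smallest is reported (an organism should not contract faster
#' for no measurable benefit).
#'
#' @param sweep a `sweep_result` from [sweep_uptake()].
#' @return Optimal rate, events/hour.
#' @export
find_optimal_rate <- function(sweep) {
  stopifnot(inherits(sweep, "data.frame"), nrow(sweep) >= 1L,
            all(c("rate_per_hr", "mean_gain", "sd_gain", "n_reps") %in%
                  names(sweep)))
  i <- which.max(sweep$mean_gain)
  se <- sweep$sd_gain[i] / sqrt(sweep$n_reps[i])
  min(sweep$rate_per_hr[sweep$mean_gain >= sweep$mean_gain[i] - se])
}
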