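# Closed-form unsteady diffusion to an absorbing sphere and the uptake
# integrals between boundary-layer resets. All lengths in mm, times in s,
# diffusivities in mm^2/s; concentrations in the (arbitrary) units of the
# far-field value.

#' Physical parameters of the spherical-absorber transport model
#'
#' Bundles the geometry and physics of the diffusion-limited uptake model: a
#' sphere of radius `a` (the polyp's head) absorbing a compound of diffusivity
#' `D` from a quiescent fluid held at concentration `C_inf` far away. The
#' characteristic diffusion time `tau = a^2/D` is always derived, never stored,
#' so it cannot drift out of sync with `a` and `D`.
#'
#' The defaults (a quarter-millimetre head, oxygen-like diffusivity of
#' 1.5e-3 mm^2/s in cool water, unit far-field concentration) are conventional
#' choices for a small freshwater polyp; every result of record in this package
#' is reported in normalized form (I/Iss, delta-J/Jss), which is independent of
#' `C_inf` and only depends on `a` and `D` through `tau`.
#'
#' @param head_radius_mm absorber (head) radius, mm; must be positive.
#' @param diffusivity_mm2_s compound diffusivity, mm^2/s; must be positive.
#' @param far_conc far-field concentration, arbitrary units; non-negative.
#' @param foot_radius_mm optional radius of the static basal foot sphere, mm.
#'   Informational only: the foot never sheds its boundary layer and sits at the
#'   permanent steady state; no two-sphere interaction is computed.
#' @param separation_mm optional head-foot separation, mm. Recorded for
#'   reporting; unused by any formula (the spheres do not interact).
#' @return An object of class `transport_params`.
#' @examples
#' p <- transport_params()
#' diffusion_time(p) # a^2 / D, seconds
#' @export
transport_params <- function(head_radius_mm = 0.25,
                             diffusivity_mm2_s = 1.5e-3,
                             far_conc = 1,
                             foot_radius_mm = NULL,
                             separation_mm = NULL) {
  stopifnot(is.numeric(head_radius_mm), length(head_radius_mm) == 1L,
            is.finite(head_radius_mm), head_radius_mm > 0,
            is.numeric(diffusivity_mm2_s), length(diffusivity_mm2_s) == 1L,
            is.finite(diffusivity_mm2_s), diffusivity_mm2_s > 0,
            is.numeric(far_conc), length(far_conc) == 1L,
            is.finite(far_conc), far_conc >= 0)
  if (!is.null(foot_radius_mm))
    stopifnot(is.numeric(foot_radius_mm), foot_radius_mm > 0)
  if (!is.null(separation_mm))
    stopifnot(is.numeric(separation_mm), separation_mm > 0)
  structure(
    list(head_radius_mm = head_radius_mm,
         diffusivity_mm2_s = diffusivity_mm2_s,
         far_conc = far_conc,
         foot_radius_mm = foot_radius_mm,
         separation_mm = separation_mm),
    class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Spherical-absorber transport parameters\n")
  cat(sprintf("  head radius a : %g mm\n", x$head_radius_mm))
  cat(sprintf("  diffusivity D : %g mm^2/s\n", x$diffusivity_mm2_s))
  cat(sprintf("  far conc C_inf: %g\n", x$far_conc))
  cat(sprintf("  tau = a^2/D   : %g s\n", diffusion_time(x)))
  if (!is.null(x$foot_radius_mm))
    cat(sprintf("  foot radius b : %g mm (static, steady state)\n",
                x$foot_radius_mm))
  invisible(x)
}

#' Characteristic diffusion time tau = a^2 / D
#'
#' @param params a [transport_params()] object.
#' @return Time scale in seconds over which the depletion layer around the
#'   absorber grows to a thickness comparable with the absorber radius.
#' @export
diffusion_time <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  params$head_radius_mm^2 / params$diffusivity_mm2_s
}

# error function via the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

check_tr <- function(params, t_s, r_mm) {
  stopifnot(inherits(params, "transport_params"),
            is.numeric(t_s), is.numeric(r_mm))
  if (any(t_s < 0)) stop("time must be non-negative")
  if (any(r_mm < params$head_radius_mm))
    stop("radius lies inside the absorbing sphere (r < a)")
}

#' Unsteady concentration field around an absorbing sphere
#'
#' Concentration at time `t` and radius `r` for diffusion to a perfectly
#' absorbing sphere of radius `a` started from a uniform field `C_inf` at
#' `t = 0` (the state immediately after a boundary-layer reset):
#' `C(t, r) = C_inf * (1 - a/r + (a/r) * erf((r - a) / sqrt(4 D t)))`.
#' At `t = 0` the erf argument is taken in the limit: 1 for `r > a`, 0 at
#' `r = a`, so the initial condition `C = C_inf` is recovered off the surface.
#'
#' @param params a [transport_params()] object.
#' @param t_s time since the last reset, s (vectorised).
#' @param r_mm radial position, mm, `r >= a` (vectorised).
#' @return Concentration in the units of `far_conc`.
#' @seealso [emitting_concentration()] for the complementary emitter problem.
#' @export
concentration <- function(params, t_s, r_mm) {
  check_tr(params, t_s, r_mm)
  a <- params$head_radius_mm
  d <- params$diffusivity_mm2_s
  n <- max(length(t_s), length(r_mm))
  t_s <- rep_len(t_s, n); r_mm <- rep_len(r_mm, n)
  z <- ifelse(t_s > 0, (r_mm - a) / sqrt(4 * d * t_s),
              ifelse(r_mm > a, Inf, 0))
  params$far_conc * (1 - a / r_mm + (a / r_mm) * erf(z))
}

#' Radial concentration gradient around an absorbing sphere
#'
#' Closed-form `dC/dr` of the unsteady field of [concentration()]. Converges to
#' the steady-state gradient `C_inf * a / r^2` as `t` grows. Non-negative
#' everywhere: the depletion layer always deepens toward the surface.
#'
#' @inheritParams concentration
#' @return Gradient in concentration units per mm.
#' @export
concentration_gradient <- function(params, t_s, r_mm) {
  check_tr(params, t_s, r_mm)
  if (any(t_s <= 0)) stop("gradient requires t > 0")
  a <- params$head_radius_mm
  d <- params$diffusivity_mm2_s
  n <- max(length(t_s), length(r_mm))
  t_s <- rep_len(t_s, n); r_mm <- rep_len(r_mm, n)
  z <- (r_mm - a) / sqrt(4 * d * t_s)
  params$far_conc * (a / r_mm^2 - (a / r_mm^2) * erf(z) +
                       (a / r_mm) * (2 / sqrt(pi)) * exp(-z^2) /
                       sqrt(4 * d * t_s))
}

#' Steady-state (Smoluchowski) uptake rate of the absorbing sphere
#'
#' `Iss = 4 * pi * D * C_inf * a`, the diffusion-limited absorption rate of a
#' sphere once the depletion layer has fully developed.
#'
#' @inheritParams concentration
#' @return Uptake rate, amount per second.
#' @export
steady_state_uptake <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  4 * pi * params$diffusivity_mm2_s * params$far_conc * params$head_radius_mm
}

#' Instantaneous uptake rate at time t after a reset
#'
#' `I(t) = Iss * (1 + sqrt(tau / (pi * t)))` with `tau = a^2/D`: the uptake is
#' largest right after a boundary-layer reset (the `1/sqrt(t)` transient) and
#' decays monotonically to the Smoluchowski rate. The `t -> 0` singularity is
#' integrable; use [interval_uptake()] for cumulative quantities.
#'
#' @inheritParams concentration
#' @param t_s time since the last reset, s; strictly positive (vectorised).
#' @return Uptake rate, amount per second.
#' @export
instantaneous_uptake <- function(params, t_s) {
  stopifnot(inherits(params, "transport_params"), is.numeric(t_s))
  if (any(t_s <= 0)) stop("instantaneous uptake requires t > 0")
  tau <- diffusion_time(params)
  steady_state_uptake(params) * (1 + sqrt(tau / (pi * t_s)))
}

#' Cumulative uptake over one inter-contraction interval
#'
#' Integrating the post-reset transient over an interval of length `Ti` gives
#' `Ji = Iss * Ti * (1 + (2/sqrt(pi)) * sqrt(tau/Ti))`. Two normalized views of
#' the excess over steady state are reported:
#' * `gain_rel = (Ji - Iss*Ti) / (Iss*Ti) = (2/sqrt(pi)) * sqrt(tau/Ti)`,
#'   the relative gain over the interval (dimensionless, decreasing in `Ti`);
#' * `excess_s = (Ji - Iss*Ti) / Iss = (2/sqrt(pi)) * sqrt(tau*Ti)`,
#'   the excess expressed as equivalent seconds of steady-state uptake
#'   (increasing in `Ti`). The identity `excess_s = gain_rel * Ti` holds
#'   exactly.
#'
#' @inheritParams concentration
#' @param interval_s inter-contraction interval length(s) `Ti`, s, positive.
#' @return A data.frame with columns `interval_s`, `gain_rel`, `excess_s`, and
#'   `uptake` (absolute `Ji` in the units implied by `far_conc`).
#' @export
interval_uptake <- function(params, interval_s) {
  stopifnot(inherits(params, "transport_params"), is.numeric(interval_s))
  if (any(interval_s <= 0)) stop("interval length must be positive")
  tau <- diffusion_time(params)
  gain <- (2 / sqrt(pi)) * sqrt(tau / interval_s)
  iss <- steady_state_uptake(params)
  data.frame(interval_s = interval_s,
             gain_rel = gain,
             excess_s = gain * interval_s,
             uptake = iss * interval_s * (1 + gain))
}

#' Cumulative uptake over a horizon partitioned by contraction resets
#'
#' For a horizon `T` split into intervals `Ti` (each started by a
#' boundary-layer reset, the last possibly censored at `T`), the excess uptake
#' relative to steady state is
#' `dJ/Jss = (1/T) * sum (2/sqrt(pi)) * sqrt(tau * Ti)`.
#'
#' @inheritParams concentration
#' @param intervals_s positive interval lengths, s; must sum to `horizon_s`.
#' @param horizon_s total horizon `T`, s.
#' @param tol relative tolerance for the interval-sum check.
#' @return A list with `gain` (dimensionless `dJ/Jss`), `uptake` (absolute `J`)
#'   and `steady` (`Jss = Iss * T`).
#' @export
cumulative_uptake <- function(params, intervals_s, horizon_s, tol = 1e-8) {
  stopifnot(inherits(params, "transport_params"),
            is.numeric(intervals_s), length(intervals_s) >= 1L,
            is.numeric(horizon_s), horizon_s > 0)
  if (any(intervals_s <= 0)) stop("all intervals must be positive")
  if (abs(sum(intervals_s) - horizon_s) > tol * horizon_s)
    stop("intervals must partition the horizon (sum(Ti) == T)")
  tau <- diffusion_time(params)
  gain <- uptake_gain(intervals_s, tau, horizon_s)
  jss <- steady_state_uptake(params) * horizon_s
  list(gain = gain, uptake = jss * (1 + gain), steady = jss)
}

# normalized excess uptake dJ/Jss for a set of reset intervals; the package's
# central closed form, shared by cumulative_uptake() and the Monte-Carlo layer
uptake_gain <- function(intervals_s, tau_s, horizon_s) {
  (2 / sqrt(pi)) * sum(sqrt(tau_s * intervals_s)) / horizon_s
}

#' Unsteady concentration field around an emitting sphere
#'
#' A sphere held at surface concentration `C_inf` emitting into a fluid that is
#' compound-free far away is the mirror image of the absorber:
#' `C~(t, r) = C_inf - C(t, r)`. Its production rate is `-I(t)`, so absorption
#' and emission are a single problem; the package works with absorption.
#'
#' @inheritParams concentration
#' @return Concentration in the units of `far_conc`.
#' @export
emitting_concentration <- function(params, t_s, r_mm) {
  params$far_conc - concentration(params, t_s, r_mm)
}

#' Evaluate the transport fields on a (t, r) grid
#'
#' Convenience export of the closed-form fields for plotting or archiving:
#' one row per grid point with concentration, gradient and the instantaneous
#' uptake rate (the latter depends on `t` only).
#'
#' @inheritParams concentration
#' @param t_s vector of times, s (positive).
#' @param r_mm vector of radii, mm (`>= a`).
#' @return A data.frame with columns `t_s`, `r_mm`, `C`, `dCdr`, `I`.
#' @export
transport_grid <- function(params, t_s, r_mm) {
  stopifnot(all(t_s > 0))
  g <- expand.grid(t_s = t_s, r_mm = r_mm, KEEP.OUT.ATTRS = FALSE)
  g$C <- concentration(params, g$t_s, g$r_mm)
  g$dCdr <- concentration_gradient(params, g$t_s, g$r_mm)
  g$I <- instantaneous_uptake(params, g$t_s)
  g
}
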