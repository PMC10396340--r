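# Body-kinematics analysis: length traces from head/foot tracks, peak
# contraction detection, contraction-rate estimation, dimensionless numbers,
# and fluid-boundary-layer thickness from velocity profiles.

#' Body-length series from a head/foot track table
#'
#' Computes the Euclidean head-foot distance per frame, a relative length
#' normalized by a running reference of the extended state, and the shortening
#' rate. The reference is the running maximum of the (3-frame median-filtered)
#' length over the trailing `ref_window_s`: the animal is near fully extended
#' at some point within any few-minute window, so this tracks the extended
#' length without requiring an absolute calibration -- and makes downstream
#' detection invariant to uniform spatial scaling of the tracks.
#'
#' @param track a data.frame with columns `time_s`, `head_x_mm`, `head_y_mm`,
#'   `foot_x_mm`, `foot_y_mm` (optional `head_z_mm`, `foot_z_mm`), e.g. from
#'   [read_track_table()] or [generate_kinematics()].
#' @param ref_window_s trailing window for the extended-length reference, s.
#' @param smooth if `TRUE` (default) apply a 3-frame running median before
#'   differencing, suppressing single-frame tracking-noise spikes.
#' @return A data.frame of class `body_length_series` with columns `time_s`,
#'   `length_mm`, `relative_length`, `rate_per_s` (centred difference of
#'   `relative_length`; `NA` on the boundary frames).
#' @export
body_length <- function(track, ref_window_s = 300, smooth = TRUE) {
  validate_track(track)
  if (nrow(track) < 3L) stop("need at least 3 frames")
  cols <- c("x", "y")
  if (all(c("head_z_mm", "foot_z_mm") %in% names(track))) cols <- c(cols, "z")
  sq <- 0
  for (cc in cols)
    sq <- sq + (track[[paste0("head_", cc, "_mm")]] -
                  track[[paste0("foot_", cc, "_mm")]])^2
  len <- sqrt(sq)
  sm <- if (smooth && length(len) >= 3L) as.numeric(stats::runmed(len, 3L))
        else len
  dt <- stats::median(diff(track$time_s))
  w <- max(1L, round(ref_window_s / dt))
  ref <- trailing_max(sm, w)
  rel <- sm / ref
  n <- length(rel)
  rate <- rep(NA_real_, n)
  if (n >= 3L)
    rate[2:(n - 1)] <- (rel[3:n] - rel[1:(n - 2)]) /
      (track$time_s[3:n] - track$time_s[1:(n - 2)])
  out <- data.frame(time_s = track$time_s, length_mm = len,
                    relative_length = rel, rate_per_s = rate)
  class(out) <- c("body_length_series", "data.frame")
  attr(out, "frame_dt_s") <- dt
  attr(out, "smoothed_relative") <- rel
  out
}

# sliding maximum over a trailing window of w samples, O(n) block algorithm
trailing_max <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n <= 1L) return(x)
  w <- min(w, n)
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  left <- as.vector(apply(m, 2L, cummax))          # prefix max within blocks
  right <- as.vector(apply(m[w:1, , drop = FALSE], 2L, cummax)[w:1, ])
  idx <- seq_len(n)
  lo <- pmax(idx - w + 1L, 1L)
  pmax(right[lo], left[idx])
}

#' Detect peak contractions and contraction episodes in a length series
#'
#' A peak contraction (PC) is a shortening of the body at 25% or more of the
#' (reference) body length per second. Because a PC lasts of order a second,
#' at slow frame rates it falls between frames: detection therefore thresholds
#' the relative-length *drop* between consecutive frames against
#' `rate_threshold * min(frame interval, pc_max_duration_s)` -- at video rate
#' this is the instantaneous rate criterion, at time-lapse rates it assumes
#' the drop happened within at most `pc_max_duration_s`. Only shortening
#' counts; re-extension is never flagged. PC frames closer than `merge_gap_s`
#' are merged into one spontaneous-contraction episode (an episode comprises
#' one or more PCs separated by at most a brief plateau), and episode start
#' times define the contraction-event sequence used for rate estimation.
#'
#' @param series a [body_length()] result.
#' @param rate_threshold_per_s PC threshold, fraction of body length per
#'   second shortening (default 0.25/s).
#' @param merge_gap_s PCs separated by less than this belong to one episode.
#' @param pc_max_duration_s assumed maximum duration of a single PC, s.
#' @param interval_from convention for inter-contraction intervals: gaps
#'   between consecutive episode `"start"` times (default; matches treating
#'   each contraction as a point reset) or from episode `"end"` to next start.
#' @return An object of class `event_calls`: list with `pc_times_s`,
#'   `episodes` (data.frame `start_s`, `end_s`, `n_pc`), `ic_intervals_s`,
#'   `duration_hr`, `direct_rate_per_hr`, `mle_rate_per_hr`, `mle_se_per_hr`,
#'   `ks_stat`.
#' @export
detect_contractions <- function(series, rate_threshold_per_s = 0.25,
                                merge_gap_s = 10, pc_max_duration_s = 1,
                                interval_from = c("start", "end")) {
  stopifnot(inherits(series, "body_length_series"))
  interval_from <- match.arg(interval_from)
  if (nrow(series) < 2L) stop("series too short")
  rel <- attr(series, "smoothed_relative")
  if (is.null(rel)) rel <- series$relative_length
  t <- series$time_s
  dt <- diff(t)
  drop <- -diff(rel)
  hit <- drop >= rate_threshold_per_s * pmin(dt, pc_max_duration_s)
  pc_times <- t[which(hit)] # start frame of each detected drop
  dur_hr <- (t[length(t)] - t[1]) / 3600
  if (length(pc_times) == 0L) {
    calls <- list(pc_times_s = numeric(0),
                  episodes = data.frame(start_s = numeric(0),
                                        end_s = numeric(0),
                                        n_pc = integer(0)),
                  ic_intervals_s = numeric(0), duration_hr = dur_hr,
                  direct_rate_per_hr = 0, mle_rate_per_hr = NA_real_,
                  mle_se_per_hr = NA_real_, ks_stat = NA_real_)
    class(calls) <- "event_calls"
    return(calls)
  }
  new_ep <- c(TRUE, diff(pc_times) >= merge_gap_s)
  ep_id <- cumsum(new_ep)
  frame_dt <- attr(series, "frame_dt_s")
  episodes <- data.frame(
    start_s = tapply(pc_times, ep_id, min),
    end_s = tapply(pc_times, ep_id, max) + min(frame_dt, pc_max_duration_s),
    n_pc = as.integer(table(ep_id)),
    row.names = NULL)
  ic <- if (nrow(episodes) >= 2L) {
    if (interval_from == "start") diff(episodes$start_s)
    else episodes$start_s[-1] - episodes$end_s[-nrow(episodes)]
  } else numeric(0)
  calls <- list(pc_times_s = pc_times, episodes = episodes,
                ic_intervals_s = ic, duration_hr = dur_hr)
  class(calls) <- "event_calls"
  est <- estimate_frequency(calls, dur_hr)
  calls[names(est)] <- est
  calls
}

#' @export
print.event_calls <- function(x, ...) {
  cat(sprintf("Contraction events: %d episodes (%d peak contractions) in %.2f hr\n",
              nrow(x$episodes), length(x$pc_times_s), x$duration_hr))
  cat(sprintf("  direct rate: %.3g /hr   exponential-fit rate: %.3g /hr\n",
              x$direct_rate_per_hr, x$mle_rate_per_hr))
  invisible(x)
}

#' Contraction-frequency estimates from detected events
#'
#' Two estimators of the contraction rate: the direct average (episode count
#' over observation time) and the exponential maximum-likelihood rate fitted
#' to the inter-contraction intervals (see [fit_rate_mle()]); the two converge
#' on Poisson-timed contractions as the observation window grows.
#'
#' @param calls an `event_calls` object from [detect_contractions()].
#' @param duration_hr observation duration, hours.
#' @return A list with `direct_rate_per_hr`, `mle_rate_per_hr`,
#'   `mle_se_per_hr`, `ks_stat` (the latter three `NA` when fewer than two
#'   intervals are available).
#' @export
estimate_frequency <- function(calls, duration_hr) {
  stopifnot(inherits(calls, "event_calls"), duration_hr > 0)
  direct <- nrow(calls$episodes) / duration_hr
  if (length(calls$ic_intervals_s) >= 2L) {
    fit <- fit_rate_mle(calls$ic_intervals_s)
    list(direct_rate_per_hr = direct, mle_rate_per_hr = fit$rate_per_hr,
         mle_se_per_hr = fit$se_per_hr, ks_stat = fit$ks_stat)
  } else {
    list(direct_rate_per_hr = direct, mle_rate_per_hr = NA_real_,
         mle_se_per_hr = NA_real_, ks_stat = NA_real_)
  }
}

#' Reynolds number Re = l U / nu
#'
#' Ratio of inertial to viscous effects for a feature of size `l` moving at
#' speed `U` in a fluid of kinematic viscosity `nu` (water at 20 C by
#' default). `Re << 1` means viscosity-dominated laminar flow with an
#' expansive fluid boundary layer.
#'
#' @param length_scale_mm feature length scale, mm; positive.
#' @param speed_mm_s speed, mm/s; non-negative.
#' @param kin_viscosity_mm2_s kinematic viscosity, mm^2/s; positive.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(length_scale_mm, speed_mm_s,
                     kin_viscosity_mm2_s = 1.0034) {
  if (any(length_scale_mm <= 0) || any(kin_viscosity_mm2_s <= 0))
    stop("length scale and viscosity must be positive")
  if (any(speed_mm_s < 0)) stop("speed must be non-negative")
  length_scale_mm * speed_mm_s / kin_viscosity_mm2_s
}

#' Peclet number Pe = L U / D
#'
#' Ratio of advective to diffusive transport of a compound of diffusivity `D`
#' over a length `L` at speed `U`; `Pe << 1` means transport is
#' diffusion-dominated.
#'
#' @param length_scale_mm transport length scale, mm; positive.
#' @param speed_mm_s characteristic speed, mm/s; non-negative.
#' @param diffusivity_mm2_s compound diffusivity, mm^2/s; positive.
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(length_scale_mm, speed_mm_s, diffusivity_mm2_s) {
  if (any(length_scale_mm <= 0) || any(diffusivity_mm2_s <= 0))
    stop("length scale and diffusivity must be positive")
  if (any(speed_mm_s < 0)) stop("speed must be non-negative")
  length_scale_mm * speed_mm_s / diffusivity_mm2_s
}

#' Velocity-magnitude profile away from a moving surface
#'
#' @param distance_mm strictly increasing distances from the surface, mm,
#'   starting at or near 0.
#' @param speed_mm_s fluid speed at each distance, mm/s; non-negative.
#' @param surface_speed_mm_s speed of the surface itself (defaults to the
#'   speed at the first sample).
#' @param freestream_speed_mm_s far-field fluid speed (default 0: quiescent
#'   tank).
#' @return An object of class `velocity_profile`.
#' @export
velocity_profile <- function(distance_mm, speed_mm_s,
                             surface_speed_mm_s = speed_mm_s[1],
                             freestream_speed_mm_s = 0) {
  stopifnot(is.numeric(distance_mm), is.numeric(speed_mm_s),
            length(distance_mm) == length(speed_mm_s),
            length(distance_mm) >= 2L)
  if (is.unsorted(distance_mm, strictly = TRUE))
    stop("distances must be strictly increasing")
  if (any(speed_mm_s < 0)) stop("speeds must be non-negative")
  structure(list(distance_mm = as.numeric(distance_mm),
                 speed_mm_s = as.numeric(speed_mm_s),
                 surface_speed_mm_s = surface_speed_mm_s,
                 freestream_speed_mm_s = freestream_speed_mm_s),
            class = "velocity_profile")
}

#' Fluid-boundary-layer thickness from a velocity profile
#'
#' The FBL thickness is the distance from the surface at which the fluid speed
#' has decayed by `decay_fraction` (90% by convention) of the surface-to-
#' freestream speed difference, i.e. the fluid has stopped following the
#' surface. Found as the first threshold crossing, linearly interpolated
#' between profile samples; monotone non-decreasing in `decay_fraction`.
#'
#' @param profile a [velocity_profile()].
#' @param decay_fraction fraction of the speed excess that must have decayed
#'   (default 0.9).
#' @return Thickness in mm.
#' @export
fbl_thickness <- function(profile, decay_fraction = 0.9) {
  stopifnot(inherits(profile, "velocity_profile"),
            decay_fraction >= 0, decay_fraction <= 1)
  us <- profile$surface_speed_mm_s
  uf <- profile$freestream_speed_mm_s
  if (us <= uf) stop("surface speed must exceed freestream speed")
  thr <- us - decay_fraction * (us - uf)
  d <- profile$distance_mm
  v <- profile$speed_mm_s
  if (decay_fraction == 0) return(0)
  below <- which(v <= thr)
  if (length(below) == 0L)
    stop(sprintf("speed never decays to threshold within profile (last distance %g mm)",
                 d[length(d)]))
  i <- below[1]
  if (i == 1L) return(d[1])
  # interpolate the crossing between samples i-1 and i
  d[i - 1] + (thr - v[i - 1]) * (d[i] - d[i - 1]) / (v[i] - v[i - 1])
}
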