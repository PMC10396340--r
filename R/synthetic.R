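# Ground-truth generators emulating the study's recordings: head/foot tracks
# with planted contraction episodes, near-surface velocity profiles with a
# known decay distance, and exponential inter-contraction intervals. All
# generators are pure functions of (parameters, seed).

#' Generate a synthetic head/foot tracking table with planted contractions
#'
#' Emulates a time-lapse recording of a tethered polyp: contraction events are
#' drawn from a Poisson process of the given rate; at each event the relative
#' body length drops linearly to `min_relative_length` within `pc_duration_s`
#' (optionally split into two peak contractions separated by a brief plateau),
#' then re-extends exponentially with time constant `reextension_tau_s`
#' toward full length. The body axis revolves slowly about the foothold (the
#' cone-tracing of the extended state), the foot stays fixed, and i.i.d.
#' Gaussian positional noise is added to both markers. Sampling is at
#' `frame_rate_per_min` frames per minute (20 by default, the time-lapse
#' regime; use 3600 for a 60 frames/s video regime).
#'
#' The defaults plant the printed facts of the emulated recordings: shortening
#' to 20% of extended length within ~1 s (well above the 25%/s peak-contraction
#' criterion), minutes-scale re-extension, 1% positional noise.
#'
#' @param rate_per_hr true contraction rate `lambda`, events/hour.
#' @param duration_hr recording length, hours.
#' @param frame_rate_per_min sampling rate, frames per minute.
#' @param extended_length_mm extended body length, mm.
#' @param min_relative_length body length at full contraction, fraction of
#'   extended length (in (0, 1)).
#' @param pc_duration_s total shortening time of an episode, s.
#' @param pc_split_prob probability that an episode consists of two peak
#'   contractions separated by `plateau_s` instead of one.
#' @param plateau_s pause between the two peak contractions of a split
#'   episode, s.
#' @param reextension_tau_s exponential re-extension time constant, s.
#' @param noise_sd fractional positional noise (s.d. as a fraction of the
#'   extended length), applied per coordinate and frame.
#' @param seed integer seed; identical inputs give identical output.
#' @return A list with `track` (a track table as in [body_length()]),
#'   `event_times_s` (planted episode starts), and `params` (the arguments).
#' @export
generate_kinematics <- function(rate_per_hr, duration_hr,
                                frame_rate_per_min = 20,
                                extended_length_mm = 5,
                                min_relative_length = 0.2,
                                pc_duration_s = 1,
                                pc_split_prob = 0.5,
                                plateau_s = 1,
                                reextension_tau_s = 60,
                                noise_sd = 0.01,
                                seed = 1L) {
  stopifnot(rate_per_hr >= 0, duration_hr > 0, frame_rate_per_min > 0,
            min_relative_length > 0, min_relative_length < 1,
            pc_duration_s > 0, reextension_tau_s > 0, noise_sd >= 0)
  dur_s <- duration_hr * 3600
  if (rate_per_hr > 0 && dur_s < pc_duration_s + plateau_s)
    stop("duration too short to hold one contraction episode")
  set.seed(seed)
  events <- sample_schedule(process_spec(rate_per_hr, duration_hr))$event_times_s
  split2 <- stats::runif(length(events)) < pc_split_prob
  ep_dur <- pc_duration_s + ifelse(split2, plateau_s, 0)

  dt <- 60 / frame_rate_per_min
  t <- seq(0, dur_s, by = dt)

  # starting relative length of each episode depends on how far re-extension
  # got since the previous one; iterate over events (few), not frames
  n_ev <- length(events)
  L0 <- numeric(n_ev)
  if (n_ev) {
    L0[1] <- 1
    if (n_ev > 1) {
      for (k in 2:n_ev) {
        gap <- events[k] - events[k - 1]
        s <- gap - ep_dur[k - 1]
        L0[k] <- if (s <= 0) min_relative_length
        else 1 - (1 - min_relative_length) * exp(-s / reextension_tau_s)
      }
    }
  }

  rel <- rep(1, length(t))
  if (n_ev) {
    idx <- findInterval(t, events) # last event at or before each frame
    inplay <- idx > 0L
    s <- t[inplay] - events[idx[inplay]] # time since that event
    k <- idx[inplay]
    drop_to <- min_relative_length
    d1 <- pc_duration_s / 2 # per-PC shortening time for split episodes
    mid <- (L0[k] + drop_to) / 2
    ed <- ep_dur[k]
    sp <- split2[k]
    relq <- ifelse(s >= ed,
                   1 - (1 - drop_to) * exp(-(s - ed) / reextension_tau_s),
            ifelse(!sp,
                   # single PC: linear drop over pc_duration_s
                   L0[k] + (drop_to - L0[k]) * pmin(s / pc_duration_s, 1),
            ifelse(s < d1,
                   L0[k] + (mid - L0[k]) * s / d1,
            ifelse(s < d1 + plateau_s,
                   mid,
                   mid + (drop_to - mid) * (s - d1 - plateau_s) / d1))))
    rel[inplay] <- relq
  }

  # slowly revolving body axis; planar angle keeps |head - foot| == length
  psi <- 0.15 * sin(2 * pi * t / 600)
  len <- rel * extended_length_mm
  noise <- function(n) stats::rnorm(n, 0, noise_sd * extended_length_mm)
  track <- data.frame(
    time_s = t,
    head_x_mm = len * sin(psi) + noise(length(t)),
    head_y_mm = len * cos(psi) + noise(length(t)),
    foot_x_mm = noise(length(t)),
    foot_y_mm = noise(length(t)))
  list(track = track,
       event_times_s = events,
       params = list(rate_per_hr = rate_per_hr, duration_hr = duration_hr,
                     frame_rate_per_min = frame_rate_per_min,
                     extended_length_mm = extended_length_mm,
                     min_relative_length = min_relative_length,
                     pc_duration_s = pc_duration_s,
                     pc_split_prob = pc_split_prob, plateau_s = plateau_s,
                     reextension_tau_s = reextension_tau_s,
                     noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic near-surface velocity profile
#'
#' Produces a monotone-decaying speed-vs-distance profile whose analytic
#' 90%-decay distance equals `thickness_mm` exactly, for validating
#' [fbl_thickness()]. Shapes: `"linear"` ramp hitting zero at
#' `thickness_mm / 0.9`, `"exponential"` decay with scale
#' `thickness_mm / log(10)`, or an `"erf"`-type complementary-error-function
#' decay. Optional multiplicative noise.
#'
#' @param thickness_mm target 90%-decay distance, mm; positive.
#' @param surface_speed_mm_s surface speed, mm/s.
#' @param shape profile family.
#' @param n_points number of samples (>= 4).
#' @param max_distance_mm profile extent (default twice the thickness).
#' @param noise_sd multiplicative noise s.d. (fraction of local speed).
#' @param seed integer seed.
#' @return A [velocity_profile()].
#' @export
generate_velocity_profile <- function(thickness_mm, surface_speed_mm_s = 1,
                                      shape = c("linear", "exponential", "erf"),
                                      n_points = 50,
                                      max_distance_mm = 2 * thickness_mm,
                                      noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(thickness_mm > 0, surface_speed_mm_s > 0, noise_sd >= 0)
  if (n_points < 4L) stop("need at least 4 profile points")
  set.seed(seed)
  d <- seq(0, max_distance_mm, length.out = n_points)
  us <- surface_speed_mm_s
  v <- switch(shape,
    linear = us * pmax(1 - 0.9 * d / thickness_mm, 0),
    exponential = us * exp(-d * log(10) / thickness_mm),
    erf = us * (1 - erf(d * erfinv09() / thickness_mm)))
  if (noise_sd > 0) {
    v <- v * (1 + stats::rnorm(n_points, 0, noise_sd))
    v <- pmax(v, 0)
    v[1] <- us # keep the anchor at the surface
  }
  velocity_profile(d, v, surface_speed_mm_s = us, freestream_speed_mm_s = 0)
}

# inverse error function value with erf(x) = 0.9
erfinv09 <- function() stats::qnorm((0.9 + 1) / 2) / sqrt(2)

#' Generate i.i.d. exponential inter-contraction intervals
#'
#' @param rate_per_hr contraction rate, events/hour; positive.
#' @param n number of intervals; positive.
#' @param seed integer seed.
#' @return Intervals in seconds.
#' @export
generate_intervals <- function(rate_per_hr, n, seed = 1L) {
  stopifnot(rate_per_hr > 0)
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  stats::rexp(n, rate_per_hr / 3600)
}
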