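# Contraction-event processes: specification, sampling, budget caps.
# Rates cross the interface in events/hour, horizons in hours; schedule
# objects store seconds internally like the transport layer.

HR <- 3600 # seconds per hour

#' Specification of a contraction-event process
#'
#' @param rate_per_hr contraction rate `lambda`, events per hour; non-negative.
#' @param horizon_hr observation horizon `T`, hours; positive.
#' @param mode `"poisson"` for exponentially distributed inter-contraction
#'   intervals, `"regular"` for a metronomic schedule with gap `1/lambda`.
#' @param cap optional positive integer: maximum number of contraction events
#'   after the implicit reset at `t = 0`; once reached, no further events occur
#'   within the horizon (a finite contraction budget).
#' @param seed optional integer seed used by [sample_schedule()].
#' @return An object of class `process_spec`.
#' @export
process_spec <- function(rate_per_hr, horizon_hr = 48, mode = c("poisson", "regular"),
                         cap = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(rate_per_hr), length(rate_per_hr) == 1L,
            is.finite(rate_per_hr),
            is.numeric(horizon_hr), length(horizon_hr) == 1L, horizon_hr > 0)
  if (rate_per_hr < 0) stop("rate must be non-negative")
  if (!is.null(cap)) {
    cap <- as.integer(cap)
    stopifnot(length(cap) == 1L, !is.na(cap), cap >= 1L)
  }
  structure(list(rate_per_hr = rate_per_hr, horizon_hr = horizon_hr,
                 mode = mode, cap = cap, seed = seed),
            class = "process_spec")
}

#' Contraction schedule on a fixed horizon
#'
#' A schedule is the ordered set of contraction (reset) times in `(0, T]`,
#' together with the implicit reset at `t = 0`: the derived `intervals_s`
#' partition the horizon exactly, the final interval being censored at `T`
#' (no contraction closes it).
#'
#' @param event_times_s strictly increasing event times in `(0, T]`, s.
#' @param horizon_s horizon `T`, s.
#' @return An object of class `contraction_schedule` with fields
#'   `horizon_s`, `event_times_s`, `intervals_s`, `censored` (logical flag per
#'   interval; only the last is `TRUE`).
#' @export
contraction_schedule <- function(event_times_s, horizon_s) {
  stopifnot(is.numeric(horizon_s), length(horizon_s) == 1L, horizon_s > 0)
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s)) {
    if (is.unsorted(event_times_s, strictly = TRUE))
      stop("event times must be strictly increasing")
    if (any(event_times_s <= 0) || any(event_times_s > horizon_s))
      stop("event times must lie in (0, T]")
  }
  intervals <- diff(c(0, event_times_s, horizon_s))
  censored <- c(rep(FALSE, length(event_times_s)), TRUE)
  # an event exactly at T leaves a zero-length censored stub; drop it
  if (intervals[length(intervals)] == 0 && length(intervals) > 1L) {
    intervals <- intervals[-length(intervals)]
    censored <- censored[-1L] # keep one TRUE flag on the (now last) interval
    censored[length(censored)] <- TRUE
  }
  structure(list(horizon_s = horizon_s, event_times_s = event_times_s,
                 intervals_s = intervals, censored = censored),
            class = "contraction_schedule")
}

#' @export
print.contraction_schedule <- function(x, ...) {
  cat(sprintf("Contraction schedule: %d events over %.3g hr (mean gap %.3g min)\n",
              length(x$event_times_s), x$horizon_s / HR,
              mean(x$intervals_s) / 60))
  invisible(x)
}

#' Sample a contraction schedule
#'
#' In `"poisson"` mode inter-contraction gaps are drawn i.i.d. from
#' Exponential(mean `1/lambda`) until the horizon is exceeded, giving a Poisson
#' process of events on `(0, T]`. In `"regular"` mode events sit at multiples
#' of `1/lambda` (at `lambda = 0` either mode yields an event-free schedule:
#' one censored interval of length `T`). A `cap` in the spec is applied as in
#' [apply_cap()].
#'
#' @param spec a [process_spec()].
#' @return A [contraction_schedule()].
#' @export
sample_schedule <- function(spec) {
  stopifnot(inherits(spec, "process_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  T_s <- spec$horizon_hr * HR
  lam_s <- spec$rate_per_hr / HR
  if (spec$rate_per_hr == 0) {
    sched <- contraction_schedule(numeric(0), T_s)
  } else if (spec$mode == "regular") {
    n_ev <- floor(spec$rate_per_hr * spec$horizon_hr + 1e-9)
    sched <- contraction_schedule(seq_len(n_ev) / lam_s, T_s)
  } else {
    times <- numeric(0)
    last <- 0
    repeat { # draw exponential gaps in blocks until the horizon is exceeded
      block <- max(64L, ceiling(1.5 * lam_s * (T_s - last)))
      cum <- last + cumsum(stats::rexp(block, lam_s))
      times <- c(times, cum[cum <= T_s])
      last <- cum[length(cum)]
      if (last > T_s) break
    }
    sched <- contraction_schedule(times, T_s)
  }
  if (!is.null(spec$cap)) sched <- apply_cap(sched, spec$cap) else sched
}

#' Impose a contraction budget on a schedule
#'
#' Keeps only the first `cap` events after `t = 0`; the remainder of the
#' horizon becomes part of the final censored interval. Capping never increases
#' the event count and always conserves the horizon.
#'
#' @param schedule a [contraction_schedule()].
#' @param cap positive integer budget of post-zero events.
#' @return A [contraction_schedule()].
#' @export
apply_cap <- function(schedule, cap) {
  stopifnot(inherits(schedule, "contraction_schedule"))
  cap <- as.integer(cap)
  stopifnot(length(cap) == 1L, !is.na(cap), cap >= 1L)
  ev <- schedule$event_times_s
  if (length(ev) <= cap) return(schedule)
  contraction_schedule(ev[seq_len(cap)], schedule$horizon_s)
}
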