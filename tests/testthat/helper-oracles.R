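# Shared oracles and fixtures, all built in code.

# high-precision error function, independent of the package internals
erf_oracle <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# cumulative uptake over [0, Ti] by adaptive quadrature of the flux transient
quad_interval_uptake <- function(params, Ti) {
  stats::integrate(function(x) instantaneous_uptake(params, x), 0, Ti,
                   rel.tol = 1e-10, subdivisions = 1000L)$value
}

# match planted event times to detected episode starts (greedy, nearest
# neighbour within a window); returns TP / FP / FN counts
match_events <- function(planted, detected, window_s = 10) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (p in planted) {
    d <- abs(detected - p)
    d[used] <- Inf
    if (length(d) && min(d) <= window_s) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(planted) - tp)
}

f1_score <- function(counts) {
  tp <- counts[["tp"]]
  2 * tp / (2 * tp + counts[["fp"]] + counts[["fn"]])
}

# synthetic track with a known analytic length law (no noise, fixed axis)
track_from_length <- function(time_s, length_mm) {
  data.frame(time_s = time_s,
             head_x_mm = 0, head_y_mm = length_mm,
             foot_x_mm = 0, foot_y_mm = 0)
}
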