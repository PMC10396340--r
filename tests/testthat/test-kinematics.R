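# Kinematics analysis: length traces, event detection, rates, dimensionless
# numbers, boundary-layer thickness.

test_that("body_length computes head-foot distance and rates", {
  t <- seq(0, 60, by = 3)
  tr <- track_from_length(t, rep(5, length(t)))
  bl <- body_length(tr)
  expect_equal(bl$length_mm, rep(5, length(t)))
  expect_equal(bl$relative_length, rep(1, length(t)))
  expect_true(all(bl$rate_per_s[2:(length(t) - 1)] == 0))
  expect_true(is.na(bl$rate_per_s[1]))
  # 3-4-5 triangle
  tr2 <- data.frame(time_s = c(0, 1, 2), head_x_mm = 3, head_y_mm = 4,
                    foot_x_mm = 0, foot_y_mm = 0)
  expect_equal(body_length(tr2)$length_mm, rep(5, 3))
  expect_error(body_length(tr2[1:2, ]), "3 frames")
})

test_that("rate matches the analytic derivative of a known length law", {
  t <- seq(0, 600, by = 1)
  len <- 5 * (0.6 + 0.4 * cos(2 * pi * t / 600)) # slow, sub-threshold
  bl <- body_length(track_from_length(t, len), smooth = FALSE)
  # while the trailing 5-min window still contains t = 0 the reference is the
  # full extension (5 mm), so d(rel)/dt has a closed form there
  an <- -0.4 * 2 * pi / 600 * sin(2 * pi * t / 600)
  mid <- 50:280
  expect_equal(bl$rate_per_s[mid], an[mid], tolerance = 1e-4)
})

test_that("detection is invariant to uniform spatial scaling", {
  k <- generate_kinematics(3, 4, seed = 8)
  tr2 <- k$track
  for (cc in c("head_x_mm", "head_y_mm", "foot_x_mm", "foot_y_mm"))
    tr2[[cc]] <- 40 * tr2[[cc]]
  e1 <- detect_contractions(body_length(k$track))
  e2 <- detect_contractions(body_length(tr2))
  expect_equal(e1$episodes$start_s, e2$episodes$start_s)
  expect_equal(e1$mle_rate_per_hr, e2$mle_rate_per_hr)
})

test_that("threshold separates peak contractions from slow shortening", {
  t <- seq(0, 1200, by = 3)
  # drop 1.0 -> 0.5 within one frame pair (rate ~0.5/s over <= 1 s): a PC
  len <- rep(5, length(t)); len[t >= 600] <- 2.5
  calls <- detect_contractions(body_length(track_from_length(t, len)))
  expect_equal(nrow(calls$episodes), 1L)
  expect_lt(abs(calls$episodes$start_s - 597), 3.1)
  # drop 1.0 -> 0.8: 0.2 of body length, below the 25% criterion
  len2 <- rep(5, length(t)); len2[t >= 600] <- 4
  calls2 <- detect_contractions(body_length(track_from_length(t, len2)))
  expect_equal(nrow(calls2$episodes), 0L)
  expect_equal(calls2$direct_rate_per_hr, 0)
  expect_true(is.na(calls2$mle_rate_per_hr))
})

test_that("sub-frame contractions are caught at video and time-lapse rates", {
  # 60 fps: a 1-s linear drop to 20% spans 60 frames, each above threshold
  t <- seq(0, 600, by = 1 / 60)
  len <- rep(5, length(t))
  drop <- t >= 300 & t < 301
  len[drop] <- 5 - 4 * (t[drop] - 300)
  len[t >= 301] <- 1
  calls <- detect_contractions(body_length(track_from_length(t, len)))
  expect_equal(nrow(calls$episodes), 1L)
  expect_lt(abs(calls$episodes$start_s - 300), 0.1)
  # 20 frames/min: the same event falls between adjacent frames
  t2 <- seq(0, 600, by = 3)
  len2 <- ifelse(t2 < 300, 5, 1)
  calls2 <- detect_contractions(body_length(track_from_length(t2, len2)))
  expect_equal(nrow(calls2$episodes), 1L)
})

test_that("planted episodes are recovered with no false positives", {
  k <- generate_kinematics(2.5, 8, noise_sd = 0.01, seed = 14)
  calls <- detect_contractions(body_length(k$track))
  m <- match_events(k$event_times_s, calls$episodes$start_s, window_s = 10)
  expect_equal(m[["fp"]], 0L)
  expect_gte(m[["tp"]], length(k$event_times_s) - 1L)
  # detected starts sit within about one frame of the planted times
  offs <- vapply(calls$episodes$start_s,
                 function(s) min(abs(k$event_times_s - s)), numeric(1))
  expect_lte(median(offs), 3)
})

test_that("estimate_frequency reports direct and exponential-fit rates", {
  k <- generate_kinematics(3, 4, seed = 15)
  calls <- detect_contractions(body_length(k$track))
  est <- estimate_frequency(calls, 4)
  expect_equal(est$direct_rate_per_hr, nrow(calls$episodes) / 4)
  # 20/30/40-minute gaps: 2 per hour from the exponential fit
  fake <- calls
  fake$ic_intervals_s <- c(20, 30, 40) * 60
  expect_equal(estimate_frequency(fake, 4)$mle_rate_per_hr, 2)
})

test_that("direct and MLE rates agree on long Poisson recordings", {
  k <- generate_kinematics(3, 48, noise_sd = 0.01, seed = 16)
  calls <- detect_contractions(body_length(k$track))
  expect_lt(abs(calls$direct_rate_per_hr - calls$mle_rate_per_hr) /
              calls$mle_rate_per_hr, 0.1)
})

test_that("Reynolds and Peclet calculators implement l U / (nu | D)", {
  expect_equal(reynolds(0.1, 0.1), 0.01 / 1.0034)
  expect_equal(round(reynolds(0.1, 0.1, 1.0034), 2), 0.01)
  expect_equal(round(reynolds(0.1, 10, 1.0034), 0), 1)
  expect_equal(reynolds(0.1, 0), 0)
  expect_error(reynolds(0, 1), "positive")
  expect_equal(peclet(1, 1, 1), 1)
  expect_equal(peclet(1, 0, 1), 0)
  expect_equal(peclet(1, 2, 1), 2 * peclet(1, 1, 1)) # linear in U
  expect_error(peclet(1, 1, 0), "positive")
})

test_that("fbl_thickness finds the decay distance by interpolation", {
  # linear profile hitting zero at 5 mm: 90% decay at 4.5 mm
  d <- seq(0, 6, by = 0.05)
  lin <- velocity_profile(d, pmax(1 - d / 5, 0))
  expect_equal(fbl_thickness(lin), 4.5, tolerance = 1e-9)
  expect_equal(fbl_thickness(lin, 0), 0)
  # exponential decay scale 1 mm: 90% decay at ln(10)
  ex <- velocity_profile(d, exp(-d))
  expect_equal(fbl_thickness(ex), log(10), tolerance = 0.01)
  # monotone non-decreasing in the decay fraction
  fr <- seq(0.1, 0.95, by = 0.05)
  th <- vapply(fr, function(f) fbl_thickness(ex, f), numeric(1))
  expect_true(all(diff(th) >= 0))
  # threshold never reached within the profile
  short <- velocity_profile(c(0, 0.5, 1), c(1, 0.9, 0.8))
  expect_error(fbl_thickness(short), "never decays")
  rising <- velocity_profile(c(0, 1), c(0.1, 0.2),
                             freestream_speed_mm_s = 0.2)
  expect_error(fbl_thickness(rising), "surface speed")
})
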