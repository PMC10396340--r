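# Closed-form transport solutions around the absorbing sphere.

p1 <- transport_params(head_radius_mm = 1, diffusivity_mm2_s = 1, far_conc = 1)

test_that("transport_params validates inputs and derives tau", {
  expect_error(transport_params(head_radius_mm = 0), "head_radius")
  expect_error(transport_params(diffusivity_mm2_s = -1))
  expect_error(transport_params(far_conc = -0.1))
  p <- transport_params(0.25, 1.5e-3)
  expect_equal(diffusion_time(p), 0.25^2 / 1.5e-3)
  expect_null(p$tau) # tau is always recomputed, never stored
})

test_that("concentration matches the closed form and its limits", {
  # absorbing boundary at all times
  expect_equal(concentration(p1, c(0, 0.3, 5), 1), c(0, 0, 0))
  # steady state C_inf (1 - a/r)
  expect_equal(concentration(p1, 1e12, 2), 0.5, tolerance = 1e-5)
  # t = 0 limit off the surface: untouched far-field value
  expect_equal(concentration(p1, 0, c(1.001, 2, 10)), c(1, 1, 1))
  # frozen value at t = tau, r = 2a (erf oracle): 0.5 + 0.5 erf(0.5)
  expect_equal(concentration(p1, 1, 2), 0.5 + 0.5 * erf_oracle(0.5),
               tolerance = 1e-12)
  expect_equal(concentration(p1, 1, 2), 0.7602499389, tolerance = 1e-9)
  expect_error(concentration(p1, 1, 0.5), "inside")
  expect_error(concentration(p1, -1, 2), "non-negative")
})

test_that("the closed-form field satisfies the diffusion equation on a grid", {
  # second-order finite differences, evaluated away from the t -> 0 transient
  # (the post-reset boundary layer is thinner than any fixed grid there)
  dr <- 1 / 200; dt <- 1 / 200
  r <- seq(1, 2.5, by = dr); t <- seq(0.5, 1.5, by = dt)
  C <- outer(t, r, function(tt, rr) concentration(p1, tt, rr))
  it <- 2:(length(t) - 1); ir <- 2:(length(r) - 1)
  Ct <- (C[it + 1, ir] - C[it - 1, ir]) / (2 * dt)
  rmat <- matrix(r[ir], nrow = length(it), ncol = length(ir), byrow = TRUE)
  lap <- (C[it, ir + 1] - 2 * C[it, ir] + C[it, ir - 1]) / dr^2 +
    (2 / rmat) * (C[it, ir + 1] - C[it, ir - 1]) / (2 * dr)
  expect_lt(max(abs(Ct - lap)) / max(abs(Ct)), 1e-3)
})

test_that("concentration is bounded and monotone in t and r", {
  t <- c(0.01, 0.1, 1, 10); r <- seq(1, 4, by = 0.05)
  for (tt in t) {
    cc <- concentration(p1, tt, r)
    expect_true(all(cc >= 0 & cc <= 1))
    expect_true(all(diff(cc) >= 0)) # increasing outward
  }
  for (rr in c(1.1, 1.5, 2.5)) {
    cc <- concentration(p1, sort(t), rr)
    expect_true(all(diff(cc) <= 0)) # depletion deepens in time
  }
})

test_that("concentration gradient matches finite differences and limits", {
  # steady-state gradient C_inf / a at the surface
  expect_equal(concentration_gradient(p1, 1e12, 1), 1, tolerance = 1e-5)
  # central-difference oracle at t = tau, several radii
  h <- 1e-5
  for (rr in c(1.3, 2, 3)) {
    fd <- (concentration(p1, 1, rr + h) - concentration(p1, 1, rr - h)) /
      (2 * h)
    expect_equal(concentration_gradient(p1, 1, rr), fd, tolerance = 1e-6)
  }
  # non-negative everywhere (concentration increases outward)
  g <- transport_grid(p1, c(0.05, 0.5, 5), seq(1, 3, by = 0.1))
  expect_true(all(g$dCdr >= 0))
  expect_error(concentration_gradient(p1, 0, 2), "t > 0")
})

test_that("uptake transient: I(t) = Iss (1 + sqrt(tau/(pi t)))", {
  iss <- steady_state_uptake(p1)
  expect_equal(iss, 4 * pi)
  expect_equal(steady_state_uptake(transport_params(2, 1, 1)), 8 * pi)
  expect_equal(steady_state_uptake(transport_params(0.25, 1.5e-3, 1)),
               4 * pi * 1.5e-3 * 0.25)
  expect_equal(instantaneous_uptake(p1, 1 / pi) / iss, 2)
  expect_equal(instantaneous_uptake(p1, 1) / iss, 1 + 1 / sqrt(pi))
  expect_equal(instantaneous_uptake(p1, 1e12) / iss, 1, tolerance = 1e-5)
  tt <- 10^seq(-3, 3, by = 0.5)
  it <- instantaneous_uptake(p1, tt)
  expect_true(all(diff(it) < 0))       # strictly decreasing
  expect_true(all(it >= iss))          # resets never reduce uptake
  expect_error(instantaneous_uptake(p1, 0), "t > 0")
  # flux integral oracle: 4 pi a^2 D dC/dr at the surface
  for (tt in c(0.1, 1, 7)) {
    flux <- 4 * pi * 1^2 * 1 * concentration_gradient(p1, tt, 1)
    expect_equal(instantaneous_uptake(p1, tt), flux, tolerance = 1e-12)
  }
})

test_that("interval uptake matches quadrature of the transient", {
  tau <- diffusion_time(p1)
  for (Ti in c(0.01 * tau, tau, 100 * tau)) {
    rec <- interval_uptake(p1, Ti)
    expect_equal(rec$uptake, quad_interval_uptake(p1, Ti), tolerance = 1e-6)
    expect_equal(rec$excess_s, rec$gain_rel * Ti) # algebraic identity
    expect_gte(rec$gain_rel, 0)
  }
  # Ti = 4 tau / pi makes the relative gain exactly 1
  expect_equal(interval_uptake(p1, 4 / pi)$gain_rel, 1)
  expect_equal(interval_uptake(p1, 1)$uptake / steady_state_uptake(p1),
               1 + 2 / sqrt(pi))
  # monotonicities in Ti
  ti <- c(0.1, 0.5, 1, 5, 50)
  rec <- interval_uptake(p1, ti)
  expect_true(all(diff(rec$gain_rel) < 0))
  expect_true(all(diff(rec$excess_s) > 0))
  expect_error(interval_uptake(p1, 0), "positive")
})

test_that("cumulative uptake sums per-interval closed forms", {
  tau <- diffusion_time(p1)
  # single interval of length T
  T1 <- 7.3
  expect_equal(cumulative_uptake(p1, T1, T1)$gain,
               (2 / sqrt(pi)) * sqrt(tau / T1))
  # N equal intervals: gain = (2/sqrt(pi)) sqrt(tau N / T)
  N <- 16; Ttot <- 12
  expect_equal(cumulative_uptake(p1, rep(Ttot / N, N), Ttot)$gain,
               (2 / sqrt(pi)) * sqrt(tau * N / Ttot))
  # mixed intervals vs summed quadratures
  iv <- c(tau, 4 * tau / pi)
  got <- cumulative_uptake(p1, iv, sum(iv))
  jq <- sum(vapply(iv, quad_interval_uptake, numeric(1), params = p1))
  expect_equal(got$uptake, jq, tolerance = 1e-8)
  expect_gte(got$gain, 0)
  expect_error(cumulative_uptake(p1, c(1, 2), 10), "partition")
  expect_error(cumulative_uptake(p1, c(-1, 11), 10), "positive")
})

test_that("emitting sphere is the exact mirror of the absorber", {
  t <- c(0.01, 0.5, 3); r <- seq(1, 4, by = 0.25)
  for (tt in t)
    expect_equal(emitting_concentration(p1, tt, r) +
                   concentration(p1, tt, r),
                 rep(1, length(r))) # machine-precision duality
  expect_equal(emitting_concentration(p1, 2, 1), 1) # surface held at C_inf
  expect_equal(emitting_concentration(p1, 1e9, 1e6), 0, tolerance = 1e-5)
})
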