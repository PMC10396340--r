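# Monte-Carlo uptake experiments: single realizations, sweeps, budgets,
# regular-vs-stochastic comparison.

test_that("degenerate realizations reproduce the closed forms", {
  tau <- 40
  # lambda = 0: single pure-diffusion transient over the horizon
  g0 <- run_realization(process_spec(0, 48, seed = 1), tau)
  expect_equal(g0, (2 / sqrt(pi)) * sqrt(tau / (48 * 3600)))
  # regular mode with integer lambda T: exactly (2/sqrt(pi)) sqrt(lambda tau)
  gr <- run_realization(process_spec(3, 48, mode = "regular"), tau)
  expect_equal(gr, (2 / sqrt(pi)) * sqrt(3 * tau / 3600))
  expect_equal(regular_gain(0, 48, tau), (2 / sqrt(pi)) * sqrt(tau / 172800))
  # capped regular schedule cannot exceed the budget gain
  expect_lt(regular_gain(10, 48, tau, cap = 144),
            regular_gain(10, 48, tau))
})

test_that("simulated cumulative gains match the analytic moments", {
  tau <- 40; T_hr <- 48; n <- 10000
  sd_th <- sqrt(variance_cumulative(tau, T_hr))
  for (lam in c(0.5, 3, 10)) {
    set.seed(1000 + lam * 10)
    g <- shedflux:::sim_gain_batch(n, lam, T_hr, tau)
    m_th <- expected_cumulative(lam, tau)
    expect_lt(abs(mean(g) - m_th), 4 * sd_th / sqrt(n))
    expect_lt(abs(sd(g) - sd_th), 4 * sd_th / sqrt(2 * n))
    expect_true(all(g >= 0)) # contractions never reduce uptake
  }
})

test_that("sweeps are reproducible and the unconstrained curve is monotone", {
  lam <- seq(0, 10, by = 1)
  s1 <- sweep_uptake(lam, 400, tau_s = 40, seed = 7)
  s2 <- sweep_uptake(lam, 400, tau_s = 40, seed = 7)
  expect_identical(s1, s2) # bit-identical under the same seed
  expect_true(all(diff(s1$mean_gain) > 0))
  expect_equal(s1$mean_gain_pct, 100 * s1$mean_gain)
  expect_true(all(s1$sd_gain >= 0))
  # unconstrained mean tracks sqrt(lambda tau) (4 MC standard errors)
  th <- vapply(lam, expected_cumulative, numeric(1), tau_s = 40)
  tol <- 4 * sqrt(variance_cumulative(40, 48)) / sqrt(400)
  expect_true(all(abs(s1$mean_gain[lam >= 0.5] - th[lam >= 0.5]) < tol))
})

test_that("a contraction budget caps the curve beyond cap/T", {
  lam <- c(1, 2, 3, 5, 8, 10)
  free <- sweep_uptake(lam, 1500, tau_s = 40, seed = 3)
  capped <- sweep_uptake(lam, 1500, tau_s = 40, cap = 144, seed = 3)
  # identical below the budget rate (cap inactive; same substreams)
  low <- lam <= 2
  expect_equal(capped$mean_gain[low], free$mean_gain[low], tolerance = 1e-3)
  # strictly below the free curve well beyond it
  high <- lam >= 5
  expect_true(all(capped$mean_gain[high] < free$mean_gain[high]))
  # interior maximum near cap / T = 3/hr
  expect_equal(which.max(capped$mean_gain), which(lam == 3))
  # a smaller budget moves the optimum accordingly: cap 48 -> 1/hr
  lam2 <- seq(0.5, 3, by = 0.5)
  c48 <- sweep_uptake(lam2, 2000, tau_s = 40, cap = 48, seed = 4)
  expect_lte(abs(find_optimal_rate(c48) - 1), 0.5)
})

test_that("find_optimal_rate picks the plateau edge on monotone sweeps", {
  s <- sweep_uptake(seq(1, 10, by = 1), 500, tau_s = 40, seed = 9)
  expect_equal(find_optimal_rate(s), 10) # unconstrained: grid maximum
  expect_error(find_optimal_rate(data.frame()))
  # plateau tie-break: flat curve reports the smallest rate
  flat <- data.frame(rate_per_hr = c(2, 3, 4),
                     mean_gain = c(0.2, 0.2 + 1e-6, 0.2),
                     sd_gain = c(0.01, 0.01, 0.01), n_reps = 100L)
  expect_equal(find_optimal_rate(flat), 2)
})

test_that("regular contraction timing beats Poisson timing by 2/sqrt(pi)", {
  lam <- c(2, 3, 6)
  cmp <- compare_modes(lam, 4000, tau_s = 40, cap = 144, seed = 13)
  # ratio -> 2/sqrt(pi) for lambda T >> 1
  expect_equal(cmp$ratio_regular_poisson, rep(2 / sqrt(pi), 3),
               tolerance = 0.005)
  expect_true(all(cmp$ratio_regular_poisson > 1)) # Jensen: sqrt is concave
  # cap inactive strictly below cap/T: capped and free columns agree
  expect_equal(cmp$mean_gain_capped[cmp$rate_per_hr < 3],
               cmp$mean_gain_poisson[cmp$rate_per_hr < 3], tolerance = 1e-3)
})
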