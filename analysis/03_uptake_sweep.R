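#!/usr/bin/env Rscript
# Monte-Carlo sweeps of cumulative uptake versus contraction rate: analytic
# agreement, the effect of a contraction budget, and the regular-vs-Poisson
# comparison. Grid 0-10/hr at 0.25 with 2,000 replicates per rate (a 5x/5x
# reduction of the full 0.05-step/10,000-replicate experiment; recorded in
# the sidecar metadata).

suppressPackageStartupMessages(library(shedflux))
dir.create("results", showWarnings = FALSE)

tau <- 40; horizon <- 48
seed <- 20260920L

## Agreement with the analytic moments at three representative rates.
mom <- do.call(rbind, lapply(c(0.5, 3, 10), function(lam) {
  s <- sweep_uptake(lam, 10000, horizon, tau, seed = seed)
  data.frame(rate_per_hr = lam,
             mean_mc = s$mean_gain, mean_analytic = expected_cumulative(lam, tau),
             sd_mc = s$sd_gain, sd_analytic = sqrt(variance_cumulative(tau, horizon)))
}))
write.csv(mom, "results/moments_check.csv", row.names = FALSE)
cat("Simulated vs analytic moments of dJ/Jss (T = 48 hr, tau = 40 s):\n")
print(cbind(mom[1], round(mom[-1], 5)), row.names = FALSE)

## Rate sweeps, free and under a 144-contraction budget.
grid <- seq(0, 10, by = 0.25)
reps <- 2000
free <- sweep_uptake(grid, reps, horizon, tau, seed = seed)
capped <- sweep_uptake(grid, reps, horizon, tau, cap = 144, seed = seed)
meta <- list(seed = seed, tau_s = tau, horizon_hr = horizon, n_reps = reps,
             grid_step = 0.25,
             reduction = "grid step 5x coarser, 5x fewer reps than the full experiment")
write_sweep(free, "results/sweep_free.csv", meta)
write_sweep(capped, "results/sweep_capped.csv", c(meta, cap = 144))

cat(sprintf("\nUnconstrained uptake gain grows monotonically: %.1f%% at 3/hr, %.1f%% at 10/hr\n",
            free$mean_gain_pct[free$rate_per_hr == 3],
            free$mean_gain_pct[free$rate_per_hr == 10]))
cat(sprintf("Under a 144-contraction budget the gain peaks at %.2f/hr (%.1f%%)\n",
            find_optimal_rate(capped), max(capped$mean_gain_pct)))
cat(sprintf("and declines beyond it (%.1f%% at 10/hr): more contractions than\n",
            capped$mean_gain_pct[capped$rate_per_hr == 10]))
cat("the budget allows only front-loads the resets and wastes the horizon tail.\n")

## Metronomic versus Poisson contraction timing.
cmp <- compare_modes(c(1, 2, 3, 5, 10), 4000, horizon, tau, cap = 144,
                     seed = seed + 1L)
write.csv(cmp, "results/compare_modes.csv", row.names = FALSE)
cat(sprintf("\nRegular timing beats Poisson timing by the factor %.3f (theory 2/sqrt(pi) = %.3f):\n",
            mean(cmp$ratio_regular_poisson), 2 / sqrt(pi)))
cat("a precise pacemaker would buy only ~13% extra uptake over stochastic timing.\n")
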