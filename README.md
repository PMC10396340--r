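# shedflux

Chemical uptake at a contracting surface via boundary-layer shedding.

Small sessile aquatic animals such as the freshwater polyp *Hydra* live at
Reynolds numbers of order 0.01 and Péclet numbers far below one: between
movements, chemical exchange across their epithelium — oxygen, metabolites,
antimicrobials relevant to their surface microbiota — is purely diffusive,
and a depleted concentration boundary layer grows around the body. Recurrent
whole-body contractions (head speeds ~10 mm/s for ~1 s) shed the fluid
envelope together with its depleted layer, restarting the diffusion
transient from fresh fluid. `shedflux` is an R package for modelling and
quantifying this mechanism, aimed at biophysicists and quantitative
biologists working on host–microbe fluid environments.

## The model

Approximating the head by an absorbing sphere (radius *a*, compound
diffusivity *D*, far-field concentration *C*∞), the post-reset field is

    C(t, r) = C∞ [ 1 − a/r + (a/r) erf( (r − a) / √(4Dt) ) ]

with uptake rate `I(t) = Iss (1 + √(τ/(πt)))`, Smoluchowski rate
`Iss = 4πDC∞a`, and diffusion time `τ = a²/D`. Over an inter-contraction
interval `Ti` the uptake is `Ji = Iss·Ti (1 + (2/√π)√(τ/Ti))`; over a horizon
`T` partitioned by Poisson(λ)-timed resets, the excess over steady state

    ΔJ/Jss = (1/T) Σᵢ (2/√π) √(τ·Tᵢ)

has mean `√(λτ)` and variance `(4−π)τ/(πT)`, the per-interval excess being
Rayleigh-distributed. The package provides these closed forms, Monte-Carlo
rate sweeps (with optional contraction budgets and metronomic comparators),
contraction-event detection and rate estimation from head/foot tracking
tables, Reynolds/Péclet calculators, fluid-boundary-layer thickness
extraction from velocity profiles, and synthetic-data generators that
emulate the recordings end to end.

## Worked example

```r
library(shedflux)

p <- transport_params()          # a = 0.25 mm, D = 1.5e-3 mm^2/s, C_inf = 1
diffusion_time(p)
#> [1] 41.66667

# uptake accumulated over a 20-min inter-contraction interval,
# relative to steady state
interval_uptake(p, 1200)$gain_rel
#> [1] 0.210261

# sweep the contraction rate under a 144-contraction budget over 48 hr
capped <- sweep_uptake(seq(0, 10, by = 0.25), n_reps = 2000,
                       horizon_hr = 48, tau_s = 40, cap = 144, seed = 101)
find_optimal_rate(capped)
#> [1] 3
subset(capped, rate_per_hr %in% c(1, 3, 10), c(rate_per_hr, mean_gain_pct))
#>    rate_per_hr mean_gain_pct
#> 5            1      10.52994
#> 13           3      17.88062
#> 41          10      11.43895
```

A freely contracting animal gains uptake monotonically with rate
(`√(λτ)`: 18.3% of steady state at 3/hr, 33.3% at 10/hr), but under a
finite contraction budget of 144 events per 48 hr the gain peaks at
3 contractions per hour — the budget spread evenly over the horizon — and
declines beyond it.

Detection on a synthetic recording:

```r
k <- generate_kinematics(rate_per_hr = 3, duration_hr = 8,
                         noise_sd = 0.01, seed = 2)
calls <- detect_contractions(body_length(k$track))
calls
#> Contraction events: 21 episodes (26 peak contractions) in 8.00 hr
#>   direct rate: 2.62 /hr   exponential-fit rate: 2.75 /hr
```

## Analysis workflow

The numbered scripts under `analysis/` reproduce the package's analyses and
write their tables to `results/`:

| script | contents |
|---|---|
| `01_kinematics.R` | synthetic recordings → detection, rate estimates, Re/Pe, FBL thickness |
| `02_transport_curves.R` | depletion-layer growth and uptake traces with/without resets |
| `03_uptake_sweep.R` | analytic-vs-simulated moments, free/capped sweeps, regular-vs-Poisson |
| `04_rate_recovery.R` | end-to-end rate recovery across the physiological rate range |

Run them from the repository root, e.g. `Rscript analysis/03_uptake_sweep.R`.

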