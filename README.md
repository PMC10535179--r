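# nanomill

Analysis toolkit for **wet stirred media milling (WSMM)** of drug
nanosuspensions — the workhorse process for turning micronised, poorly
soluble drug powders (here: griseofulvin) into sub-200 nm suspensions by
agitating the suspension with small yttrium-stabilised zirconia (YSZ)
beads. It is written for formulation and process scientists who need to
compare milling conditions (stirrer speed, bead loading, bead size and
bead-size mixtures) quantitatively rather than by eyeballing size curves.

The package covers five connected analyses:

1. **Breakage kinetics.** The median particle size follows an nth-order
   decay law

   d50(t) = d_lim + [(d50,0 − d_lim)^(1−n) − (1−n) k t]^(1/(1−n)),

   with rate constant *k* (µm^(1−n)/min), breakage order *n*, and limiting
   size *d_lim*. `fit_breakage()` estimates (k, n, d_lim) by
   Levenberg–Marquardt least squares on log-transformed sizes;
   `time_to_size()` finds the time to reach a 0.2 µm median by
   shape-preserving pchip interpolation.

2. **Microhydrodynamics (MHD).** `granular_temperature()` solves the
   granular energy balance

   P_w = 54 µ_L c θ R_diss / D_b² + (12/D_b) √π (1−e²) g₀ c² ρ_b θ^{3/2} + ε_ht

   for the granular temperature θ, and `compute_mhd_state()` derives the
   bead-collision parameters used to explain breakage: maximum contact
   pressure σ_b^max, contact radius α_b, compression frequency a = p·ν, and
   the pseudo-energy dissipation rate Π·σy.

3. **Kinetics prediction.** `select_and_fit()` trains elastic-net, ridge,
   linear, decision-tree and gradient-boosting candidates on the 24-run
   factorial training set (one regression per response), scores them by
   leave-one-out CV and by the 3-run test set, and keeps the test-RMSE
   minimiser — with MHD predictors or raw process parameters.

4. **Merit scores and economics.** `merit_table()` ranks conditions with
   Merit = 100/10^((m̄ + P̄ + N̄_d50)/3) over min–max-normalized cycle-time,
   power and thermal-cycling metrics; `bead_economics()` converts Zr
   contamination into bead wear, usable lifetime and 9-year capital cost
   under monthly or wear-threshold replacement.

5. **Synthetic studies.** `simulate_study()` generates the whole campaign
   (factorial design, noisy size series, power/viscosity responses,
   intermittent 35 °C thermal cycling) from a response surface calibrated
   against the bundled reference fits, so every stage is testable without
   experimental data.

## Worked example

```r
library(nanomill)
library(dplyr)

study <- simulate_study(build_design(seed = 7))
fit <- fit_breakage(filter(study$timeseries, run_id == "19"))
fit
#> nth-order breakage fit
#>   k = 4.787 um^(1-n)/min, n = 2.340, d_lim = 0.1239 um (d50_0 = 11.2 um)
#>   log-scale R2 = 0.9961 (adj 0.9948), SSR = 0.008574

time_to_size(filter(study$timeseries, run_id == "19"))
#> # A tibble: 1 × 2
#>   t_cross_min crossed
#>         <dbl> <lgl>
#> 1        4.40 TRUE
```

Run 19 (4000 rpm, bead loading 0.50, 100 µm beads) is the most energetic
condition: its simulated suspension crosses the 0.2 µm target in ~4.4 min,
and the fitted k ≈ 4.8 µm^(1−n)/min is the largest in the study. The same
summary statistics the campaign reports are one call away:

```r
summarize_fits(reference_kinetics())
#> # A tibble: 3 × 3
#>   parameter  mean     sd
#>   <chr>     <dbl>  <dbl>
#> 1 k         1.35  1.32
#> 2 n         2.02  0.361
#> 3 d_lim_um  0.125 0.0256

k_ratio(reference_kinetics(), "19", "24")
#> [1] 3.333333

bead_economics()[, c("nominal_um", "usable_years", "cost_usd", "savings_pct")]
#> # A tibble: 3 × 4
#>   nominal_um usable_years cost_usd savings_pct
#> 1        100         3.08     323.        0
#> 2        200         2.09     306.        5.12
#> 3        400         1.13     251.       22.2
```

So the limiting size is essentially bead-independent (0.125 ± 0.026 µm),
the smallest beads break 3.3× faster than the largest at the most
energetic condition, and switching to coarse beads saves at most ~22% in
bead capital cost — the quantitative backbone of the conclusion that small
beads win on process grounds while coarse beads win (modestly) on cost.

`run_pipeline(out_dir, default_config())` chains every stage and writes
`runs.csv`, per-run `timeseries/`, `fits.csv`, `mhd.csv`,
`predictions.csv`, `merit.csv`, `economics.csv` and a `summary.txt`; a thin
CLI over it lives at `inst/scripts/nanomill.R`.

## Documentation

The methods vignette (`vignettes/milling-analysis.Rmd`) describes the
models, their assumptions, the tunable parameters and the numerical
choices in detail.
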