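---
title: "Breakage kinetics, microhydrodynamics and process economics of wet stirred media milling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakage kinetics, microhydrodynamics and process economics of wet stirred media milling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomill)
library(dplyr)
```

Wet stirred media milling (WSMM) reduces micronised drug crystals to
sub-micron sizes by stirring the suspension with a dense charge of small
ceramic beads. This vignette explains the models implemented in
`nanomill`, the assumptions behind them, the tunable parameters and their
defaults, and the numerical choices a user should know about before
trusting the outputs.

## The breakage kinetics model

The median size of the milled drug particles decays monotonically toward
an apparent grinding limit. `nanomill` models this with an nth-order rate
law for the median size $d_{50}$:

$$\frac{\mathrm{d}\,d_{50}}{\mathrm{d}t} = -k\,(d_{50} - d_{\mathrm{lim}})^n,$$

whose closed-form solution, implemented in `breakage_d50()`, is

$$d_{50}(t) = d_{\mathrm{lim}} +
  \left[(d_{50,0}-d_{\mathrm{lim}})^{1-n} - (1-n)\,k\,t\right]^{1/(1-n)}.$$

Here $k$ (µm$^{1-n}$/min) is the breakage rate constant — the single most
useful figure of merit for "how fast does this condition mill" — $n$ is
the breakage order, $d_{\mathrm{lim}}$ (µm) the limiting median size, and
$d_{50,0}$ the feed size. The model assumes breakage is the only active
mechanism (no aggregation), which holds for well-stabilised suspensions
with monotone size decay.

Three numerical details matter:

* **Branches.** At $n = 1$ the bracket degenerates; for $|n-1| < 10^{-8}$
  the exponential limit $d_{\mathrm{lim}} + (d_{50,0}-d_{\mathrm{lim}})e^{-kt}$
  is used, and the two branches agree to $10^{-6}$ relative where they
  meet. For $n < 1$ the bracket reaches zero at a finite extinction time;
  past it the function returns $d_{\mathrm{lim}}$ and flags those times in
  the `"extinct"` attribute rather than producing complex numbers.
* **Fitting.** `fit_breakage()` minimises squared residuals of
  $\log d_{50}$ (sizes span two decades, so log residuals weight the
  late, sub-micron part of the curve fairly) with the Levenberg–Marquardt
  algorithm (`minpack.lm`). $d_{50,0}$ is fixed at the $t=0$ observation:
  letting it float creates a near-degeneracy with $d_{\mathrm{lim}}$ on
  sparse late-time grids. $d_{\mathrm{lim}}$ is constrained below the
  final measured size, $n$ to $[0.5, 4]$. A deterministic 12-point
  multi-start grid over $(k, n, d_{\mathrm{lim}})$ guards against local
  minima; the lowest log-scale SSR wins, ties keeping the earlier start.
* **Fit statistics.** $R^2$, adjusted $R^2$ (3 parameters) and SSR are
  computed on the log scale, consistently with the objective. Because the
  scale convention is a genuine ambiguity when comparing against other
  software, the linear-scale $R^2$ and SSR are stored alongside
  (`R2_linear`, `SSR_linear`). A series with zero size variance is
  degenerate ($d_{\mathrm{lim}}$ can absorb the constant level) and is
  flagged via `boundary_k`.

`time_to_size()` reports the specific time $t_{d50}$ to reach a 0.2 µm
median. Following standard practice it interpolates the *measured* series
with a shape-preserving piecewise-cubic Hermite polynomial
(`pracma::pchipfun`, the MATLAB `pchip` analog) and finds the first
downward crossing by bracketed root finding; an observation exactly at the
target returns that time, and a series that never crosses returns an
explicit `crossed = FALSE` rather than an error. When the interpolant
touches the target tangentially, the earliest bracketing interval wins.
On the campaign's sampling schedule (t = 0, 40 s, then 1–180 min with
geometric spacing) the interpolation error near a crossing at ~5 min is
below 1%; the test suite bounds it by the interpolant's deviation divided
by the local curve slope.

## The microhydrodynamic model

The MHD model explains *why* a condition mills fast. Its state variable is
the granular temperature $\theta$ (m²/s²), one third of the mean-square
fluctuation velocity of the beads. The measured stirrer power density
$P_w = (P - P_{\mathrm{no-load}})/V_m$ is dissipated three ways — viscous
friction/lubrication between beads and suspension, partially inelastic
bead–bead collisions, and shearing of the beads-free suspension
($\varepsilon_{ht}$):

$$P_w = \frac{54\,\mu_L\,c\,\theta R_{\mathrm{diss}}}{D_b^2}
 + \frac{12}{D_b}\sqrt{\pi}\,(1-e^2)\,g_0\,c^2\rho_b\,\theta^{3/2}
 + \varepsilon_{ht}.$$

Both dissipation terms increase monotonically in $\theta$, so the
non-negative root is unique; `granular_temperature()` brackets it with
`uniroot` and polishes with Newton steps until the energy-balance residual
is below $10^{-10}$ relative (the test suite checks $10^{-8}$ across a
27-run sweep, plus agreement with a dense-grid bracketing oracle).

Closure relations, all from the kinetic theory of granular flows and
Hertzian contact mechanics:

* radial distribution at contact (Lun form):
  $g_0 = [1 - (c/c_{\mathrm{lim}})^{1/3}]^{-1}$, diverging at the packing
  limit $c_{\mathrm{lim}} = 0.63$;
* effective drag coefficient $R_{\mathrm{diss}}$: the dilute/dense drag
  polynomial plus a lubrication term $-c\,g_0\ln\varepsilon_m$ with
  cut-off $\varepsilon_m = 0.01$;
* single-bead oscillation frequency
  $\nu = 24\,c\,g_0\sqrt{\theta/\pi}/D_b$ and mean oscillation speed
  $u_b = \sqrt{8\theta/\pi}$;
* average maximum collision force
  $F_b^n = 1.96\,[Y_b/(1-\eta_b^2)]^{2/5}\rho_b^{3/5}R_b^2\,\theta^{3/5}$,
  contact radius $\alpha_b = [3(1-\eta_b^2)R_bF_b^n/(4Y_b)]^{1/3}$ and
  maximum contact pressure $\sigma_b^{\max} = 3F_b^n/(2\pi\alpha_b^2)$;
* capture probability $p$ of a drug particle of radius $R_p$ between
  colliding beads, and the compression frequency $a = p\,\nu \propto
  \theta^{9/10}/R_b^2$ — implemented both as the product and as the
  closed form, and required by the tests to agree to $10^{-10}$;
* pseudo-energy dissipation rate $\Pi\cdot\sigma_y \propto
  \theta^{13/10}$, a milling-intensity measure used only as a predictor.
  The drug volume fraction enters it as a single multiplicative constant
  whose placement is typographically ambiguous in the source material;
  since the quantity is consumed only after standardization by the
  prediction models, and in scaling tests, the choice is inconsequential
  (it is recorded in the function's documentation).

All collision-derived quantities are defined as 0 at $\theta = 0$ (the
continuous no-collision limit). Internally everything is strict SI;
µm, mL and rpm appear only at the I/O boundary.

Default material constants (`mhd_constants()`): restitution $e = 0.76$,
$\rho_b = 6000$ kg/m³, $Y_b = 200$ GPa, $\eta_b = 0.2$ for YSZ beads;
$Y_p = 11.5$ GPa, $\eta_p = 0.3$, $R_p = 5.7$ µm, volume fraction 0.061
for the drug; $V_m = 80$ mL. Bead mixtures are approximated as an
equivalent monodisperse charge at the arithmetic mean of the measured
median sizes (112/194/403 µm) — a deliberate first approximation; the
model makes no distinction between fine–fine, fine–coarse and
coarse–coarse collisions, which is exactly where its predictions for
mixtures are weakest.

## Predicting kinetics for unseen runs

`select_and_fit()` implements a deliberately simple protocol suited to a
24-run training set: fit every candidate (one regression per response on
$(k, n, d_{\mathrm{lim}})$), record the total (summed over responses)
leave-one-out CV RMSE as an overfitting check, and select by total RMSE on
the three held-out test runs, breaking ties by grid order. Responses are
not rescaled before summing — a documented convention, switchable by
rescaling the targets upstream. Two predictor modes exist: MHD parameters
$(\sigma_b^{\max}, \alpha_b, a, \Pi\cdot\sigma_y)$, standardized on the
training rows, and raw process parameters
$(\omega, c, x_{100}, x_{200}, x_{400})$ for the tree-based models.

The candidate grid — elastic-net mixing $\{0.1, 0.5, 0.9\}$ with penalties
log-spaced over $[10^{-4}, 10]$, ridge, plain linear, trees of depth 1–4
with minimum leaf $\{1, 2, 4\}$, and shallow gradient boosting — is small
on purpose: with $n = 24$, finer grids only reward noise. The process
predictors are exactly collinear ($x_{100}+x_{200}+x_{400}=1$), so the
plain linear candidate zeroes aliased coefficients rather than failing.
All stochastic libraries run single-threaded with exact tree methods, so
selection is deterministic and invariant to training-row order.

## Merit scores and bead economics

To rank conditions on more than speed, four metrics are min–max
normalized across the comparison set — inverse rate constant $1/k$ (or
$t_{d50}$), power $P$, and the number of intermittent milling cycles
$N_{d50}$ begun before the 0.2 µm target — and combined as

$$\mathrm{Merit} = 100 / 10^{(\bar m + \bar P + \bar N_{d50})/3},$$

which spans 10 (worst corner) to 100 (best corner) and decreases in each
argument. A degenerate metric (all runs equal) normalizes to 0 — the best
value — with a warning, keeping single-condition comparisons defined.
Both cycle-time variants are always computed; they rank identically
whenever $1/k$ and $t_{d50}$ are rank-concordant.

The economics module converts a Zr contamination measurement to a wear
rate (`wear_rate_from_contamination()`, oxide factor 1.351 = ZrO₂/Zr mass
ratio, configurable), a wear rate to a usable lifetime, and a lifetime to
a capital cost over a 9-year horizon under two replacement policies:
monthly (108 loads) or wear-threshold
($\lceil \mathrm{horizon}/\mathrm{lifetime} \rceil$ loads). Two lifetime
conventions are implemented because they are genuinely different: the
default 20% cumulative mass-loss threshold, and a nominal "5% median-size
reduction" rule (equivalent to $1-0.95^3 \approx 14.3\%$ mass loss for
geometrically similar wear). The default reproduces the reference
cost comparison; neither is claimed as canonical. Savings between bead
sizes are computed on unrounded costs — rounding first changes the
second digit.

## The synthetic study generator

`simulate_study()` emulates the full campaign the analysis stack expects:

* **Design** (`build_design()`): 24 training runs = {3000, 4000} rpm ×
  loadings {0.35, 0.50} × six bead charges (three narrow lots, three
  50-50 binary mixtures), plus three test runs at (3500 rpm, 0.43) with
  the single lots; sampling at $t = 0$, 40 s, $2^s$ min ($s = 0..7$), and
  24, 48, 96, 128, 180 min.
* **Ground truth** (`default_surface()`): log-linear response maps in
  $(\log\omega, \log c, \log \bar D_b)$ with an $\omega\times c$
  interaction, least-squares calibrated against the 24 bundled reference
  fits and clipped to the envelopes $k \in [0.1, 5.5]$, $n \in [1.1, 2.8]$,
  $d_{\mathrm{lim}} \in [0.05, 0.16]$ µm. By construction $k$ increases
  with speed and loading and decreases with bead size. Power follows
  $P \propto \omega^{2.5} c^{1}$ with a weak positive bead-size exponent
  (0.12) anchored at 60 W for the design centre; viscosity decreases with
  speed and loading, increases with bead size, and is clipped to the
  plausible 0.060–0.120 Pa·s range of concentrated polymer-stabilised
  suspensions.
* **Noise**: multiplicative lognormal on each size observation with
  CV 3% by default (replicate laser-diffraction scatter; the replicate-SD
  column is CV × value). $d_{10}$/$d_{90}$ are feed-ratio copies of the
  $d_{50}$ trajectory (4.30/11.4 and 23.5/11.4) — sufficient for
  span-style consumers, but carrying no independent information.
* **Thermal cycling** (`simulate_thermal_cycles()`): a single lumped heat
  balance $C_{th}\,\dot T = \eta_{heat} P - UA\,(T - T_{coolant})$,
  solved exactly as piecewise exponentials with closed-form hitting
  times. Milling pauses at 35 °C, resumes at 20 °C, with an 8 °C coolant.
  The constants ($\eta_{heat} = 0.9$, $UA = 3$ W/K, $C_{th} = 3000$ J/K)
  are nominal values for a small recirculating mill chosen so that
  low-power runs complete uninterrupted while the most energetic runs
  need on the order of ten cycles; only the cycle-counting *logic*, not
  absolute cycle counts, should be compared across systems, because real
  chiller characteristics are rig-specific. Milling segment durations
  always sum to the 180 min total exactly.
* **Reproducibility**: one master seed on the design; per-run child seeds
  are derived deterministically from it, and `simulate_run()` restores
  the caller's RNG state.

What passing tests on synthetic data do **not** show: the generator's
surface is smooth and log-linear, its noise is homoscedastic in relative
terms and independent across times, and its $d_{10}/d_{90}$ carry no
extra information — real campaigns have screen-clogging transients at
early times, drifting power readings, correlated replicate errors, and
bead-mixture physics the monodisperse MHD model cannot represent. The
parameter-recovery results therefore validate the *estimation machinery*,
not the physical adequacy of the models for any particular rig.

## Problem sizes and runtime choices

The test suite and examples run the full 27-run campaign (14 time points
per run), 50-seed noise-recovery replicates on a single representative
condition, a $10^6$-point grid oracle for the granular-temperature solver,
and the complete model-selection grid (~40 candidates × 24 LOO folds ×
3 responses); this keeps the default suite around five minutes on one
core. Larger sweeps scale linearly in runs and seeds.

## Known limitations

* The MHD model assumes monodisperse spheres; bead mixtures enter only
  through an averaged size, which is exactly where its predictive power
  degrades.
* $t_{d50}$ inherits interpolation error from the sampling schedule near
  the crossing (sub-1% at the default schedule, larger if the crossing
  falls in a sparse late-time interval).
* The thermal module is a single-capacity model with nominal constants;
  it is meant for counting cycles under a cutoff, not for predicting
  temperatures.
* Wear data exist only for the single-size bead lots; the economics module
  deliberately has no wear model for mixtures.
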