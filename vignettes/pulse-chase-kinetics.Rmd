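---
title: "Methods: pulse-chase kinetics of recombinant protein secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse-chase kinetics of recombinant protein secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secflux)
```

## The model and its assumptions

`secflux` describes a secreted recombinant protein in a chemostat with two
pools: intracellular protein `P_i` and extracellular protein `P_e`, both
expressed per gram yeast dry mass (YDM). Four first-order processes and one
zero-order source connect them:

$$\frac{dP_i}{dt} = \frac{q_{Pi}}{60} - (K_{Sec}+K_{Deg}+K_{Dil})\,P_i,
\qquad
\frac{dP_e}{dt} = s(P_i) - K_{Har}\,P_e,$$

with $s(P_i)=K_{Sec}P_i$ unconstrained or
$s(P_i)=\min(K_{Sec}P_i,\,q_{Sec,max}/60)$ when a secretion-capacity cap is
imposed. The assumptions this rests on:

- **First-order removal.** Secretion, degradation and dilution-by-growth
  each remove intracellular protein proportionally to the pool size;
  harvest removes extracellular protein proportionally to its pool. This
  is the standard formal kinetics for secretory protein traffic and is
  what makes the pulse-chase log-linear.
- **Chemostat steady state.** Biomass is not a state variable:
  concentrations are per gram YDM and YDM is constant in a steady-state
  chemostat. Both pools are at their fixed point before labeling starts.
- **`D = µ` and `K_Har = K_Dil`.** At viability of at least 99% the
  dilution rate equals the specific growth rate, so dilution into daughter
  cells and harvest of the medium share one time constant, `D/60` per
  minute. The estimation functions enforce this gate and refuse lower
  viabilities rather than silently proceeding.
- **Negligible re-labeling.** During a continuous ³⁴S labeling the ³²S
  share of new synthesis equals the residual ³²S fraction of the medium
  sulfate pool, which stays below 1%; the intracellular ³²S pool therefore
  decays essentially as $e^{-K_{tot}t}$ with
  $K_{tot}=K_{Sec}+K_{Deg}+K_{Dil}$.

### Units

One convention throughout: time constants `K` in min⁻¹, concentrations in
µg per g YDM, rates `q` in µg g⁻¹ h⁻¹. The single point where the two time
bases meet is the factor 60 inside the model functions (`q_Pi/60`,
`q_X = K_X · P_i · 60`); user code never converts.

### The capped variant

The cap acts on the secretion **flux term** only: it is continuous in
`P_i`, leaves the intracellular balance untouched, and makes the
extracellular steady state piecewise —
$P_e^* = s(P_i^*)/K_{Har}$ plateaus at $(q_{Sec,max}/60)/K_{Har}$ once
$K_{Sec}P_i^*$ exceeds the cap, which happens for formation rates above
`q_Pi_switch = q_Sec_max · K_tot / K_Sec` (reported by `steady_state()`).
Where the excess flux goes (enhanced degradation, aggregation) is outside
the model's scope; the cap only expresses that the medium cannot receive
more.

## Estimation chain

`estimate_fluxes()` runs, in order:

1. **Media gate.** The ³²S fraction of the small-molecule sulfur pool must
   stay below a threshold (default 1%) for the negligible-re-labeling
   assumption to hold. The gate warns by default and can hard-fail;
   measurement noise can push a nominally 1% series marginally over the
   line, which is why advisory is the default.
2. **Background correction** (`correct_background()`). Intracellular
   immunoprecipitates carry impurities whose sulfur shows up as a floor in
   the isotope ratio. All intracellular signal at `t >= cutoff_min`
   (default 140 min) is attributed to that background; its mean is
   subtracted (floored at zero) from the replicate's intracellular points.
   The correction is per replicate, because each cultivation has its own
   immunoprecipitation series. A linear time-trend variant
   (`method = "linear"`) is exposed but off by default: impurity carryover
   is plausibly time-invariant, and a constant is the weaker assumption.
   `background = "none"` skips the step for data known to be clean — that
   path is exact on ideal data, which the identity tests exploit.
   Note a consequence of the 140-min convention: with the reference
   constants (`K_tot ≈ 0.026 min⁻¹`) a few percent of true signal remains
   at 140–200 min, so the background is slightly over-estimated; the
   Monte-Carlo tests show the resulting bias on `K_Deg` is well under the
   10% recovery band.
3. **Log transform** (`transform_for_regression()`). `y = ln(frac32 /
   frac32_ref)` with the earliest usable post-correction intracellular
   point as reference. Because the regression keeps a free intercept the
   reference choice shifts the intercept only — the slope is invariant, and
   a property test pins that to 1e-12. Points flagged below the limit of
   quantification, or non-positive after background subtraction, cannot be
   log-transformed; they are excluded and counted, and a replicate must
   keep at least 3 points.
4. **Decay regression** (`fit_decay()`). Ordinary least squares per
   replicate; the slope estimates `-K_tot`, with a two-sided 95%
   confidence interval from the t-distribution. A non-negative slope is an
   error naming the replicate, since it signals a failed labeling rather
   than a parameter value.
5. **Constants.** `K_Dil = D/60` (viability-gated); `K_Sec = K_Dil · P_e /
   P_i` from the steady-state balance; `K_Deg = K_tot − K_Sec − K_Dil` per
   replicate, then averaged. A non-positive `K_Deg` is an error reporting
   all three inputs. When only the printed constants are available (no
   time series), `reference_flux_table()` takes `K_Deg` directly.
6. **Fluxes and uncertainty.** `q_X = K_X · P_i · 60`; `q_Pi` is their sum
   by construction, so the balance closes exactly. Across-replicate
   spread is summarised as relative standard deviation (sample SD over
   mean); single-replicate quantities get `NA`, not zero.

**A deliberate ambiguity.** With shared concentrations across replicates,
the mean slope 0.0249 min⁻¹ minus `K_Sec + K_Dil` gives
`K_Deg ≈ 0.0140 min⁻¹`, whereas per-replicate concentration pairings can
give values nearer 0.0151. The package computes `K_Deg` per replicate from
each replicate's own slope with the shared `K_Sec` and `K_Dil`, and also
accepts a directly supplied `K_Deg` through `reference_flux_table()`; both
paths are exposed rather than reconciled, because the data needed to
reconcile them (per-replicate concentrations) are not part of the standard
input.

## Sensitivity analysis

`sweep_titer()` varies two of {`t_half_Deg`, `t_half_Sec`, `q_Pi`}
multiplicatively against the steady-state titer. Design choices:

- **Fold axes are log-spaced in [0.1, 10]** (default 41 points per axis,
  with the baseline fold 1 guaranteed on the grid). A "±10-fold" change of
  a rate parameter is read as multiplication by 0.1–10; a negative rate
  constant is meaningless.
- **Half-time axes** are converted to rate constants (`K = ln 2 / t½`)
  before evaluation, so a fold `f` on a half time divides the constant by
  `f`. "Improvement" means longer `t_half_Deg` (slower degradation),
  shorter `t_half_Sec` (faster secretion), larger `q_Pi`.
- **Titer = analytic steady state**, not an ODE endpoint at a finite
  horizon. The uncapped model is linear, so every grid node has a closed
  form, and the tests require grid/closed-form agreement to 1e-9. An ODE
  endpoint at, say, 8 h would still be ~20% short of steady state on the
  slow harvest eigenvalue (`t½ ≈ 416 min`), which is a plausible origin of
  small discrepancies between analytic fold changes (≈2.39 for 10-fold
  faster secretion, ≈2.10 for 10-fold slower degradation, ≈2.73 combined,
  5075 µg/g at 10-fold formation) and coarser readouts of the same
  surfaces; `simulate_pools()` provides the endpoint cross-check for
  anyone who wants it.
- `plateau_analysis()` reports the capped ceiling `(q_Sec_max/60)/K_Har`
  and the closed-form single-parameter folds that reach it (for the
  reference parameters with a 2× cap: doubling `q_Pi`, or slowing
  degradation ≈7-fold).

## The synthetic-data generator

`generate_experiment()` replaces the wet-lab experiment. It emulates:

- the chase itself, via the **exact closed-form solution** of the linear
  label kinetics from a fully-³²S steady state (sums of exponentials, with
  the confluent `t·e^{-Kt}` branch that always arises because
  `K_Har = K_Dil`) — not a numeric ODE, so generator and solver stay
  independent and can cross-check each other;
- residual ³²S sulfate: initial fraction 1% (the documented upper bound),
  washing out first-order at `K_Dil` and feeding a matching ³²S share into
  new synthesis — the generator does *not* assume the approximation the
  estimator makes, which is what makes recovery a fair test;
- multiplicative lognormal measurement noise, unit mean, CV 5% (the
  instrument's long-term repeatability); ratios are positive and the error
  is quoted as relative, hence lognormal rather than Gaussian;
- a constant intracellular impurity background, default 0.02 (the true
  magnitude is not documented anywhere, so this is a placeholder exercised
  over a range in tests); extracellular ratios get none, as impurities are
  seen only in cell-lysate immunoprecipitates;
- a limit of quantification on the ratio (default 0.005) and random
  dropouts (default 10%) reproducing samples lost to insufficient
  signal-to-noise;
- sampling every 10 min (up to 6/h) over an 8 h chase, 2 replicate
  cultivations.

The cultivation record defaults to the truth's analytic steady state with
viability 0.995: concentration measurement error is **not** simulated, so
`K_Sec` and `K_Dil` recovery is exact by construction and the Monte-Carlo
statements about them are statements about the chain's bookkeeping, not
about concentration assays. Real data add ~10% concentration uncertainty
that propagates into `K_Sec` and all `q` values; passing recovery tests do
not cover that, and `propagate_uncertainty()` exists precisely to carry
replicate spread through when real replicate concentrations are available.
Per-cell heterogeneity, immunoprecipitation recovery efficiency and
mass-spectral interferences are likewise out of scope.

All randomness flows from one mandatory seed; the RNG state is restored
afterwards so the generator does not perturb the caller's stream.

## Numerical choices

- ODE integration: `deSolve::ode` with `lsoda` (stiff-capable implicit
  multistep), `rtol = 1e-8`, `atol = 1e-10`, both exposed. Solver failure
  surfaces the diagnostics; it is never silent.
- The closed forms use the confluent branch when two eigenvalues are
  within 1e-12 of each other.
- Zero-residual regressions (noiseless fixtures) yield degenerate
  confidence intervals; `fit_decay()` collapses non-finite interval ends
  onto the slope instead of propagating `NaN`.
- Observed fractions are clipped to `[0, 1]` after noise (a ratio cannot
  leave that range physically; clipping at `t = 0` with a background is
  the only place it routinely binds).
- Fold grids guarantee an exact baseline node so surface invariants can be
  asserted without interpolation.

## Problem sizes in the test suite

The Monte-Carlo studies use a 12-point decay window (0–110 min, 10-min
spacing) plus an 11-point post-cutoff window (150–480 min, 30-min spacing)
for background estimation, two replicates, 200 seeded repetitions for both
the recovery study and the confidence-interval calibration; dropout is
disabled there so the per-replicate point count is fixed by design. These
sizes were chosen as the smallest that give stable Monte-Carlo
proportions; single runs use the full default schedule.

## Known limitations

- The model is deliberately unstructured below the two-pool level: no ER /
  Golgi compartments, no unfolded-protein-response feedback, no
  amino-acid-level labeling kinetics. `K_Deg` lumps every intracellular
  loss route.
- The 140-min background convention slightly over-subtracts when `K_tot`
  is small (see above); for substantially slower proteins the cutoff
  should be lengthened to ≥ `5/K_tot`.
- The capped model says nothing about the fate of unsecreted excess
  protein.
- Estimates inherit the steady-state premise; transient cultures (batch,
  fed-batch) violate every balance used here.
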