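# secflux

Kinetic modeling and stable-isotope pulse-chase estimation of recombinant
protein secretion fluxes in continuous culture.

## The problem

When a yeast such as *Pichia pastoris* secretes a recombinant protein, the
titer in the medium is the tail end of a balance that the culture hides:
protein is formed inside the cell, and from there it is either secreted,
degraded intracellularly (e.g. via ER-associated degradation), or passed to
daughter cells as the culture grows. Deciding whether to engineer folding,
secretion capacity or gene dosage requires numbers for each of those
fluxes, measured under production-like (carbon-limited, bioreactor)
conditions. `secflux` implements the structured kinetic model and the full
analysis chain for a continuous ³⁴S sulfate labeling experiment in a
chemostat, where the decay of the pre-existing ³²S protein acts as a chase
and ³²S/³⁴S isotope ratios (measured by HPLC-ICP-MS) trace the turnover of
the intra- and extracellular protein pools.

## The model

Two pools, first-order kinetics, concentrations per gram yeast dry mass
(YDM), time constants `K` in min⁻¹ and rates `q` in µg g⁻¹ h⁻¹:

```
dP_i/dt = q_Pi/60 − (K_Sec + K_Deg + K_Dil) · P_i
dP_e/dt = s(P_i) − K_Har · P_e ,   s(P_i) = min(K_Sec · P_i, q_Sec_max/60)
```

At chemostat steady state (dilution rate `D`, viability ≥ 99% so `D = µ`
and `K_Har = K_Dil = D/60`):

- `K_Sec = K_Dil · P_e / P_i` from the extracellular balance;
- the intracellular ³²S fraction decays as `exp(−K_tot · t)` with
  `K_tot = K_Sec + K_Deg + K_Dil`, so an ordinary least-squares fit of
  `ln(frac32)` against time gives `K_tot`, and `K_Deg` follows by
  subtraction;
- fluxes close the balance: `q_X = K_X · P_i · 60` and
  `q_Pi = q_Sec + q_Deg + q_Dil`;
- half times are `t½ = ln 2 / K`.

Intracellular immunoprecipitates carry an impurity background, estimated
from late samples (default: t ≥ 140 min) and subtracted before the
regression. A pairwise sensitivity module sweeps formation, secretion and
degradation against the steady-state titer, optionally under a secretion
capacity cap that produces a titer plateau. A synthetic-data generator
emulates the whole labeling experiment (5% instrument CV, impurity
background, residual unlabeled sulfate washing out at `D`, limit of
quantification, sample dropouts) with known ground truth.

## Worked example

From the measured chemostat quantities — `D = 0.1 h⁻¹`, intracellular
91.8 µg/g, extracellular 507.5 µg/g, degradation constant
`K_Deg = 0.0151 min⁻¹` — the flux table:

```r
library(secflux)
cult <- cultivation_record(dilution_rate = 0.1, P_i = 91.8, P_e = 507.5)
reference_flux_table(cult, K_Deg = 0.0151)
#>   flux q_ug_g_h K_per_min half_time_min percent_of_qPi
#> 1   Pi   143.10        NA            NA        100.000
#> 2  Deg    83.17  0.015100         45.90         58.120
#> 3  Sec    50.75  0.009214         75.23         35.465
#> 4  Dil     9.18  0.001667        415.89          6.415
```

Of the 143 µg of protein formed per gram YDM and hour, about 58% is
degraded inside the cell, 35% reaches the medium, and 7% is inherited by
daughter cells.

The same estimates can be recovered from a complete in-silico labeling
experiment (two replicate cultivations, 8 h chase, realistic noise):

```r
truth <- kinetic_params(q_Pi = 143.1, K_Sec = 0.0092, K_Deg = 0.0151,
                        K_Dil = 0.1 / 60)
design <- experiment_design(truth, seed = 42)
experiment <- generate_experiment(design)
estimate_fluxes(experiment$series, design$cultivation)
#> Intracellular flux estimates (34S pulse-chase)
#>
#>  flux q_ug_g_h K_per_min half_time_min percent_of_qPi
#>    Pi  146.123        NA            NA        100.000
#>   Deg   86.237  0.015648         44.29         59.017
#>   Sec   50.700  0.009200         75.34         34.697
#>   Dil    9.185  0.001667        415.89          6.286
#>
#> Mean decay slope magnitude K_total = 0.02652 min^-1 (2 replicates)
#> Media small-molecule 32S max: 1.026%
```

With the secretion flux capped at twice its measured value
(`q_Sec_max = 101.4 µg g⁻¹ h⁻¹`), the titer plateaus:

```r
plateau_analysis(truth, cap = 101.4)
#> $plateau_P_e      1014        # µg/g ceiling of the extracellular titer
#> $baseline_q_Sec   50.7
#> $q_Pi_fold        2           # doubling formation reaches the cap
#> $t_half_Deg_fold  7.13        # degradation must slow ~7-fold to reach it
```

A YAML-driven pipeline (`run_pipeline()`) and a thin command-line wrapper
(`inst/cli/secflux.R`, subcommands `synth`, `simulate`, `estimate`,
`sensitivity`) bind these steps together and write CSV artifacts plus a
JSON run report with provenance (config fingerprint, seed, versions).

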