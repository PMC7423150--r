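# ignitome

Whole-brain mean-field ignition analysis on weighted structural
connectomes. The package is for computational neuroscientists who want to
ask: *given a connectome, which regions can sustain an "ignited"
(high-firing) state, at what global coupling strength, and how is that
decided by the network's weighted core–shell organisation?*

## The model and the analysis

Each region is a reduced Wong–Wang neural mass,

dS_i/dt = −S_i/τ_S + (1 − S_i) γ R_i,  R_i = (aχ_i − b) / (1 − e^{−d(aχ_i − b)}),
χ_i = w J_N S_i + J_N G Σ_j C_ij S_j + I_0,

coupled through the weighted connectome C and a global coupling gain G.
Sweeping G under low vs high initial conditions maps a hysteresis region
[G−, G+]: between the *ignition point* G− and the *flaring point* G+ the
steady state depends on the initial conditions, and the set of regions
ignited at G− (the *ignition core*) coincides with the connectome's
maximal weighted s-core when the core's mutual weights are strong enough.
The package provides:

* `connectome()` / `read_connectome()` / `write_connectome()` — dense-matrix
  and edge-list I/O with strict validation,
* `planted_core_connectome()` / `hagmann_like_connectome()` — synthetic
  connectomes with a planted strong core (66 nodes, 1148 connections, mean
  weight 1.332e-2 by default),
* `node_strengths()`, `k_core_decomposition()`, `s_core_decomposition()`,
  `small_world_sigma()` — local, mesoscale and global network metrics,
* `build_ensemble()` — the six surrogate null ensembles (homogeneous-weight,
  degree-preserving rewired, small-world matched; each also weight-permuted),
* `run_sweep()`, `detect_bistable_range()`, `first_ignition_profile()`,
  `rank_r2()`, `bootstrap_r2()`, `run_full_analysis()` — the ignition
  pipeline and its statistics.

## Worked example

```r
library(ignitome)

g <- hagmann_like_connectome(seed = 1)   # synthetic 66-region connectome
sw <- run_sweep(g$connectome, sim_params(),
                sweep_config(g_min = 0.3, g_max = 2.2, g_step = 0.02))
detect_bistable_range(sw)
#> <bistability range> G- = 0.640 (11 ignited, F- = 16.7%), G+ = 1.880 (58 ignited, F+ = 87.9%)

s_core_decomposition(g$connectome)
#> <core decomposition> max level 0.7412, 11 member(s) in the maximal core
```

The bistable range opens at G− = 0.64, where exactly the 11 planted
strong-core regions ignite (F− = 16.7% of 66), and closes at G+ = 1.88
with 58 of 66 regions ignitable (F+ ≈ 88%). The 11-member maximal s-core
recovered by the weighted core decomposition is exactly the ignition core.
Contrast with a weight-permuted surrogate, which needs roughly twice the
coupling to first ignite (G− ≈ 1.4 on the same grid): heterogeneous strong
mutual weights, not the wiring pattern alone, are what make early, compact
ignition possible.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Regenerates the synthetic reference connectome, runs the full pipeline
(gain sweep on both branches, bistable-range detection, core
decompositions, first-ignition profile, bootstrap rank correlations) and a
weight-permuted null contrast, printing the report; the JSON output records
the run.

## Layout

* `R/`, `src/` — implementation (R front-end, compiled integrator)
* `tests/testthat/` — unit, property and acceptance suites with
  brute-force/root-finding oracles
* `vignettes/ignition-analysis.Rmd` — model, assumptions, parameter
  meanings, numerical choices, limitations
* `scripts/acceptance.R` — end-to-end run
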