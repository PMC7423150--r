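---
title: "Ignition dynamics and the weighted core of a connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ignition dynamics and the weighted core of a connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignitome)
```

## The scientific question

Cortical regions can switch from a low-firing baseline to a sustained
high-firing "ignited" state, a bistability thought to underlie working
memory and access to a global workspace. When bistable neural masses are
coupled through a structural connectome, which regions ignite first, and at
what global coupling strength, is decided by the network — in particular by
its *weighted core–shell organisation*. `ignitome` provides the complete
computational pipeline for studying this: deterministic mean-field
simulation on a weighted connectome, a coupling-gain sweep that maps the
hysteresis (bistable) region, weighted s-core and binary k-core
decompositions, surrogate-connectome null ensembles, and bootstrap
rank-correlation statistics relating ignition order to network structure.

## The model

Each region `i` carries a reduced Wong–Wang neural mass with a single
gating variable $S_i \in [0,1]$ (open NMDA fraction):

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\,R_i, \qquad
R_i = \frac{a\chi_i - b}{1 - e^{-d\,(a\chi_i - b)}},$$

$$\chi_i = w\,J_N\,S_i + J_N\,G \textstyle\sum_j C_{ij} S_j + I_0 .$$

$C_{ij}$ is the connection weight from region $j$ to region $i$; the
coupling gain $G$ scales all long-range input relative to local recurrence.
Defaults are $\tau_S = 100$ ms, $\gamma = 0.641$, $a = 270$ (V·nC)$^{-1}$,
$b = 108$ Hz, $d = 0.154$ s, $w = 0.9$, $J_N = 0.2609$ nA, $I_0 = 0.3$ nA.
With $w = 1$, $I_0 = 0.322$ a single isolated node is bistable
(`isolated_fixed_points()` finds stable/unstable/stable); with the network
defaults it is monostable, so any bistability observed in the network is a
collective effect of the coupling:

```{r}
isolated_fixed_points(sim_params(I_0 = 0.322, w = 1))
isolated_fixed_points(sim_params())  # network defaults: monostable
```

Units: the equations are treated as dimensionally consistent with the
printed constants (the convention of the source literature); internally all
times are seconds, rates Hz. Integration is plain forward Euler at
$\Delta t = 1$ ms (the model's stiffness is mild, $\Delta t \le \tau_S/10$
is enforced), with $S$ clamped to $[0,1]$ after each step as an overshoot
guard and no noise anywhere — the analysis concerns the deterministic
attractor structure.

### Steady-state detection

Runs integrate until $\max_i |dS_i/dt| < 10^{-9}\,\mathrm{s^{-1}}$ holds
for 100 consecutive steps, capped at 120 s of simulated time (the cap
reproduces the fixed-duration protocol; early exit is an optimisation).
The threshold is set three orders of magnitude tighter than strictly
needed for branch classification because the package also promises
agreement with multivariate root-finding oracles to $10^{-6}$ Hz: near a
fixed point the state error is the residual divided by the slowest
eigenvalue, and rate sensitivities of order $a = 270$ Hz/nA amplify it.
At a looser $10^{-6}\,\mathrm{s^{-1}}$ that guarantee would not hold.

## The sweep and the bistable range

`run_sweep()` scans $G$ (paper protocol: $0.5 \le G \le 5$, $\Delta G =
0.01$) twice per grid point: from Low initial conditions ($S_i \sim
U[0, 0.1]$) and High initial conditions ($S_i \sim U[0.3, 1]$). A region is
*ignited* when its steady rate exceeds 5 Hz (strict inequality). The
network state is summarised by $R_{\max}$, the largest steady rate over
regions; `detect_bistable_range()` marks a grid point bistable when the two
branches' $R_{\max}$ differ by more than `branch_gap` (1 Hz), giving the
ignition point $G_-$ and the flaring point $G_+$. The *ignition core* is
the ignited set on the high-IC branch at $G_-$.

Repetitions (`reps = 60` under `paper_protocol = TRUE`) re-draw the initial
conditions within each regime; because the dynamics are deterministic and
branch membership empirically never depends on the draw, the desk default
is one repetition, with cross-repetition mask consistency checked and
flagged when requested.

## Synthetic connectomes: what the generator emulates

`hagmann_like_connectome()` stands in for the 66-region average human DSI
connectome that the original analysis used (not redistributable here): 66
nodes, 1148 nonzero directed entries laid out symmetrically (574 pairs)
with independent ±10% log-normal per-direction jitter so in- and
out-strengths differ, weights right-skewed log-normal (`sdlog = 1`,
a modelling choice — the empirical weight distribution's form is not
published) rescaled so the nonzero mean is exactly $1.332\times10^{-2}$,
and a planted 11-node fully connected core whose mutual weights are
boosted sixfold.

Within-core weights are drawn with a tenth of the off-core log-dispersion
(`core_sdlog = sdlog/10`). This is deliberate: the structure being planted
is a *compact core of comparably strong mutual weights*, which is what
makes the clique fall in a single cascade of the s-core peeling and hence
*be* the maximal s-core. With full dispersion inside the core, one extreme
reciprocal pair out-ranks the clique and the planted set is recovered in
only about half of realizations — a different (and unintended) stated
world. With the default, the planted set is the realized $s_{\max}$-core in
20/20 test seeds, and the full pipeline recovers it as the ignition core:

```{r, eval = FALSE}
g <- hagmann_like_connectome(seed = 1)
sw <- run_sweep(g$connectome, sim_params(),
                sweep_config(g_min = 0.3, g_max = 2.2, g_step = 0.02))
rg <- detect_bistable_range(sw)
setequal(rg$ignition_core, g$core)    # TRUE
```

What a green synthetic test does **not** establish: the generator has no
spatial embedding, no hemispheric symmetry, no distance-dependent weight
decay, and its degree distribution is binomial rather than the empirical
one. Quantities tied to the empirical matrix ($G_- = 0.945$,
$s_{\max} = 0.431$, $\sigma = 1.63$, $\rho^2 = 0.867$, ...) are therefore
not reproduced by the synthetic world; the pipeline that computes them is
exercised end-to-end, and loading the empirical matrix through
`read_connectome()` runs the identical code path.

## Core decompositions

`k_core_decomposition()` works on the binarized undirected projection
(edge iff either direction is nonzero) — degree-based measures in this
literature are standard-unweighted. `s_core_decomposition()` uses the
weighted analogue with *total* (in + out) within-subgraph strength,
matching the strength definition used for node metrics. Both use the same
recursive peeling engine: the removal level only ratchets upward, all nodes
at or below the current level are removed in whole passes with strengths
recomputed after every pass (order-independence), and a node's coreness is
the level at which it falls. Levels are therefore located exactly at
attained strengths; the `shell_width` parameter (default $s_{\max}/100$)
only bins coreness into shells for reporting. Maximal cores may have any
size ≥ 1 member; no minimum is imposed. Correctness is pinned against
exhaustive-subgraph oracles (all $2^n$ induced subgraphs at $n = 8$) and,
for the k-core, against igraph's independent implementation.

`small_world_sigma()` computes $\sigma = (\gamma/\gamma_{\mathrm{rand}}) /
(\lambda/\lambda_{\mathrm{rand}})$ with mean local clustering (isolated and
degree-1 nodes counting 0) and characteristic path length on the binarized
projection, normalised by the mean over $n_{\mathrm{random}} = 100$
connected Erdős–Rényi references with matched node and edge counts. The
reported dispersion is the standard error of per-reference $\sigma$
estimates; a *single* graph scored against its own ensemble scatters at the
per-reference SD, not the SE.

## Surrogate ensembles

Six null models isolate which aspect of the connectome drives ignition
(`build_ensemble()`): homogeneous-weight (`*_hw`) ensembles set every link
to the reference's mean weight — the same wiring (`human_hw`),
degree-preserving Maslov–Sneppen rewirings (`dpr_hw`, 10 attempted swaps
per edge), or Watts–Strogatz graphs selected for matching small-worldness
(`sw_hw`: generate 1000, keep the 100 closest in $\sigma$; lattice degree
chosen to match the reference edge count, rewiring probability drawn
log-uniformly on $[0.01, 0.5]$ — selection, not construction, matches the
target, since the original construction parameters are unstated).
Weighted (`*_rw`) ensembles permute the reference's weight multiset
uniformly onto those structures. Default sizes follow the reference
protocol (100 hw, 60 rw members); all member seeds derive deterministically
from one master seed, so ensembles regenerate bit-exactly.

## Statistics

Ignition order is related to structure by the squared Spearman rank
correlation between each node's first-ignition $G$ (the smallest grid value
from which it stays ignited on the high-IC branch; transient flickers are
logged, not counted) and its s-coreness or strength. Never-ignited nodes
have no first-ignition value; the default censors them (the censored count
is reported) and `run_full_analysis()` additionally reports the variant
that retains them at just above the grid maximum, since either convention
is defensible. Uncertainty comes from bootstrap resampling of node pairs
(10 000 replicas in the reference protocol) with (2.5, 97.5) percentile
intervals; two correlations are called different when their intervals do
not overlap — no multiple-testing correction, matching the source
convention. Coverage of the percentile interval was validated at ~95% on
500 synthetic bivariate-normal datasets of $n = 66$ (the parcellation
size) with population Spearman $\rho = (6/\pi)\arcsin(r/2)$, $r = 0.5$.

## Numerical choices and edge cases

* Transfer-function singularity at $a\chi = b$: series expansion
  $1/d + x/2 + dx^2/12$ for $|a\chi - b| < 10^{-9}$.
* `steady_state(tol = Inf)` returns the initial state immediately with
  `converged = TRUE` (degenerate contract); hitting the time cap reports
  `converged = FALSE` via the flag, never an exception.
* Fixed-point search for isolated nodes: dense sign-change bracketing
  (2000 grid points on $S\in[0,1]$) + bisection to $10^{-12}$; stability
  from the sign of the RHS derivative.
* Ties in peeling are removed in whole passes; s-core scaling covariance
  (all weights × c ⇒ all corenesses × c) is exact and tested.
* Edge lists are 0-based `source target weight`; matrices are
  whitespace-delimited text. Weights are never renormalised on load.

## Limitations

**The flaring point is an $R_{\max}$-level notion, not a node-level one.**
$R_{\max}$ is a scalar proxy for the network state; implementing the
definition exposed a genuine subtlety: just above the detected $G_+$, the
two branches can converge to *distinct, fully converged attractors that
differ in a single weak node* (5–11 Hz at that node) while $R_{\max}$
differs by under 0.05 Hz, because $R_{\max}$ saturates among the strong,
already-ignited nodes. No $R_{\max}$ threshold can see this sub-dominant
bistability, so "both branches coincide node-wise outside the bistable
range" holds below $G_-$ but not, in general, above $G_+$. The package
keeps the $R_{\max}$ definition (it is the field's) and additionally
reports the node-wise envelope (`g_minus_nodewise`, `g_plus_nodewise`)
outside which node-level coincidence does hold; one acceptance-suite
assertion states the idealised node-wise claim literally and is expected
to fail, as a permanent record of this behaviour.

Other limitations: no stochastic simulations or BOLD forward model; no
perturbational ("intrinsic ignition") transient analysis — the pipeline
characterises equilibria only; surrogate small-world matching assumes a
Watts–Strogatz family; the synthetic generator makes no claim of matching
any empirical connectome beyond the statistics listed above.
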