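# ctlesion

Functional imaging studies in multiple sclerosis report contradictory
connectivity findings: both increases and decreases correlate with disease
burden. `ctlesion` provides a fully controlled, simulation-based way to ask
how that can happen, for computational neuroscientists and network
neuroimagers. It couples a corticothalamic neural mass model — per region a
cortical excitatory/inhibitory pair and a thalamic relay/reticular pair —
over a structural connectome, drives it with relay-population noise, and
measures MEG-like outcomes while white matter, cortical or thalamic
structure is degraded step by step.

## Model

Population firing is a sigmoid of membrane potential,
`Q(V) = Q_max / (1 + exp(-(V - θ)/σ))`. Each potential obeys a second-order
synapto-dendritic equation; the excitatory population of region *j*
additionally receives delayed fields from its structural neighbours,

```
D V_e,j = ν_ee φ_e,j + ν_ei Q_i,j + ν_es Q_s,j(t − τ_ct)
          + (ε/N) Σ_n A_jn φ_e,n(t − τ_jn),
```

with `D = (1/αβ) d²/dt² + (1/α + 1/β) d/dt + 1`, and the outgoing field is
damped at rate γ. The system is integrated by Euler–Maruyama at
`dt = 1e-4 s` with ring-buffered delays; the first 2 s (20,000 samples) are
discarded. Outputs are the excitatory cortical fields only, band-passed to
the alpha band (8–13 Hz, the model's dominant rhythm).

Outcome measures per simulation: mean alpha **activity** (region-averaged
band-limited power), mean **PLV** (phase-locking value over all region
pairs from analytic-signal phases), and two topology measures on the
maximum spanning tree of the PLV matrix — **diameter** (longest shortest
path, in hops; inverse integration) and **leaf fraction** (fraction of
degree-1 nodes; segregation).

Damage experiments scale, linearly from the intact baseline:
predilection-site white-matter edges (up to 14%), within-cortical-unit
densities region-wise by a cortical atrophy map, or within-thalamic-unit
densities globally by the thalamic volume ratio
`1 − 18.50/20.78 ≈ 11%`.

## Worked example

```r
library(ctlesion)

ctm <- generate_connectome(n_regions = 40, edge_density = 0.15, seed = 1)
p   <- ct_params()

calibrate_alpha(p, ctm)$peak_frequency
#> [1] 9.5

sim <- euler_maruyama_run(p, ctm, duration = 16, seed = 1)
fn  <- plv_matrix(bandpass_alpha(sim$phi, sim$fs))
fn
#> <functional_network> 40 regions, mean PLV 0.209, mean activity 42.13

mst_summary(fn)
#> <spanning_tree_summary> 40 regions: diameter 13 hops, leaf fraction 0.400
```

The dominant rhythm sits at 9.5 Hz, inside the alpha band; mean PLV ≈ 0.21
is clearly above the independent-phase floor (≈ 0.11 at this window
length), i.e. the network is partially synchronized. A full damage
experiment runs all iterations × realizations and aggregates mean ± SD
curves:

```r
maps <- generate_damage_maps(ctm, wm_site_fraction = 0.5, seed = 2)
sch  <- damage_schedule("white_matter", maps, n_iterations = 10)
traj <- run_experiment(sch, p, ctm, n_realizations = 5, base_seed = 101)
summarize_trajectory(traj)$mean_activity
#> <curve_summary> mean_activity: trend rho -0.76 (p 0.017), peak at iteration 3
```

Under white-matter damage, activity declines (significant negative rank
trend, after a small initial rise) while mean PLV follows a rise-then-fall
curve; cortical and thalamic degeneration instead raise
both activity and connectivity — two opposite connectivity responses from
one model, depending on which tissue is damaged.

`ms_damage_study()` wraps the whole protocol (connectome + maps + all three
schedules), and `inst/scripts/ctlesion` exposes `generate`, `simulate` and
`experiment` subcommands for shell use.

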