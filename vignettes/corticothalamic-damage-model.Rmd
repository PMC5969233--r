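---
title: "Modelling white and grey matter damage in a corticothalamic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling white and grey matter damage in a corticothalamic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ctlesion` simulates MEG-like resting-state activity with a corticothalamic
neural mass model. Each network *unit* contains four neural populations:
cortical excitatory (e), cortical inhibitory (i), thalamic relay (s) and
thalamic reticular (r). For population $a$ in region $j$, the mean firing
rate is a sigmoid of the mean membrane potential,

$$Q_{a,j} = \frac{Q_{\max}}{1 + \exp(-(V_{a,j}-\theta)/\sigma)},$$

and each membrane potential is driven by the synaptically weighted firing of
its afferents through a second-order synapto-dendritic filter
$D_a = \tfrac{1}{\alpha\beta}\tfrac{d^2}{dt^2} + (\tfrac1\alpha + \tfrac1\beta)\tfrac{d}{dt} + 1$
with rise rate $\beta$ and decay rate $\alpha$. The excitatory population of
region $j$ receives, besides its within-unit inputs, delayed excitatory
fields from every structurally connected region:

$$D_a V_{e,j} = \nu_{ee}\phi_{e,j} + \nu_{ei}Q_{i,j}
  + \nu_{es}Q_{s,j}(t-\tau_{ct})
  + \frac{\epsilon}{N}\sum_{n \ne j} A_{jn}\,\phi_{e,n}(t-\tau_{jn}),$$

where $A$ is the structural adjacency matrix, $\epsilon$ the global coupling
strength, $\tau_{ct}$ the one-way corticothalamic delay and $\tau_{jn}$ the
inter-regional delay (Euclidean distance over a conduction velocity). The
outgoing excitatory field is damped at rate $\gamma$:
$(\tfrac{1}{\gamma^2}\tfrac{d^2}{dt^2} + \tfrac{2}{\gamma}\tfrac{d}{dt} + 1)\,\phi_{e,j} = Q_{e,j}$.
The spatial Laplacian of the full field formulation is dropped (all
observables are position-independent apart from the network term), and only
the excitatory cortical fields are used as output, mirroring the fact that
MEG mainly reflects cortical pyramidal activity. Zero-mean Gaussian white
noise enters the relay population alone, as
$\nu_n \phi_{\mathrm{noise}}$ with
$\phi_{\mathrm{noise}} = \sigma_n \alpha \beta \chi(t)$; an optional tonic
relay drive `phi_n0` (sensory input, default 0) is also available.

Inhibitory synaptic densities ($\nu_{ei}, \nu_{ii}, \nu_{sr}$) are stored as
negative numbers so the equations are implemented exactly as sums. The
thalamic input to the inhibitory population reuses $\nu_{es}$ (the
random-connectivity convention $\nu_{is}=\nu_{es}$); a separate `is` entry
can be set in `ct_params()` to decouple them.

## Integration

The coupled second-order delay equations are rewritten as first-order pairs
and integrated with the Euler–Maruyama scheme at `dt = 1e-4` s; noise is
scaled by $\sqrt{dt}$. Delays are rounded to the nearest step and served
from ring buffers holding $\phi_e$ (network and corticothalamic terms) and
$Q_s$ (the delayed relay feedback onto cortex). The pre-simulation history
is pinned at the noise-free steady state, found by damped Newton iteration
on the algebraic fixed-point system with continuation in $\epsilon$ (the
low-firing branch is tracked from the uncoupled single-unit solution). The
first 2 s — exactly 20,000 samples at the default step — are discarded as
startup transient, and the retained fields are block-averaged to an output
rate of 250–500 Hz, far above twice the analysis band. A blown-up state
aborts the run with the step index; the experiment driver records such
cells and continues.

## Default parameters and calibration

The exact working-point values of the resting-state literature this model
descends from are not reproduced verbatim; instead the package ships a
documented default set in that lineage and *gates* it on its spectral
behaviour (`calibrate_alpha()`): the shipped defaults must place the
dominant peak of the region-averaged spectrum inside the alpha band
(8–13 Hz). The defaults were fixed by a linearised transfer analysis of the
unit (sharp resonance near 9.5 Hz from the delayed corticothalamic loop,
$2\tau_{ct} = 80$ ms) followed by simulation at increasing coupling, using
baseline criteria only: an in-band dominant peak and a baseline mean PLV
(~0.21) clearly above the finite-sample null level (~0.11) yet far from
saturation.

Two structural choices deserve note:

* **Asymmetric cortical inhibition.** With $|\nu_{ei}| > |\nu_{ii}|$ the
  partially saturated high-firing state (where the inhibitory population
  equilibrates mid-sigmoid and can no longer veto cortical runaway) is
  eliminated; without it, that attractor captures the dynamics at any
  useful coupling strength.
* **Near-critical coupling.** $\epsilon = 0.3$ sits on the rising flank of
  the synchrony-vs-coupling curve and below the collapse boundary
  ($\epsilon \approx 0.5$ for the default network), so graded damage moves
  the system smoothly rather than across a bifurcation.

Key defaults (all overridable via `ct_params()` or a YAML config):
$Q_{\max}=250$ s⁻¹, $\theta=15$ mV, $\sigma=6$ mV, $\alpha=50$ s⁻¹,
$\beta=200$ s⁻¹, $\gamma=100$ s⁻¹, $\tau_{ct}=40$ ms,
$\nu = (ee\,1.2,\ ei\,{-3.09},\ es/is\,0.6,\ ie\,1.2,\ ii\,{-3.0},\
se\,4.5,\ sr\,{-0.8},\ re\,0.4,\ rs\,0.2,\ n\,0.5)$ mV·s,
$\epsilon=0.3$, $\sigma_n=10^{-3}$, conduction velocity 10 m/s. The delay
between regions uses that velocity because none is fixed by the protocol;
10 m/s is a standard myelinated cortico-cortical value and is exposed as an
argument everywhere it enters.

## The synthetic structural substrate

No empirical tractography matrix is shipped. `generate_connectome()` builds
a binary, symmetric, connected graph with mirrored hemispheres and
distance-dependent connection probability ($\propto e^{-d/45\,\mathrm{mm}}$
over brain-scale coordinates), emulating the gross organisation of
atlas-based cortical networks: short-range connections dominate, homotopic
regions sit symmetrically. It does **not** reproduce the degree sequence,
modular layout or specific tracts of any empirical connectome, so
conclusions supported by the tests are about damage-response *shapes* on a
generic spatially embedded network, not about any one brain. Likewise
`generate_damage_maps()` emulates the three damage substrates: a
predilection-site edge mask biased toward long (periventricular-like)
connections covering half the edges by default, a per-region cortical
atrophy map drawn uniformly from 2–20% (the range of published regional
cortical-thickness losses in longstanding MS), and the thalamic maximum
computed from published mean thalamic volumes, $1 - 18.50/20.78 \approx
11\%$. The white-matter maximum is 14%, the tract-strength loss reported
in MS tractography.

## Virtual lesions

Damage is always applied as a fractional reduction *from the intact
baseline* — the final schedule point hits the stated maximum exactly, with
no multiplicative compounding:

* white matter: adjacency weights on masked edges scaled by $1-f$, $f \le 0.14$;
* cortical: within-cortical-unit densities $\{\nu_{ee},\nu_{ei},\nu_{ie},\nu_{ii}\}$
  scaled region-wise by the atrophy map (the corticothalamic densities
  $\{es, se, re, is\}$ belong to neither schedule);
* thalamic: within-thalamic-unit densities $\{\nu_{sr},\nu_{rs}\}$ scaled
  globally by up to 11%.

`run_experiment()` walks a linear schedule (first iteration intact, last at
maximum), repeating each iteration across stochastic realizations whose
seeds derive from a per-cell hash of `(base_seed, iteration, realization)`,
so every cell is independently reproducible. Outcomes per cell: mean
alpha-band activity (region-averaged variance of the 8–13 Hz zero-phase
FIR-filtered signal, one filter length trimmed at each edge), mean PLV
(analytic-signal phases, full post-transient window, strict upper-triangle
average), and the diameter and leaf fraction of the maximum spanning tree
of the PLV matrix (the strongest-connection backbone; ties broken
lexicographically for reproducibility, diameter reported in hops).

## Problem sizes

The full-scale protocol (78 regions, 20 iterations, 50 realizations) is the
default of `ms_damage_study()`. The test suite and the acceptance script
run a scaled-down study — 40 regions at density 0.15, 10 iterations, 5
realizations, 16 s of activity per run — which preserves every structural
feature of the full protocol while completing in minutes. The vignette's
statements about curve shapes refer to what those scaled runs themselves
compute.

## Numerical choices and edge cases

* Steady-state Newton tolerance $10^{-10}$ mV (max-norm); line search
  accepts only improving steps and the solver warns if the residual stays
  above $10^{-8}$.
* PLV matrices are symmetrised to machine precision, clamped to $[0,1]$,
  with an exactly unit diagonal; an all-zero channel is an error naming the
  channel rather than a silent NaN.
* The band-pass is a Hamming-window FIR with a ~3 Hz transition band
  (order $2\lceil 1.65 f_s/3\rceil$), run forward–backward for zero phase;
  series shorter than three filter lengths are rejected.
* Spanning-tree functions reject disconnected or cyclic inputs; the
  spanning tree of an already-tree-shaped graph is returned unchanged.
* `summarize_trajectory()` reports Spearman rank trends with permutation
  p-values (iteration labels shuffled across realization cells) and an
  inverted-U detector that requires an interior maximum to clear both
  endpoints by a configurable margin.

## Known limitations

* The PLV response to the white-matter schedule is weak at the shipped
  working point: a 14% reduction confined to half the edges shifts mean PLV
  by roughly its between-realization standard deviation, so the rise-then-
  fall connectivity signature is at the edge of detectability in small
  studies — unlike the activity decline, which is robust.
* Grey-matter demyelination (within-unit delays) and conduction-velocity
  heterogeneity are out of scope, as is any forward model from fields to
  MEG sensors.
* The synthetic atrophy map is uniform-random over its range; empirical
  regional patterns are spatially structured, which matters for any claim
  about *which* regions drive topology changes (none is made here).

## Persistence

Everything the package writes is plain text: dense TSV matrices with JSON
sidecars for simulations and functional networks, edge-list TSVs for trees
and masks, per-cell and aggregate TSVs for trajectories. A binary container
would be faster for long recordings, but text keeps every artefact
diff-able and portable; the sampling-rate decimation (block averaging to
250–500 Hz) keeps the files small.
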