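---
title: "Modelling inflammation and inferring cell communication from transfer-entropy networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inflammation and inferring cell communication from transfer-entropy networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflanet)
```

## The model

`inflanet` simulates an episode of tissue inflammation driven by mechanical
strain and/or pathogens, and infers the macrophage–fibroblast communication
structure from the simulated cell trajectories. The simulator is a
multi-layer agent-based model on a bounded 2-D lattice:

* **Epithelium** — one cell per site, cycling through *alive*, *dead*,
  *healing* and *fibrosis* states.
* **Cytokine fields** — TNF (pro-inflammatory) and TGF (anti-inflammatory)
  concentrations, one value per site, obeying a diffusion–dissolution
  equation $\partial_t \phi = D \nabla^2 \phi - K \phi$.
* **Motile cells** — macrophages guided by TNF and fibroblasts guided by TGF,
  performing biased random walks with collision avoidance.
* **Pathogens** — unbiased random walkers, spawned by a periodic replication
  schedule and removed by adjacent activated macrophages (phagocytosis).
* **Strain** — a uniform scalar $s \in [0, 1]$ over the whole grid
  (the mechanical time scale is much faster than the inflammatory one, so
  only its average level matters).

One tick applies, in fixed order: field diffusion and decay; activation and
stochastic secretion; motile movement (macrophages then fibroblasts, shuffled
within kind by the seeded generator); pathogen movement, phagocytosis and
replication; epithelial transitions. Fixing the order is what makes a seeded
run bit-reproducible; the order itself is a modelling choice, since the rule
set does not dictate one.

### Epithelial rules

1. All sites start alive.
2. A live site dies by apoptosis with per-tick probability given by the beta
   CDF with shapes $(a, b)$ evaluated at $\min(\mathrm{TNF}/\mathrm{tnf_{ref}}, 1)$.
   A CDF is used (rather than a density) because the requirement is a
   monotone map from TNF level to death probability that is 0 at no TNF and
   saturates at 1.
3. A dead site with at least one fibroblast in its Moore neighbourhood enters
   *healing* for `th` ticks, then revives. When a connected patch of healing
   sites completes, one uniformly chosen member of the patch becomes a
   *fibrosis* (scar) site for `th` ticks.
4. A new fibrosis site damages its surroundings once, at creation: each live
   neighbour dies with probability $N_f / N_{nei}$, the fraction of its own
   neighbourhood occupied by fibrosis.
5. A dead site revives by mitosis with per-tick probability `p_mitosis`.

Two readings of rules 3–4 were possible, and the choice matters a great
deal. If every healed *site* spawns a scar, and a scar re-draws death for
all 8 neighbours every tick of its `th = 100`-tick life, each scar kills
essentially its whole neighbourhood and each killed cell becomes a new scar
after healing: the scar "reproduction number" is far above 1 and the tissue
enters a chronic state that never resolves. Reading the rules as
one-scar-per-healed-patch and damage-drawn-once-at-creation gives a
reproduction number below 1, so scarring churns briefly and dies out — which
is the behaviour an acute inflammatory episode must show. The package
defaults to the resolving reading; the chronic variants remain available via
`sim_params(fibrosis_damage = "per_tick")` for studying non-resolving
fibrosis.

### Motile-cell rules

Candidate moves are the 8 Moore neighbours plus "stay". Each candidate's
weight is the guiding cytokine's value at the candidate site plus a small
$\varepsilon = 10^{-6}$, zeroed for occupied sites; weights are normalised.
With no cytokine anywhere this reduces to an unbiased random walk. The move
set is Moore (cell motion spans the eight compass directions on this
lattice); a Neumann variant is available via `move_neighborhood`.

Macrophages latch to *activated* on pathogen contact (Moore adjacency) or by
a per-tick strain draw with probability $\min(\texttt{strain\_act} \cdot s, 1)$.
Activated macrophages secrete TNF with probability
$\mathrm{clamp}(1 - \mathrm{TGF}/\theta_{TGF},\, 0,\, 1)$ — secretion is
suppressed by the anti-inflammatory signal at their own site. Fibroblasts
latch to activated when local TNF is positive and secrete TGF with
probability $\mathrm{clamp}(1 - \mathrm{TNF}/\theta_{TNF},\, 0,\, 1)$.
Each secretion deposits `secrete_amount` at the cell's site.

### Pathogens

Pathogen count pressure follows a rectified sinusoid: at ticks that are
multiples of `replication_period`, $\mathrm{round}(\max(0, A \sin(2\pi t/\alpha)))$
pathogens appear at random free sites (a raw sinusoid would go negative; the
negative phase simply means no inhalation). The study conditions use
$A = 1$, $\alpha = 25$. The default `replication_period = 40` is deliberately
incommensurate with $\alpha$: sampling every 50 ticks, say, would always hit
the same phase of a 25-tick sine — a zero crossing — and no pathogen would
ever spawn.

Phagocytosis requires the macrophage to be activated (default). This is what
couples the stimulus history to pathogen control: under sustained strain the
whole macrophage pool hunts from the start, whereas without strain only
macrophages that have already met a pathogen do, so pathogen suppression is
weaker and across-trial variability grows.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| grid | 100 × 100 | sites | tissue patch (test profile: 50 × 50) |
| `n_macrophages`, `n_fibroblasts` | 50, 50 | cells | conserved over a run (test profile: 20, 20) |
| `n_steps` | 8000 | ticks | episode length (test profile: 2000) |
| `beta_a`, `beta_b`, `tnf_ref` | 2, 2, 1 | —, —, conc. | apoptosis dose–response |
| `th` | 100 | ticks | healing and scar duration |
| `p_mitosis` | 0.001 | 1/tick | baseline tissue repair |
| `strain_act` | 0.01 | 1/tick per unit *s* | strain-driven activation rate |
| `secrete_amount` | 0.5 | conc. | deposit per secretion event |
| `secrete_theta_tgf` | 0.5 | conc. | TGF level that silences TNF secretion |
| `secrete_theta_tnf` | 5 | conc. | TNF level that silences TGF secretion |
| `D` | 0.2 | sites²/tick | diffusion constant (both fields) |
| `K_tnf`, `K_tgf` | 0.01, 0.002 | 1/tick | dissolution constants |
| `amplitude`, `alpha`, `replication_period` | 1, 25, 40 | counts, ticks, ticks | pathogen schedule |

Values not dictated by the model description were chosen once, on
biological and dynamical grounds, and then frozen:

* **Asymmetric dissolution** (`K_tnf = 0.01`, `K_tgf = 0.002`). The steady
  reach of a point source is $\sqrt{D/K}$ sites, so TNF is a sharp,
  short-lived signal (reach ≈ 4.5 sites, half-life ≈ 70 ticks) while TGF
  accumulates and blankets the tissue (reach ≈ 10 sites, time constant
  500 ticks). This mirrors the biology — TNF-α is cleared in minutes, active
  TGF-β persists — and it is dynamically necessary: with symmetric constants
  the anti-inflammatory field never reaches the macrophage clusters (which
  chemotax up their own TNF and sit far from fibroblasts), TNF secretion
  never stops, and the injury curve plateaus instead of recovering.
* **Asymmetric secretion thresholds** (`secrete_theta_tgf = 0.5`,
  `secrete_theta_tnf = 5`). The negative feedback is potent (a modest TGF
  level silences macrophages) and robust (fibroblasts keep producing TGF
  even in a TNF-rich environment). With both thresholds at the same scale
  the two arms deadlock in a mixed steady state.
* `strain_act = 0.01` makes full macrophage activation take a few hundred
  ticks at high strain — slow enough that strain level visibly shifts the
  timing of the inflammation phase, fast enough to fit an 8000-tick episode.

With these defaults the model produces the canonical acute time course: the
inflammation score (dead epithelial count / 1000) rises quickly, peaks in the
first half of the episode, and decays as TGF shuts down TNF secretion while
mitosis and fibroblast-mediated healing repair the tissue. Raising strain
makes the rise faster and the peak earlier.

## Communication inference

The premise is that if a macrophage influences a fibroblast (via the
cytokine relay), the influence shows up in the fibroblast's *turning
behaviour*. From each cell's track the displacement vectors
$m_t = p_t - p_{t-1}$ give the turning angle

$$\theta_t = \arccos \frac{m_t \cdot m_{t-1}}{|m_t||m_{t-1}|} \in [0, \pi],$$

which on a Moore lattice takes the five values
$\{0, \pi/4, \pi/2, 3\pi/4, \pi\}$. Ticks where the cell stayed put yield an
undefined angle; these are kept as an explicit *no-move* sentinel and treated
as a sixth symbol downstream, both because staying put is informative
behaviour and because dropping samples would break the time alignment that
pairwise analysis needs. Angles are binned to symbols with width 0.005 rad
(`discretize_angles()`); any width below $\pi/4$ keeps the five lattice
angles distinct, so the estimator is insensitive to the exact value in that
range.

For each (macrophage, fibroblast) pair the **transfer entropy**

$$T_{M \to F} = \sum p(F_t, F_{t-1}, M_{t-1})
  \log_2 \frac{p(F_t \mid F_{t-1}, M_{t-1})}{p(F_t \mid F_{t-1})}$$

is estimated by plug-in joint frequencies with history length 1, in bits,
clamped at zero, with no bias correction — the raw estimate is compared
against an empirical threshold derived from the same distribution, so a
common bias largely cancels. The macrophage is the source and the fibroblast
the target by default (predicting the fibroblast's next turn); both the
reverse orientation and the symmetrised maximum are available via the
`direction` argument. A permutation-null utility (`te_permutation_null()`)
is provided for calibrating what finite-sample bias alone produces.

**TE networks.** Within each sliding window (default 200 ticks stepped by
100 — long enough that pair counts stabilise against the ~6-symbol alphabet,
short enough to resolve the episode's phases) the pairwise TE matrix is
computed, and a bipartite graph over macrophage and fibroblast nodes is built
by starting from the complete edge set and deleting edges that fail the
threshold criterion. The threshold $T_C$ is the third quartile of that
window's own TE distribution (edges kept iff $T > T_C$); an interquartile
band mode (keep $Q_1 < T \le Q_3$) and a fixed threshold are also provided,
since "derived from the first and third quartiles" admits both readings.
Quartiles use R's default linear-interpolation convention (type 7).

**Centrality dynamics.** Eigenvector centrality $Ac = \lambda c$ is computed
by power iteration on $A + I$ (same eigenvectors; the shift breaks the
$\pm\lambda$ symmetry of bipartite adjacency spectra, without which power
iteration oscillates), to tolerance $10^{-10}$, normalised to sum to 1 over
all nodes. Isolated nodes get centrality 0; in a disconnected graph the
vector concentrates on the component with the largest eigenvalue. `Mc` and
`Fc` are the arithmetic means over macrophage and fibroblast nodes (means,
not sums, so the ratio is invariant to group sizes), and the summary
statistic is `Fc/Mc`: above 1, fibroblasts dominate the communication
structure. Windows with edgeless networks or `Mc = 0` yield `NA` rather than
an error, so time courses keep their length through low-communication
regimes.

## Synthetic fixtures and what they validate

`generate_coupled_pair()` produces symbol pairs with analytically known
transfer entropy: the source is i.i.d. uniform over `k` symbols and the
target copies it at a lag with probability `c`. The closed form
(`te_lagged_copy_analytic()`) is the mutual information of the noisy copy
channel — 1 bit at `k = 2, c = 1`, 0 at `c = 0`. `generate_random_walk_tracks()`
produces unbiased, collision-avoiding lattice walks: the no-communication
null for the whole pipeline.

These fixtures validate the estimator's calibration, directionality recovery
and null behaviour — but they are i.i.d.-driven processes with a single lag,
while real (and simulated) cell tracks have autocorrelated, non-stationary
turning behaviour. Passing the fixture tests therefore shows the estimator
is correct, not that a thresholded TE value on tissue data identifies a
causal cell pair; in the tissue analysis TE is used comparatively (against
the same window's distribution), which is the only use the package's results
depend on.

Similarly, the simulator emulates the collective phenomenology — injury
rise and recovery, strain-accelerated onset, pathogen suppression, the
fibroblast-dominated middle phase — not any specific tissue's physiology:
cells occupy single sites, secretion is binary, strain does not alter
locomotion, and there are no neutrophils or adaptive immunity. Conclusions
from this package are statements about the model.

## Numerical choices

* **Field solver**: explicit FTCS with the 5-point Laplacian, `dt = dx = 1`,
  no-flux boundaries via clipped neighbour sums (mass-conserving by
  construction when `K = 0`); stability requires `D * dt <= 0.25`, enforced
  at construction. Decay is applied multiplicatively after the diffusion
  sub-step (operator splitting), keeping each sub-step testable in
  isolation.
* **Lattice cosines**: turning-angle cosines are computed as
  `dot / sqrt(|m_t|^2 * |m_{t-1}|^2)` — one square root of an integer
  product — so lattice angles come out exact instead of accumulating
  `sqrt(2)*sqrt(2) != 2` noise.
* **Determinism**: all stochastic rules consume one seeded generator in a
  fixed order (sites in ascending linear order, cells shuffled within kind,
  macrophages before fibroblasts), so identical `(params, seed)` give
  bit-identical traces.
* **Degenerate inputs**: constant symbol series give TE exactly 0; edgeless
  networks raise an error from `eigenvector_centrality()` but propagate as
  `NA` through `centrality_timecourse()`; `Mc = 0` gives an `NA` ratio, not
  an exception.
* **Scaled test profile**: the test suite and the acceptance script run a
  50 × 50 grid, 20 + 20 cells, 2000 ticks and 5 trials (`scaled_params()`).
  The cell count keeps 400 TE pairs per window — enough for a meaningful
  quartile threshold — while a full 15-run study completes in about two
  minutes; the full-scale profile (`sim_params()` defaults) is the
  documented configuration for study-size runs.

## Known limitations

* The TE estimator is plug-in, positively biased at short windows; only
  within-window comparisons (quartile thresholding) are bias-robust.
  Kernel/KSG estimators, longer histories and per-edge significance testing
  are out of scope (a permutation utility is provided instead).
* The Fc/Mc peak timing is a noisy statistic at the test scale: with 5
  trials its relation to the recovery onset holds as a majority, not per
  run.
* Movement spans 8 directions; steric effects, strain-dependent locomotion
  and continuous space are not modelled.
* With `fibrosis_damage = "per_tick"` the model deliberately enters a
  chronic, non-resolving regime; the acute defaults are calibrated as
  described above and changing the secretion/dissolution asymmetries can
  return the system to deadlock.

## A minimal run

```{r, eval = FALSE}
library(inflanet)
sim <- simulate_inflammation(scaled_params(strain = 0.8), seed = 42)
glance(sim)

fcmc <- sim$tracks |>
  turning_angles() |>
  te_network_timecourse(window = 200, step = 100) |>
  centrality_timecourse()

plot_fc_mc(fcmc)
autoplot(sim)
```
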