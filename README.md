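# inflanet

Agent-based simulation of tissue inflammation and inference of macrophage–
fibroblast communication networks from cell trajectories.

## What it does, and for whom

Inflammation is a collective process: macrophages and fibroblasts steer each
other through diffusing cytokines (TNF pro-inflammatory, TGF
anti-inflammatory), and the course of an inflammatory episode — how fast
injury rises, whether pathogens are suppressed, how the tissue recovers —
emerges from that exchange. `inflanet` is for computational biologists who
want to (1) simulate inflammation episodes driven by mechanical strain
and/or pathogens, and (2) quantify *who is talking to whom* directly from
cell tracks, without observing the cytokines.

The simulator is a multi-layer lattice model: epithelial sites that die
(TNF-dose-dependent apoptosis via a beta CDF), heal (fibroblast contact) and
scar (fibrosis); two diffusing–dissolving cytokine fields
(∂φ/∂t = D ∇²φ − K φ); chemotactic macrophages and fibroblasts; random-walk
pathogens spawned on a rectified sinusoidal schedule Pc(t) = A sin(α·t) and
cleared by activated macrophages. The injury readout is the **inflammation
score**: dead epithelial count / 1000.

The inference side works from tracks alone. Each cell's turning angle

    θ_t = arccos( m_t · m_{t−1} / (|m_t||m_{t−1}|) ),  m_t = p_t − p_{t−1}

is discretised into symbols, and for every (macrophage M, fibroblast F) pair
the **transfer entropy**

    T_{M→F} = Σ p(F_t, F_{t−1}, M_{t−1}) log2 [ p(F_t | F_{t−1}, M_{t−1}) / p(F_t | F_{t−1}) ]

measures, in bits, how much the macrophage's past movement reduces
uncertainty about the fibroblast's next turn beyond the fibroblast's own
past. Within sliding time windows, pairs whose TE exceeds the third quartile
of that window's TE distribution become edges of a bipartite **TE network**;
eigenvector centrality (Ac = λc) summarises each class's influence, and the
ratio of mean fibroblast to mean macrophage centrality, **Fc/Mc**, tracks
which cell class dominates communication as the episode unfolds.

## Worked example

A reduced-scale episode under high strain with pathogens (50 × 50 tissue,
20 macrophages + 20 fibroblasts, 2000 ticks):

```r
library(inflanet)

sim <- simulate_inflammation(scaled_params(strain = 0.8), seed = 42)
sim
#> <inflam_sim> 50 x 50 grid, 20 macrophages + 20 fibroblasts, 2000 ticks (seed 42)
#>   strain s = 0.80, pathogen amplitude A = 1
#>   peak inflammation score 0.924 at tick 505; final score 0.223
```

Injury rises quickly (924 of 2500 epithelial sites dead at the peak, tick
505 — an inflammation score of 0.924), then the anti-inflammatory feedback
shuts TNF secretion down and the tissue recovers to a score of 0.223 by the
end of the run. The communication time course from the same run:

```r
fcmc <- sim$tracks |>
  turning_angles() |>
  te_network_timecourse(window = 200, step = 100) |>
  centrality_timecourse()
fcmc
#> # A tibble: 18 × 5
#>   window_start window_end     fc     mc fc_mc
#>          <dbl>      <dbl>  <dbl>  <dbl> <dbl>
#> 1            2        201 0.0241 0.0259 0.932
#> 2          102        301 0.0249 0.0251 0.989
#> 3          202        401 0.0240 0.0260 0.921
#> # …

fcmc$window_start[which.max(fcmc$fc_mc)]
#> [1] 702
recovery_onset(sim$timecourse)
#> [1] 500
```

Fc/Mc peaks in the window starting at tick 702, right at the onset of the
recovery phase (tick 500, within one TE window) — fibroblasts dominate the
communication structure exactly when the tissue turns the corner. Multi-trial
studies (`experiment_plan()` + `run_experiment()`) aggregate inflammation
curves, pathogen-count mean/SD across trials, and per-trial Fc/Mc courses;
`autoplot()` and `plot_fc_mc()` draw them; `tidy()`/`glance()` give tabular
summaries.

Estimator calibration on ground truth:

```r
pair <- generate_coupled_pair(k = 2, coupling = 1, lag = 1, n = 10000, seed = 1)
transfer_entropy(pair$source, pair$target)
#> [1] 0.9998823   # analytic value: 1 bit
```

A command-line front end over the same functions is installed at
`system.file("cli", "inflanet.R", package = "inflanet")` with subcommands
`simulate`, `infer`, `experiment` and `fixtures`.

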