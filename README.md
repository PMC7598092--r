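# brainmass

Long-horizon simulation of whole-brain dynamics as a network of neural mass
oscillators with axonal conduction delays and ongoing synaptic plasticity.

Studying slow processes — synaptic reorganization over hours, disease-related
connectivity drift — requires simulating *biological time*, not neuron count:
millisecond resolution sustained for hours of activity. `brainmass` targets
exactly that regime: each brain region is a three-population neural mass
(cheap enough to run for hours of biological time), regions are coupled
through a structural connectome with conduction delays, and the integrator's
memory is bounded by a circular history buffer so the horizon can grow
without the footprint growing with it. It is intended for computational
neuroscientists who want a transparent, fully scriptable R implementation of
this model class with a test-backed numerical core.

## The model

Each region holds an excitatory population `E`, a subtractive-inhibitory
population `Is` (raises the effective threshold) and a divisive-inhibitory
population `Id` (divides the gain). With the three-argument logistic

$$F_j(x,\theta,a) = \frac{1}{1+e^{-\frac{a_j}{1+a}(x-(\theta_j+\theta))}} - \frac{1}{1+e^{\frac{a_j\theta_j}{1+a}}},\qquad
k_j = \lim_{x\to\infty}F_j,$$

region *i* evolves by the delay differential system

$$\tau_e \dot E_i = -E_i + (k_e-E_i)\,F_e\big(w_1E_i + \sum_{j\ne i}W_{ij}E_j(t-d_{ij}) + P_e,\; w_2 Is_i,\; w_3 Id_i\big)$$
$$\tau_i \dot{Is}_i = -Is_i + (k_i-Is_i)\,F_i(w_4E_i+P_s,0,0)$$
$$\tau_i \dot{Id}_i = -Id_i + (k_i-Id_i)\,F_i(w_5E_i+P_d,\; w_6 Is_i + w_7 Id_i,\;0)$$

Weights come from streamline tractography counts, `W_ij = 0.1 ln S_ij`;
delays from fiber lengths at 7 m/s. Integration is the fixed-step (1 ms)
Bogacki–Shampine RK(2,3) pair with cubic Hermite dense output over a ring
buffer for the delayed lookups. Every 10 steps, existing connections update
by the Hebbian rule `ΔW_ij = c · E_j(t−d_ij) · (E_i(t) − E_i(t−1))` with
synaptic normalization (incoming weights rescaled to unit sum), and the
seven within-region weights update by the analogous pre/post rule with
per-node conservation. See `vignettes/brainmass-methods.Rmd` for every
modeling and numerical decision.

## Worked example

```r
library(brainmass)

con <- synthetic_connectome(n = 82, p = 0.2, seed = 1)
con
#> <connectome> 82 regions, 1343 directed connections (density 0.202)
#>   weights in [0.06931, 0.5964], delays in [2.878, 21.43] ms

sim <- run_chunked(con, population_params(),
                   engine_config(t_end = 10000),           # 10 s biological
                   plasticity = plasticity_config(c = 0.01),
                   recorder = recorder_config(interval = 5000))
sim
#> <brainmass_sim> 82 regions, 10000 ms simulated in 10000 steps of 1 ms
#>   snapshots: 3
#>   rhs evaluations: 31001, coupling multiply-adds: 4.163e+07, plasticity cycles: 1000
#>   max embedded error estimate: 8.36e-06, buffer capacity: 26, wall 8.85 s
```

Reading the numbers: 82 regions at 20% density give 1343 external
connections; the longest fiber (150 mm at 7 m/s) needs 21.4 ms of history,
so the ring is auto-sized to 26 entries. 10,000 steps cost 3×10,000 + 1
regular stage evaluations plus one refresh per plasticity cycle
(31,001 total; the fourth stage is recycled — FSAL), each touching all 1343
connections (≈ 4.2×10⁷ multiply-adds). The embedded error estimate staying
near 10⁻⁵ says the 1 ms step resolves these dynamics comfortably.

Results are tidyverse-friendly:

```r
library(dplyr)
tidy(sim) |>
  filter(time == 10000) |>
  group_by(variable) |>
  summarise(mean = mean(value))
#> # A tibble: 3 × 2
#>   variable   mean
#>   <chr>     <dbl>
#> 1 E        0.0122
#> 2 Id       0.0113
#> 3 Is       0.0117
```

(the default parameters relax toward a low-activity equilibrium — they are
package choices, not published values, and everything is overridable).
`tidy(sim, "weights")` gives the long-format weight trajectories,
`glance(sim)` a one-row run summary, `autoplot(sim)` and
`plot_weight_matrix(sim)` quick ggplot figures.

Long runs stream to disk with bounded memory:

```r
cfg <- simulation_config(connectome = list(n = 82, p = 0.2),
                         engine = engine_config(t_end = 100000),
                         plasticity = plasticity_config(c = 0.01),
                         seed = 7, out_dir = "snapshots/")
sim <- run_simulation(cfg)      # 100 s -> snapshots at t = 0, 50, 100 s
read_series("snapshots/")       # lossless round trip
```

A thin CLI wraps the same functions (`inst/cli/sim.R`):

```sh
Rscript inst/cli/sim.R gen-connectome --n 82 --p 0.2 --seed 1 --out con/
Rscript inst/cli/sim.R run --config run.json
Rscript inst/cli/sim.R bench --sizes 2,10,25,50 --p 0.2 --plasticity on --bio-time 1000
Rscript inst/cli/sim.R export --in snapshots/ --out activities.csv
```

## Snapshot store layout

`manifest.json` (region count, interval, snapshot times, run metadata:
config hash, seed, package version), `activities.csv` (long format:
`time, region, variable, value`), and per-snapshot `snap_<k>_W.csv` /
`snap_<k>_internal.csv` weight matrices. All floats carry 17 significant
digits, so reading the store back reproduces the run bit-exactly; the
manifest is refreshed after every appended snapshot, so an interrupted run
still leaves a valid store.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
a seeded 82-region synthetic connectome, 100 s of biological time at 1 ms
with Hebbian plasticity and normalization, snapshots every 50 s — and writes
its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
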