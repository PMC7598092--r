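---
title: "Methods: delayed neural mass networks with synaptic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed neural mass networks with synaptic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmass)
```

## The model

`brainmass` simulates whole-brain activity as a network of coupled neural
mass oscillators, one per brain region. Each region holds three interacting
populations described by their mean firing-rate proxies: an excitatory
population $E$, a subtractive-inhibitory population $I_s$ and a
divisive-inhibitory population $I_d$. The two inhibition modes act
differently on the excitatory input–output function: subtractive inhibition
shifts it to higher inputs (raising the effective threshold), divisive
inhibition scales down its slope and maximum (gain control).

The population input–output function is a three-argument logistic,

$$F_j(x,\theta,a) \;=\; \frac{1}{1+\exp\!\big[-\tfrac{a_j}{1+a}\,\big(x-(\theta_j+\theta)\big)\big]}
\;-\; \frac{1}{1+\exp\!\big[\tfrac{a_j\theta_j}{1+a}\big]},
\qquad j\in\{e,i\},$$

where $x$ is the driver, $\theta$ the subtractive modulator, $a \ge 0$ the
divisive modulator, and $a_j,\theta_j$ the gain and threshold constants. The
subtraction of the constant second term centers the curve so that
$F_j(0,0,0)=0$, making the origin an equilibrium of the unforced system. The
saturation value

$$k_j \;=\; \lim_{x\to\infty} F_j(x,\theta,a) \;=\;
\frac{e^{a_j\theta_j/(1+a)}}{1+e^{a_j\theta_j/(1+a)}}$$

doubles as the refractory ceiling of each population.

Per region $i$ in an $n$-region network, the dynamics are the delay
differential system

$$\tau_e \dot E_i = -E_i + (k_e - E_i)\,
  F_e\!\Big(w_1 E_i + \textstyle\sum_{j\neq i} W_{ij}\, E_j(t-d_{ij}) + P_e,\;
  w_2 I_{s,i},\; w_3 I_{d,i}\Big)$$
$$\tau_i \dot I_{s,i} = -I_{s,i} + (k_i - I_{s,i})\, F_i(w_4 E_i + P_s,\, 0,\, 0)$$
$$\tau_i \dot I_{d,i} = -I_{d,i} + (k_i - I_{d,i})\,
  F_i(w_5 E_i + P_d,\; w_6 I_{s,i} + w_7 I_{d,i},\, 0)$$

with $w_1\ldots w_7$ the seven internal (within-region) weights, $P_e, P_s,
P_d$ constant external drives, $W$ the inter-region weight matrix (row =
target, column = source) and $d_{ij}$ the axonal conduction delay. Only
excitatory populations project between regions.

### The refractory "constants"

The formula for $k_j$ contains the divisive input $a$, yet the model treats
$k_j$ as a constant. The package follows the constant reading: $k_e, k_i$
are evaluated once at configuration time with $a = 0$. Because the
alternative reading is defensible, `population_params(dynamic_k = TRUE)`
recomputes $k_e$ at every evaluation from the instantaneous divisive input
$w_3 I_d$; the default stays static.

### Default parameters

The source model never prints its parameter values, so the defaults below
are package choices, selected once to give bounded, well-behaved activity in
a single node (with the default drives the network relaxes to a stable
low-activity equilibrium) and kept fixed thereafter. All are plain arguments of
`population_params()`.

| parameter | default | meaning |
|---|---|---|
| $\tau_e$ | 5 ms | excitatory response time constant |
| $\tau_i$ | 10 ms | inhibitory response time constant (both populations) |
| $a_e, a_i$ | 1 | sigmoid gains |
| $\theta_e, \theta_i$ | 4 | sigmoid thresholds |
| $w_1\ldots w_7$ | 2.4, 1, 1, 2, 2, 0.5, 0.5 | internal weights (E→E, Is→E, Id→E, E→Is, E→Id, Is→Id, Id→Id) |
| $P_e, P_s, P_d$ | 0.5 | external drives |

## Connectivity

Inter-region weights are initialized from streamline tractography counts
$S_{ij}$ as $W_{ij} = 0.1\,\ln S_{ij}$ for $S_{ij}>0$ and $0$ otherwise
(natural log by default, `log10` available); delays are fiber trajectory
lengths over a 7 m/s propagation speed, i.e. $d_{ij} = L_{ij}/7$ in ms for
$L$ in mm. `W` is treated as directed: tractography is symmetric, but
plasticity breaks the symmetry after the first update.

The **synthetic connectome generator** stands in for imaging-derived
matrices: each ordered pair is connected independently with probability
$p = 0.2$ (the empirical density of inter-region connections), counts are
drawn as $2 + \mathrm{Geom}(\text{mean }48)$ and lengths uniform on 20–150
mm. The count law is not specified by the source; this choice puts the
weights $0.1\ln S$ in $\approx 0.07$–$0.6$ and the delays in
$\approx 2.9$–$21.4$ ms, the scales the real matrices are described to have.
What the generator does *not* emulate: the log-normal-ish heavy tail of real
streamline counts, distance-dependent connection probability, hemispheric
symmetry, and any correlation between count and length. A green test on
synthetic data therefore establishes the correctness of the machinery, not
biological realism of any particular run.

## Integration

The system is integrated with the explicit Bogacki–Shampine (2,3) pair —
four stages, third-order solution, embedded second-order estimate, FSAL — at
a **fixed step** of 1 ms. Fixed rather than adaptive stepping reproduces the
stated operating regime and keeps runs bit-reproducible; the embedded error
estimate is still computed every step, its running maximum is reported in
`glance()`, and a warning is emitted the first time it exceeds `err_warn`
(default $10^{-3}$). In the default regime it stays near $10^{-5}$.

Delayed terms $E_j(t-d_{ij})$ are read from a **circular history buffer**
holding the last `capacity` accepted steps as (time, state, derivative)
triples. Lookups use piecewise cubic Hermite interpolation, the dense output
matching the pair's third order; at a stored node the stored state is
returned exactly. The buffer capacity is auto-raised to
$\lceil d_{\max}/h\rceil + 4$ (never below the reference ring length of 10),
so retained memory is bounded and independent of the simulated horizon —
the contract that makes day-long simulations feasible.

Numerical edge cases are handled as follows:

* Exponent arguments of the logistic are evaluated through `plogis` with a
  ±500 clamp, so extreme drives saturate instead of overflowing.
* Delays are used at full floating precision (not rounded to step
  multiples); sub-step interpolation makes that well defined.
* A delay below one step would require extrapolation inside the current
  step; such delays are clamped up to one step with a warning.
* Pre-history for $t \le 0$ is the constant initial state.
* Any non-finite stage value, or any activity beyond `divergence_limit`
  (default $10^6$), aborts the run with a `brainmass_divergence` condition;
  when snapshots stream to disk, everything up to the last completed
  snapshot is already flushed.

The original implementation restarted its solver every 10 steps on a ring of
the last 10 values. `run_chunked()` keeps `chunk_steps` in its configuration
for interface fidelity but integrates continuously over the ring; the test
suite proves the equivalence by comparing against `run_monolithic()` (a
full-history reference built from the generic `dde_integrate()` path) to
below $10^{-9}$ over 1000 steps. Note the reference ring of 10 could not by
itself serve delays above 10 ms — auto-raising the capacity to the longest
delay is the package's resolution of that tension.

## Plasticity

Every `update_every = 10` steps, existing inter-region connections update by
the simplified Hebbian rule

$$\Delta W_{ij} \;=\; c\; E_j(t - d_{ij})\;\big(E_i(t) - E_i(t-h)\big),$$

followed by clipping at zero and **synaptic normalization**: each region's
incoming weights are rescaled to unit sum. Two conventions had to be fixed
here. First, the coupling equation makes row $i$, column $j$ a
target–source pair, while a literal reading of the published update formula
swaps the roles; the package resolves the ambiguity with the rule's own
pre/post wording — *pre* is the delayed source activity, *post* the
target's change — which is the biologically meaningful Hebbian pairing.
Second, normalization runs over incoming (row) weights, matching the
synaptic-scaling literature the rule cites. "One step earlier" is exactly
one solver step, read from the buffer.

Internal weights follow the analogous rule
$\Delta w_k = c\,\mathrm{Pre}(t)(\mathrm{Post}(t)-\mathrm{Post}(t-h))$ with
the pre/post populations implied by each weight's wiring; after updating,
the plastic set of each node is jointly rescaled to conserve its pre-update
sum (the source says only "with subsequent normalization"; conserving the
node's total internal weight is the package's choice, keeping the internal
circuit's operating point stable while redistributing weight within it).

Three deliberate details:

* **`c = 0` is a strict no-op.** A cycle that still normalized would alter
  `W` once, contradicting the requirement that a zero learning rate be
  bitwise identical to plasticity off. Consequently the *first* effective
  cycle of a plastic run performs the initial normalization of `W`.
* **Zero weights are never updated** — absent connections stay absent
  (no structural plasticity), and the update work scales with the number of
  existing connections.
* **Boundary derivative refresh.** Weights change discontinuously at cycle
  boundaries. The stored derivative at the boundary node is recomputed under
  the new weights (one extra rhs evaluation per cycle) so that dense output
  ahead of the boundary — and the FSAL stage — use the weights actually in
  force. The scalar reference implementation in the tests mirrors this
  independently.

The learning rate default `c = 0.01` is a package choice (the source prints
no value); it produces weight changes of order $10^{-4}$ per cycle at the
default activity scale, slow enough that normalization keeps the dynamics
stable over the horizons tested. An Oja-style rule
($\Delta W = c\,\mathrm{post}(\mathrm{pre} - \mathrm{post}\,W)$) is exposed
through the same plugin seam as a non-validated extra.

## Recording

Snapshots of activities, `W` and the internal weights are taken at every
multiple of the recorder interval (default 50 s of biological time,
i.e. every 50,000 steps), always including $t = 0$; a 24 h horizon yields
1729 snapshots. With `out_dir` set, snapshots stream to disk through
`series_writer()` — one snapshot in memory at a time, manifest kept current
after every append, so an aborted run leaves a readable store. The on-disk
format is plain text (JSON manifest, long-format activities CSV,
per-snapshot weight CSVs) written at 17 significant digits, which makes the
write→read round trip bit-exact; no HDF5 dependency is available in the
target environment, and the text layout keeps stores diffable.

## Instrumentation instead of wall time

Runtime claims are hardware-bound, so the benchmark harness
(`benchmark_scaling()`) reports deterministic operation counters — rhs
evaluations and coupling multiply-adds (one per existing connection per
stage evaluation) — alongside an informational wall-time column that no test
asserts on. The coupling counter makes the $O(n^2)$ complexity claim
literal: at full connectivity its per-step value is exactly $n(n-1)$, and
its log–log slope against $n$ sits in $[1.9, 2.1]$ on the tested family.

```{r bench, eval = FALSE}
b <- benchmark_scaling(c(50, 100, 200), p = 1, plasticity = FALSE,
                       bio_time = 10)
scaling_slope(b)  # ~ 2.01
```

## What the tests establish — and what they do not

The suite verifies: the closed forms of $F$ and $k_j$ and their gain-control
ordering; bit-identity of the vectorized coupling sum with a naive double
loop; third-order convergence of the stepper and exactness on the delayed
test equation $y'(t) = -y(t-1)$; agreement of the bounded-memory engine with
a full-history reference to $10^{-9}$; plasticity invariants (sparsity
pattern, unit incoming sums, non-negativity, `c = 0` bitwise identity) and
equality with an independent scalar reference run; snapshot scheduling,
bit-exact disk round trips and byte-identical seeded re-runs; and the
counter-based scaling law. They do not establish biological validity of any
parameter set, and all quantitative checks run on the synthetic connectome
family, not on imaging data.

## Known limitations

* Populations are mean-field: no spatial structure within a region, no
  individual-neuron effects.
* No structural plasticity — connections are never created, and a weight
  driven to exactly zero stays zero thereafter.
* Fixed-step explicit integration: time constants far below the step are
  numerically unstable (by design detected through the divergence guard, as
  exercised in the tests).
* The fixed normalization makes total incoming weight a conserved quantity
  after the first cycle; regimes where absolute coupling strength should
  drift are out of scope.
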