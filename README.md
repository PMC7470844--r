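# segwave

Simulation and analysis of **two-module models of segmentation-clock
arrest** — how a tissue-wide genetic oscillation is converted into a
frozen spatial pattern of cell fates, and why the *route* of that
conversion matters.

Each cell of a 1D embryo obeys

```
dP/dt = θ_D(g)·D(P) + θ_S(g)·S(P) + C(P) + η(g, P)
```

where `D` is an oscillatory transcriptional module (a repressilator, or a
non-harmonic oscillator on the unit circle), `S` a multistable fate
module (mutual repression, or a bistable cubic landscape), `C`
degradation, `η` noise, and the control parameter `g ∈ [0,1]` slides from
1 (pure clock) to 0 (pure landscape) behind a regressing morphogen front
`g(x,t) = H(s(x − x0 − vt))`. Depending only on how the module weights
`θ_D, θ_S` interpolate, the clock stops in one of two ways:

* **SNIC** (saddle-node on invariant cycle) — fate states are born
  directly on the limit cycle; the period diverges while the amplitude
  survives, and the oscillation's phase is translated into fates without
  erasure. This is the generic outcome of smooth interpolation (linear
  weights).
* **Hopf** — sufficiently nonlinear weights (or an explicit intermediate
  module) carve out a mid-route regime with a single attracting state;
  the cycle's amplitude collapses at finite period, phase memory is
  partially erased, and the fate states appear only later through
  saddle-nodes (or a pitchfork, or a saddle-node of limit cycles in the
  subcritical variant).

The package provides both model families with reference fixtures
(`make_fixture()`), deterministic and stochastic embryo simulation with
copy-number (`1/Ω`) noise and diffusion (`simulate_embryo()`), numerical
bifurcation diagrams with automatic classification of the arrest route
(`bifurcation_diagram()`, `classify_transition()`), a phase-to-fate
mutual-information metric of patterning precision (`mi_experiment()`),
wave-shape diagnostics — sawtooth asymmetry, local wavelength and the
analytic relation `S(x) = S / (1 − T0/T(x))` — and a coupled
phase-oscillator lattice as the explicit infinite-period reference
(`simulate_phase_lattice()`).

## Worked example

```r
library(segwave)

model <- make_fixture("gene_model2")          # 3 genes, linear weights
front <- morphogen_front(steepness = 2, speed = 3.09)
kym   <- simulate_embryo(model, embryo_config(n_cells = 60), front)
kym
#> <kymograph> 504 frames x 60 cells x 3 variables; t in [ 0 , 39.23 ]

call_fates(kym)
#> <fate_pattern> 60 cells, 15 runs: A C B A C B A C B A C B ...
```

The front translates the clock's phase into a repeating three-fate
pattern (A, C, B — about four cells per fate at this front speed). The
arrest route behind it:

```r
d <- bifurcation_diagram(model, g_grid = seq(1, 0, length.out = 51))
d$events
#>   type    g_star max_period amplitude_end dist_to_cycle
#> 1 snic 0.1715625   675.3074       2.09534   0.001675243
#> 2 snic 0.1715625   675.3074       2.09534   0.001689429
#> 3 snic 0.1715625   675.3074       2.09534   0.001669104
classify_transition(d)
#> <transition_class> SNIC
```

Three simultaneous saddle-nodes land on the cycle (distance ~2e-3) at
g ≈ 0.172 while the period has grown past 170 times the posterior period
and the amplitude is intact — a SNIC. The quadratic-weight sibling
(`make_fixture("gene_model1")`) instead reports a supercritical Hopf at
g ≈ 0.720 (amplitude collapsing, finite period) followed by three
off-cycle saddle-nodes at g ≈ 0.297, and classifies `HOPF_SUPER`.

A perfect three-fate phase readout carries

```r
mutual_information(diag(3) * 100)
#> [1] 1.584963         # log2(3) bits
```

and under the reference noise conditions (`mi_reference_conditions()`;
shallow slow front, diffusion 0.2) the SNIC-route model retains about
1.35 bits at a copy-number scale of Ω = 5000 while the Hopf-route model
needs more than ten times as many protein copies to match it — the package's
quantitative form of "SNIC transitions read the clock more robustly".

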