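# motifadapt

Simulation and analysis of **adaptive biochemical network motifs under
dynamic and spatial stimuli** — for systems and synthetic biologists who
want to test, mechanically, which circuit architectures keep adapting when
the input is a ramp, an oscillation, or a spatial pattern rather than a
step.

## The science

Many signalling circuits adapt exactly to step inputs: the output returns
precisely to its pre-stimulus level. Whether that robustness survives
*dynamic* stimuli depends on circuit structure, not parameters. The package
implements three mechanistic classes as mass-action ODE models, each with a
configurable **signal site** (the one reaction whose rate the signal S
multiplies):

- **Inflow–outflow motifs** (two- and three-node, `DR08_M1*`, `DR08_M32`,
  `DR08_M34`, `REV3`): a zeroth-order inflow and first-order outflow force
  the balance d(A+B)/dt = k0 − k2·B, pinning the output at B = k0/k2 at
  any steady state. The same balance, integrated over a stimulus cycle or
  a periodic spatial domain, pins the *time-averaged* output under
  sinusoids ((1/T)∫B dt = k0/k2) and the *space-averaged* output in static
  gradients — a homeostasis "in the mean".
- **Incoherent feedforward** (`KR09`): activator and inhibitor legs driven
  by the same signal feed a covalent-modification readout
  R\* = RT·(A/I)/(kr/kf + A/I); the ratio A/I is signal-independent, so the
  readout adapts even to ramps under which neither leg reaches a steady
  state — but not to exponentials, where A/I settles at
  ka(k−i+λ)/(ki(k−a+λ)).
- **Transcritical / autocatalytic** (`TC`): a closed cycle with
  autocatalytic conversion B→C pins B = k4/k3 on its nonzero-C branch
  (absolute concentration robustness), feasible when
  Xt > (k4/k3)(1 + k2/(k1·S)).

Hybrid circuits (`HYB_XAI`, `HYB_S2`, `HYB_AUTO`) combine the mechanisms to
realize every presence/absence combination of three behaviours — exact ramp
adaptation, period-mean maintenance, spatial-mean maintenance — which
`build_combination_matrix()` reproduces by simulation as an 8 × 3
qualitative matrix.

Stimuli (`stimulus()`) cover steps, linear/quadratic/capped ramps,
exponentials, sinusoids, static spatial gradients, spatially modulated
ramps, and travelling and standing waves on a 1-D periodic domain.
Integration is stiff-capable (`deSolve`); spatial problems use the method
of lines with periodic central differences.

## Worked example

Ramp a two-node inflow–outflow motif through its forward site, then through
its reverse site:

```r
library(motifadapt)

m <- build_circuit("DR08_M1_REV", "A_to_B")
m
#> <circuit_model> DR08_M1_REV: two-node inflow-outflow motif, reversible A<->B
#>   species:     A, B  (output: B)
#>   signal site: A_to_B
#>   params:      k0=1, k1=1, k11=1, k2=1

traj <- integrate_temporal(m, stimulus("linear_ramp", a = 0.1, S1 = 0.1, t0 = 50))
classify_response(traj)
#> <response_report> class = exact (P = 8.92e-06, baseline = 1, steady = 1, peak dev = 2.24)
```

The output overshoots (peak deviation 2.24) and returns to its baseline
k0/k2 = 1 with residual precision P ≈ 9·10⁻⁶: exact adaptation to the ramp.
Moving the *same* signal to the reverse reaction changes the verdict
qualitatively:

```r
rev <- build_circuit("DR08_M1_REV", "B_to_A")
classify_response(integrate_temporal(rev, stimulus("linear_ramp"), t_end = 1050))
#> <response_report> class = nonadaptive_steady (P = 1, baseline = 1, steady = 0.9091, peak dev = 0.0909)
```

B settles at the non-adaptive level 1/(1 + k1k2/(k11·S1)) = 0.9091 — which
carries information about the ramp slope — while A grows linearly at the
predicted rate k0/(1 + k1k2/(k11·S1)). Period means under sinusoids are
pinned regardless of basal level or amplitude:

```r
period_mean_sweep("DR08_M1_REV", "A_to_B",
                  sweep = data.frame(a = c(0.2, 0.8), b = c(0.1, 0.4)))$means
#> [1] 1 1    # prediction: k0/k2 = 1
```

The experiment registry (`list_experiments()`, `run_experiment()`,
`run_full_suite()`) packages these and the spatial/wave analyses as named,
deterministic runs with oracle comparisons; a thin CLI is provided at
`inst/cli/motifadapt.R` (`list`, `run <name>`, `suite`, `matrix`).

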