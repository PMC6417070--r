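---
title: "Adaptive network motifs under dynamic and spatial stimuli: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive network motifs under dynamic and spatial stimuli: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Exact adaptation — the return of a circuit's output to its pre-stimulus
level despite a persistent change in input — is a recurring design feature
of cellular signalling and homeostasis: bacterial and amoeboid chemotaxis,
osmoregulation, phototransduction, iron homeostasis. Most of what is known
about adaptive circuits comes from their response to steps. Cells, however,
live in ramps, oscillations and spatial gradients, and circuits that look
interchangeable under a step can behave in completely different ways under
such stimuli.

`motifadapt` implements a suite of small mass-action circuit models that
adapt to steps through three distinct mechanisms, a family of dynamic and
spatiotemporal stimuli, and the analysis machinery to classify responses
and test mean-value homeostasis. Every qualitative claim the package makes
— which circuit adapts exactly to which stimulus class, which maintains
the time- or space-averaged output — is backed by a closed-form prediction
and checked by simulation in the test suite.

## The circuits

All models are ODE systems with mass-action rates; an external signal
\(S \ge 0\) multiplies the rate of exactly one designated reaction (the
*signal site*). Three adaptation mechanisms are covered:

**Open (inflow–outflow) circuits.** The two-node motif
\[
  \dot A = k_0 - k_1 S A + k_{11} B,\qquad
  \dot B = k_1 S A - k_{11} B - k_2 B
\]
(`DR08_M1_IRREV` with \(k_{11}=0\), `DR08_M1_REV` otherwise) adapts
because the balance \(\mathrm{d}(A+B)/\mathrm{d}t = k_0 - k_2 B\) forces
\(B = k_0/k_2\) at any steady state, independent of \(S\). Three-node
variants add a node C with either a second outflow (`DR08_M32`), a second
inflow (`DR08_M34`, output steady state \((k_0+k_3)/k_2\)), or full
reversibility (`REV3`). The same integral balance, applied over a stimulus
cycle or over a periodic spatial domain, is what pins time- and
space-averaged outputs below.

**Incoherent feedforward.** `KR09` drives an activator and an inhibitor
leg, \(\dot A = k_a S - k_{-a}A\), \(\dot I = k_i S - k_{-i}I\), which
converge on a covalent-modification readout
\(\dot R^* = k_f A (R_T - R^*) - k_r I R^*\). The steady readout depends
only on the ratio \(A/I\), which is independent of a constant \(S\); under
ramps both legs grow without bound but their ratio — and hence the output —
still returns to baseline.

**Transcritical / autocatalytic.** `TC` is a closed three-species cycle
with an autocatalytic conversion \(B \to C\) at rate \(k_3 B C\) and
release \(k_4 C\). On its nonzero-C branch the autocatalysis pins
\(B = k_4/k_3\) regardless of the total material \(X_t\) (absolute
concentration robustness). The branch exists only when
\(X_t > (k_4/k_3)(1 + k_2/(k_1 S))\); `build_circuit()` enforces this at
the configured basal signal and refuses infeasible parameterizations.

**Hybrids.** Three circuits combine feedforward legs with inflow–outflow
structure: `HYB_XAI` (\(\dot X = k_0 A - k_2 I X\), with the inhibitor leg
diffusible in spatial settings), and the `HYB_S2` / `HYB_AUTO`
augmentations in which the conversion of the output back to its upstream
species is regulated quadratically by the signal or autocatalytically.
These realize the remaining presence/absence combinations of the three
exact behaviours.

## Stimuli

Ten parametric families (`stimulus()`): step, linear/quadratic/capped
ramps, exponential, sinusoid, static spatial gradient, spatially modulated
ramp, travelling wave and standing wave. All hold the basal level \(a\)
before the onset \(t_0\) and are built to stay nonnegative; the
constructor rejects violating amplitudes (e.g. a sinusoid with \(b > a\)).
Spatial kinds are periodic over a domain of length \(L\) (default 1) with
integer mode \(m\); the wave forms are
\(S = a + b\sin(2\pi m\theta/L - w t)\) (travelling) and
\(S = a + b\sin(2\pi m\theta/L)\sin(w t)\) (standing) — the simplest
periodic realizations of their verbal descriptions. Defaults follow the
simulation protocol used throughout: low basal \(a = 0.1\), onset
\(t_0 = 50\), slope \(S_1 = 0.1\), so stimulus variation and circuit
relaxation play out on comparable timescales.

## Simulation protocol

Every run first equilibrates the circuit at the basal signal (chunked
integration until the scaled residual falls below \(10^{-10}\), capped at
\(t = 10^4\)), then restarts the clock, so the pre-onset segment of every
trajectory sits at the basal steady state. Temporal integration uses
`deSolve::lsoda` (stiff-capable, variable step) at `rtol = 1e-8`,
`atol = 1e-10`: the exact-adaptation claims are asserted at 0.1–1%
precision, so solver error is kept several orders below that. Spatial
problems are discretized by the method of lines on \(n\) uniform grid
points (default 128; \(n < 16\) is rejected) with second-order central
differences and periodic wrap-around, and integrated with `lsodes`, whose
sparse Jacobian handling copes with the stiffness introduced by diffusion
(\(k_d/\Delta\theta^2\) up to \(\sim 10^4\)).

A useful discrete property: on the periodic grid the diffusion matrix has
exactly zero column sums, so the semi-discrete system inherits the
integral balances exactly — the spatial mean of the output at steady state
matches the analytic value to solver precision at any \(n\), and the
grid-convergence test (means change by \(<10^{-4}\) between \(n = 128\)
and \(256\)) guards the profile shapes rather than the means.

**Steady-state detection** uses a trailing window (10% of the horizon):
steady when \(\max|\dot y| \cdot T_{\mathrm{win}} / |y| < 10^{-6}\).
Non-steady trailing segments are classified by the slope of
\(\log y\) vs \(\log t\): \([0.8, 1.2]\) is linear growth (the diagnostic
asymptote of the reverse-signal ramp cases), above that superlinear.

**Response classification** scales the residual offset by the peak
excursion, \(P = |y_{ss} - y_{base}| / \max|y - y_{base}|\): exact for
\(P < 0.01\), partial to \(0.5\), non-adaptive steady above, unbounded
when the output itself grows. In every in-scope case the classes are
separated by at least an order of magnitude in \(P\), so the bands are not
delicate. A stimulus with no measurable excursion is reported as exact
with \(P = 0\).

**Period means** are trapezoid averages over the last full stimulus cycle,
accepted once the cycle-to-cycle drift of the mean falls below
\(10^{-6}\) (cap: 200 cycles; typical runs use 25–40 cycles of
\(w = 1\) forcing). Spatial means are plain grid averages (trapezoid rule
on a uniform periodic grid). Local temporal-mean profiles report a
uniformity statistic \((\max-\min)/\mathrm{mean}\) across the domain.

## Parameter choices

Rate constants default to 1.0 and the structural claims (which sites adapt
in ramps, which balances pin which means) are parameter-independent, so
O(1) defaults suffice for them. The exceptions, where a *magnitude* is the
claim, are set once from the physics of the regime:

- **TC**: \(X_t = 5\) with basal \(S = 0.5\) (the feasibility bound at
  these rates is \(S > 0.25\)).
- **KR09**: symmetric legs would make the exponential-stimulus ratio
  \(r(\lambda) = k_a(k_{-i}+\lambda)/(k_i(k_{-a}+\lambda))\) identically
  equal to its prestimulus value, and a slow readout cycle would average
  its inputs so that \(\langle A\rangle/\langle I\rangle\) — exactly the
  prestimulus ratio — is all the readout sees. Both effects would hide
  behaviour the model class is known for. The registry therefore uses the
  canonical fast-excitation / slow-inhibition regime, \(k_{-i} = 0.2\),
  with a readout fast enough to track the ratio (\(k_f = k_r = 10\)), the
  same quasi-steady-readout assumption under which the circuit's ramp
  behaviour is derived analytically.
- **Hybrids** share those legs; the `HYB_S2`/`HYB_AUTO` augmentation
  strength is \(k_{11} = 10\), making the extra nonlinear regulation the
  dominant pathway — it is introduced precisely as a *stronger* regulation
  of the output.
- **Wave experiments** on the one-outflow three-node motif use
  \(k_d = 0.025\) for A: the standing-wave nonuniformity of local means
  vanishes in both the local (\(k_d \to 0\)) and well-mixed (large
  \(k_d\)) limits, and is strongest when the diffusion length per stimulus
  period, \(\sqrt{k_d T} \approx 0.4 L\), is comparable to the wavelength.
  Static-gradient experiments use \(k_d = 1\) (strongly diffusible), the
  regime for graded steady responses. The travelling-wave uniformity is
  protected by the translational symmetry of the discretized system and is
  insensitive to \(k_d\).

## The combination matrix

`build_combination_matrix()` instantiates eight circuits, one for each
presence/absence pattern of {exact ramp adaptation, period-mean
maintenance, spatial-mean maintenance}, and computes all 24 verdicts by
simulation: a linear ramp classified by \(P\); a sweep of sinusoids whose
period means must agree with the closed form (and each other) within 1% to
count as maintained; and a static gradient whose steady spatial mean must
stay within 1% of the pre-gradient adapted level. Because non-maintenance
is second order in the stimulus amplitude while maintenance is structural,
the matrix uses strong stimuli (gradient amplitude \(0.9a\), wide or
fixed-amplitude basal sweeps) — these sharpen the "No" cells without
biasing the "Yes" cells. The two-outflow row is instantiated with the
signal on the B→C conversion (the reaction *between* the outflow
variables), the combination for which all three behaviours fail; the
ratio-readout rows (feedforward, hybrids) use the fixed-amplitude
10× basal sweep under which their mean shift is visible.

## Known limitations

- The registry is closed: the circuits above are the supported topologies
  (extensible in code, not by configuration).
- Spatial problems are 1-D with periodic boundaries; no 2-D/3-D domains,
  no other boundary conditions, no stochastic dynamics.
- The magnitudes of the non-maintenance effects (feedforward and hybrid
  period means, standing-wave nonuniformity) are regime-dependent; the
  package fixes defensible regimes and documents them here, but the
  qualitative verdicts should not be read as magnitude claims for other
  parameter sets.
- For the autocatalytic hybrid with its inhibitor-mediated outflow
  retained (required for its spatial-mean property), asymptotic analysis
  and simulation agree that the output still adapts exactly to ramps in
  the entire basal-feasible (subcritical) parameter region; the package's
  oracle encodes that, and the inexact-in-ramp combination is realized by
  the quadratically regulated variant `HYB_S2` instead.
- Pre-equilibration assumes the basal steady state is reachable from the
  registry initial guess; for TC the analytic nonzero-C branch is used as
  the start (the C = 0 branch is invariant and must not be crossed).

## Problem sizes

The shipped tests and the acceptance script use: temporal horizons of
\(10^3\) (ramps; \(2\times 10^4\) for the quadratic reverse ramp, whose
output decays like \(1/t\)), 25–40 stimulus cycles for period means,
\(n = 128\) grid points for spatial runs (256 for the grid-convergence
check, 64 for the diffusion-free local-response case), and 1000 random
draws for the positivity invariant.
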