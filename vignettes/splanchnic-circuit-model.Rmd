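---
title: "A lumped-parameter electrical analog of splanchnic arterial steal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter electrical analog of splanchnic arterial steal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocircuit)
```

## The physiological question

Celiac artery (CA) stenosis and pancreaticoduodenal artery (PDA) aneurysm are
each rare, yet they co-occur far more often than chance allows. The usual
account is stenosis-first: a narrowed celiac trunk forces flow through the
pancreaticoduodenal arcade, and the chronically overloaded collateral dilates.
But the causality could equally run the other way: an aneurysm or collateral
bed with low resistance steals flow from the CA, and a trunk already under
raised wall tension (for instance under median arcuate ligament compression)
collapses. Because neither disease can be provoked in patients or animals, the
question is inaccessible to experiment — but not to simulation, because
steady blood flow through a vascular bed and direct current through a
resistor obey the same linear laws. `hemocircuit` implements that analogy as
a small, fully testable model.

## The model

The splanchnic arterial tree is reduced to a two-branch current divider:

- a 12 V DC source stands for the 120 mmHg aortic pressure
  (scale: 1 mmHg = 0.1 V, 1 L/min = 1 mA, hence 100 ohm per mmHg·min/L);
- the CA branch is a stenosis potentiometer (0–50 kΩ) in series with a fixed
  3.3 kΩ resistor;
- the PDA branch ("PDA block") is a fixed 3.3 kΩ resistor in parallel with an
  aneurysm/collateral potentiometer (0–50 kΩ);
- both branches feed a common 12 kΩ pancreas+liver load returning to ground.

The 3.3 kΩ values arise from a nominal 1.3 kΩ per arterial segment, two
segments in series, rounded up to the nearest stock resistor; the load is
sized so the normal portal flow of 0.86 L/min (0.86 mA) survives the ~1.4 V
drop across the paralleled arterial pair: (12 − 1.4) V / 0.86 mA ≈ 12.3 kΩ,
realised as a stock 12 kΩ. `derive_parameters()` reproduces this arithmetic.

CA flow is the current in the CA branch; **PDA flow is the total current
entering the PDA block** (resistor plus aneurysm path). That measurand choice
is forced by the reported readings: at the normal state the PDA flow is
0.455 mA, whereas the PDA resistor alone carries 0.427 mA. An electrically
equivalent wiring treats the aneurysm potentiometer as a sibling branch
rather than as strapped across the PDA resistor; the two are
indistinguishable for every measurand in scope, and the package measures the
block total so either reading applies.

```{r}
steady_flows(state = c(0, 50000))       # normal
steady_flows(state = c(50000, 50000))   # stenosis without aneurysm
steady_flows(state = c(50000, 0))       # full steal (preoperative)
steady_flows(state = c(0, 0))           # aneurysm without stenosis
```

## Solver

`solve_dc()` uses modified nodal analysis: Kirchhoff's current law at every
non-ground node with element conductances, extended with one branch-current
unknown per voltage source. A zero-resistance element (a potentiometer at
exactly 0 Ω) is handled the same way — as an exact 0 V constraint with its
own current unknown — rather than by substituting a small epsilon
resistance. This matters for the model's headline states: with the aneurysm
potentiometer at 0 Ω the CA branch sees exactly zero potential difference,
so its flow is exactly 0.000 mA, not merely small. The linear system is
solved by LU factorisation with the condition-number guard disabled, because
user resistance tables may legitimately mix near-open (1e12 Ω) and near-short
(1e-3 Ω) edges; structural singularity (missing ground, disconnected graph,
an all-short loop through the source) is instead caught by explicit graph
checks, exact-zero-pivot detection and a post-solve residual test
(relative residual above 1e-8 rejects the solution).

`equivalent_resistance()` removes (open-circuits) voltage sources, injects a
unit test current between the two terminals and reads the potential
difference. Disconnected terminal pairs report `Inf`. The test suite checks
this against two independent oracles: recursive series/parallel reduction on
randomly generated series-parallel topologies, and the conductance-weighted
graph-Laplacian pseudoinverse on general random networks.

`steady_flows()` is the closed-form series/parallel reduction of the reduced
circuit and serves as the analytic twin of the nodal route (`solved_flows()`);
the suite holds the two to within 1e-9 mA over a 50×50 potentiometer grid.

## Scenarios

The two chronologies are quasi-static 7 s timelines (`builtin_scenario()`):
resistive circuits have no memory, so each instant is an independent steady
state and time only orders the manipulations. Both start at the normal state
(0 Ω, 50 kΩ) and end at the postoperative state (50 kΩ, 50 kΩ); every
manipulation is a 1 s ramp and every hold lasts 1 s. Ramps are linear — the
published tracings show straight resistance segments, and only transition
samples would change under a step shape; hold-zone values are unaffected
either way. `run_combined()` concatenates the two runs on one 14 s axis with
the aneurysm-first half offset by +7 s.

Sampling uses `dt = 0.001` s by default. Because the solve is exact at every
sample, `dt` is purely a tracing resolution; zone summaries are taken at the
midpoint sample of each zone precisely so that boundary samples and `dt`
refinement cannot move them (halving `dt` is asserted to change no hold-zone
value). Zones are half-open `[start, end)` with the final sample assigned to
the last zone.

```{r}
scn <- builtin_scenario(1)
summarize_scenario(run_scenario(scn, dt = 0.001), scn)
```

Two qualitative flags condense the clinical reading. `steal_flag` marks any
hold zone whose CA flow falls below 0.0005 mA — i.e. reads 0.000 at the
3-decimal reporting precision. `detect_reconstitution()` encodes the clinical
hallmark of the modelled case: preoperative CA flow at zero, postoperative CA
flow positive but below normal (44 mL/min at default parameters), exactly the
reappearance of flow after aneurysm ablation with the stenosis left in situ.
`classify_brightness()` maps a flow to the LED classes of a breadboard
realisation (off/dim/normal/bright at ratio thresholds 0.02, 0.5 and 1.1 of
the normal-state current). All three thresholds are presentation heuristics
of this package, chosen once for the default parameterisation; they are not
measured physiological or photometric constants.

The central claim is path independence: `scenario_equivalence()` verifies
that normal, preoperative and postoperative flows agree between the
stenosis-first and aneurysm-first runs (to 1e-6 mA). In a purely resistive
network the steady flows are functions of the potentiometer state alone, so
either lesion can come first and produce the identical presentation — the
bidirectional-causality argument, stated testably.

## The full splanchnic graph

`splanchnic_edges()` ships the topology of the unreduced splanchnic network
(celiac, superior/inferior mesenteric trunks, the pancreaticoduodenal arcade
and arc of Riolan, the venous return through the portal vein and liver).
No edge resistances are shipped: none are established physiological
constants at this scale, and inventing defaults would lend them false
authority. `build_full_network()` therefore demands a complete user
resistance table. The suite checks that pricing the CA and PDA edges at the
reduced-model values and effectively opening every side path reproduces the
reduced model's flows to better than 1e-6 mA.

## Auxiliary physiology

Two proportionalities frame the discussion of why a vessel yields:
`laplace_wall_tension()` (T = P·R, in mmHg·length — no absolute unit
conversion is attempted since no absolute radii are in scope) and
`poiseuille_resistance_ratio()`, the inverse 4th-power scaling of hydraulic
resistance with radius (inverse square for a wire; both exponents supported).
Both operate on ratios; the package deliberately does not attempt absolute
Poiseuille resistances, which would require viscosity and vessel lengths.

## Synthetic fixtures

`generate_random_network()` produces connected random resistor networks
(spanning tree plus extra edges, 100–10 000 Ω uniform, one 12 V source) as
solver fixtures. They emulate nothing physiological — their only purpose is
to exercise conservation laws and the equivalent-resistance oracles on
topologies the splanchnic circuits never reach. Passing those tests shows the
solver is correct, not that the splanchnic parameterisation is
physiologically calibrated: the model's own authors stress that it is
qualitative, a statement about which causal orderings are possible, not a
quantitative hemodynamic prediction.

## Numerical choices and limitations

- Reported currents are rounded to 3 decimals in mA (the reporting precision
  of the measurands); traces are written at 6 significant digits.
- Internal tolerances: KCL residual and oracle agreement at 1e-9 mA;
  scenario equivalence at 1e-6 mA.
- DC only: no pulsatility, no capacitive/inductive vessel compliance, no
  nonlinear elements; a single voltage source per circuit.
- Potentiometer range caps the stenosis at 50 kΩ, so a fully *occluded* CA is
  outside the state space (flows approach, never reach, the open-branch
  limit).
- Test and acceptance runs use the 50×50 state grid and `dt = 0.001` s
  (7 001 samples per scenario), which keeps the whole suite in seconds.
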