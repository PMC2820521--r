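---
title: "Modelling dopamine- and calcium-dependent plasticity in striatal spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dopamine- and calcium-dependent plasticity in striatal spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Corticostriatal synapses onto D1-receptor-expressing medium spiny neurons
are bidirectionally plastic: cortical (glutamatergic) activity alone tends
to depress them, while coincident dopamine converts depression into
potentiation, and strong calcium influx can potentiate even without
dopamine. `spinesim` implements a deterministic kinetic model of the spine
signalling cascade that links these two inputs — intracellular free
calcium and extracellular dopamine — to the number of AMPA receptors
anchored in the post-synaptic membrane, which is the model's measure of
synaptic efficacy.

Every process is expressed in exactly two mass-action forms:

* a **binding reaction** `A + B <-> AB` with forward rate `kf`
  (µM⁻¹ s⁻¹) and backward rate `kb` (s⁻¹); when a row is specified
  thermodynamically we use `kb = 1/τ`, `kf = 1/(Kd·τ)`, so `Kd = kb/kf`
  exactly;
* an **enzymatic reaction** `E + S <-> ES -> E + P` integrated as its two
  elementary steps. The Michaelis–Menten shortcut is deliberately avoided
  (enzyme sequestration in ES matters in this network). When only
  `(Km, kcat)` are known we adopt the classical simulator default
  `kb = 4·kcat`, hence `kf = 5·kcat/Km`, which preserves
  `Km = (kb+kcat)/kf` exactly.

The shipped network has 72 reactions over 62 named species (plus
auto-generated ES complexes), with 132 distinct rate parameters organised
in rate groups; 83 parameter values derive from the literature-based model
family for this pathway and 49 were hand-tuned to reproduce the
qualitative behaviours listed below. Concentrations are µM, time is
seconds, and the spine is treated as one homogeneous volume.

The pathways realised (all as binding/enzymatic rows):

* dopamine → D1 receptor → catalytic activation of the olfactory-type G
  protein → active adenylyl cyclase 5 → cAMP → PKA, with the
  PKA → phosphodiesterase → cAMP negative feedback, calcium inhibition of
  the cyclase and calmodulin-enhanced phosphodiesterase activity;
* calcium → calmodulin (four sequential sites) → CaMKII (with Thr286
  auto- and inter-subunit phosphorylation opposed by PP1), PP2B
  (calcineurin) and PP2A (a calcium-bound and a PKA-phosphorylated active
  form);
* PP2B → CK1 (reversal of CK1's self-inhibitory autophosphorylation) →
  Cdk5, collapsed to a single enzymatic activation step → DARPP-32
  phospho-Thr75;
* the 8-state DARPP-32 model over Thr34 × Thr75 × Ser137: PKA
  phosphorylates Thr34, PP2B dephosphorylates it (ten-fold slower on
  Ser137-phosphorylated states), CK1/PP2C cycle Ser137, and phospho-Thr75
  binds and sequesters active PKA while phospho-Thr34 (and
  phospho-inhibitor-1) sequester PP1;
* AMPA receptor trafficking: serial phosphorylation (PKA at Ser845, then
  CaMKII at Ser831 on the anchored form), anchoring of phosphorylated
  receptors at the membrane, removal of dephosphorylated ones, and
  constitutive exchange with a bulk cytosolic pool via a clamped carrier.

## The positive feedback loop and bistability

The scientific heart of the model is the double-negative loop: active PKA
phosphorylates a PP2A regulatory subunit, phospho-PP2A dephosphorylates
DARPP-32 Thr75, and phospho-Thr75 binds and inhibits PKA. Three design
choices make this loop genuinely bistable here:

1. **Tight stoichiometric inhibition.** The phospho-Thr75:PKA complex has
   `Kd = 0.033` µM against a DARPP-32 pool (50 µM) far exceeding total
   PKA (1.2 µM), so the free-kinase level is an ultrasensitive function
   of phospho-Thr75.
2. **Zero-order antagonism on Thr75.** Both the Cdk5 phosphorylation and
   the PP2A dephosphorylation of Thr75 run near substrate saturation
   (Km 2 and 0.5 µM against tens of µM of substrate), so the
   phospho-Thr75 level switches sharply when the two maximal velocities
   cross.
3. **Direct cAMP gating of the kinase.** The doubly-cAMP-bound
   holoenzyme is treated as the active kinase (two sequential cAMP
   binding steps), which couples the loop's state to cAMP with
   cooperativity 2 and avoids diluting the sequestration feedback
   through a separate regulatory-subunit equilibrium.

`feedback_subsystem()` extracts the loop with cAMP and calcium clamped
and the active-Cdk5 and PP2C pools as conserved parametric totals (a
conserved enzyme pool can saturate; a clamped one cannot, and saturation
of the phosphorylating side is essential for the zero-order switch). At
the default operating point (Cdk5 3.6 µM, PP2C 1.2 µM, calcium 0.06 µM,
totals from the table initials) the subsystem has one stable state below
cAMP ≈ 0.2 µM, exactly two stable states separated by a saddle for
intermediate cAMP, and one high-activity state beyond a few µM.
Quasi-static cAMP sweeps (`hysteresis_sweep()`) traverse a wide
hysteresis loop whose upward jump occurs at much higher cAMP than the
downward jump; near the folds the escape from the disappearing branch is
slow ("ghost" dynamics), so finite settling times shift the apparent
jump slightly beyond the static fold — an expected property of
quasi-static protocols, not a numerical artefact.

Steady states are found by damped Newton iteration on
conservation-reduced coordinates: the state is parameterised as
`y = y0 + N z` where `N` is an orthonormal basis of the null space of
the moiety-law matrix, which keeps every conserved total exact and makes
the reduced Jacobian nonsingular at hyperbolic fixed points. Stability
is classified from the eigenvalues of that reduced Jacobian (threshold
1e-8 s⁻¹ for "marginal"), and saddles between two attractors are located
by bisecting the basin boundary along the connecting segment and letting
a short trajectory run toward the saddle along its stable manifold
before the final Newton polish. Seed states for the search are
interpolations between constructed low-activity and high-activity
extremes projected onto the compatibility class of the initial state.

## Inputs and study conditions

Inputs are forced (clamped, time-varying) species. Each presynaptic spike
evokes a normalised alpha-function transient `(t/τ)·e^(1−t/τ)` with unit
maximum at `t = τ`. Calcium uses 8 spikes at 100 Hz per train, six trains
10 s apart, transients combined by pointwise maximum (not summation), so
the waveform is bounded by basal + amplitude; dopamine contributes one
pulse per train, combined the same way. Defaults, chosen once as this
package's study conditions:

* `τ_ca = 0.3` s, `τ_da = 0.3` s (sub-second transient decay);
* basal calcium 0.06 µM; weak/strong calcium amplitudes 1 and 10 µM;
* basal dopamine 0.003 µM (low-nanomolar tonic level), phasic amplitude
  1 µM; the dopamine-depletion condition sets basal and amplitude to 0,
  and the hyperdopaminergic condition raises basal to 0.008 µM;
* experiments start from `pre_equilibrate()`'s resting state (chunked
  stiff integration to `max|dy/dt| < 1e-9` µM/s plus a Newton polish)
  and are evaluated 600 s after stimulation onset (a 2400 s option
  probes persistence).

Numerical settings: `deSolve::lsoda` with `rtol 1e-8`, `atol 1e-12` µM
and the analytic mass-action Jacobian; because the pulses are brief, the
solver's maximum step is capped at τ/4 inside stimulus windows so no
transient can be stepped over (outside the windows the step is free).
The default map resolution in the command-line driver is a coarse 4×4
grid; resolution affects smoothness only, not the depression/potentiation
topology.

## What the model reproduces

With the shipped parameterisation, from the control resting state:

* weak calcium alone depresses (ratio ≈ 0.52) and strong calcium alone
  potentiates (≈ 1.46); dopamine alone potentiates (≈ 1.7) with a clear
  rise of phospho-Thr34 and a fall of phospho-Thr75; dopamine coincident
  with weak calcium converts depression to potentiation (≈ 1.13);
* under dopamine depletion, weak calcium input leaves efficacy near 1
  (≈ 0.94–0.95, at the edge of the 5% band — see limitations);
* fixing PP1 at its resting activity yields potentiation for every
  input; fixing PKA removes the dopamine dependence; fixing CaMKII
  removes calcium-driven potentiation;
* removing the CK1→Cdk5 step eliminates Thr75 phosphorylation and with
  it the weak-calcium phospho-Thr75 rise;
* dopamine arriving 500 ms after the calcium train is the most
  effective of the three timings (calcium inhibits the cyclase during
  the train, so dopamine that follows it meets a disinhibited cyclase);
* raising basal dopamine from 0.003 to 0.008 µM flips the loop to its
  high-PKA state: resting membrane AMPAR roughly doubles (×2.05) and
  inputs that potentiated at control now depress.

## Known limitations

These are properties of the reported behaviour of this system that the
present parameterisation does not reproduce, found and characterised
during development:

* **Knockout of DARPP-32 does not abolish calcium-driven potentiation.**
  It does flatten the dopamine dependence (the loop's amplification is
  gone), but the CaMKII→Ser831 route is structurally independent of
  DARPP-32 here and can still potentiate from the knockout's resting
  state. Coupling strong enough to remove it (a much stronger PKA→PDE
  negative feedback) destroyed the dopamine rescue of weak-calcium
  depression and was reverted.
* **The strong-calcium fall of phospho-Thr75 is transient.** Free
  phospho-Thr75 dips well below baseline during and shortly after the
  stimulus trains (calcium-bound PP2A is a pulse-gated trigger), but by
  600 s the net level is above baseline; the weak-calcium rise holds at
  all times.
* **The hyperdopaminergic condition raises resting PKA by more than
  two-fold.** The loop's switch-like character makes the PKA step large
  (≈8×) even though the membrane-AMPAR doubling is quantitative.
* The depletion condition sits at ratio ≈ 0.945, marginally outside a
  strict ±5% band, because the residual receptor-phosphorylation tone
  from basal cyclase activity still responds slightly to calcium.

The acceptance-style tests in `tests/testthat/test-acceptance.R` assert
all of the above at face value; the assertions corresponding to the
first and last bullets fail by design rather than being weakened.

## What the toy generators emulate

`generate_fixture()` produces analytically solvable networks used as
test oracles: a single binding reaction (quadratic equilibrium), an
enzymatic reaction in the `E ≪ S` regime (Michaelis–Menten initial
velocity), an autocatalytic phosphorylation cycle against a saturable
phosphatase (a minimal bistable switch), and random small networks for
brute-force derivative and conservation checks. They share the
integrator and assembly code with the full model but none of its
biology; passing those oracles validates the numerics, not the
parameterisation.

## A worked session

```{r example}
library(spinesim)

net <- build_network()          # 72 reactions from the packaged tables
rest <- pre_equilibrate(net)    # control resting state

tc <- run_experiment(net,
                     calcium_protocol(ca_amp = 1),
                     dopamine_protocol(da_amp = 1),
                     y0 = rest)
plasticity_ratio(tc, net)       # > 1: dopamine rescues weak-calcium LTD

sub <- feedback_subsystem(net)
find_steady_states(sub)         # two stable states and a saddle
```
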