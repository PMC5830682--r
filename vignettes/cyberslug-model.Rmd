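---
title: "The Cyberslug foraging model: equations, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Cyberslug foraging model: equations, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyberslug)
```

This vignette documents the model this package implements, the meaning
and provenance of every tunable parameter, the numerical and design
choices that were genuinely open, and what the simulated experiments can
and cannot tell you about real foraging animals.

## The model in one pass

A single predator agent moves through a toroidal grid arena. Each prey
deposits odor on its cell every step: betaine (an innate feeding
stimulant common to all prey) plus a species signature odor. Fields
diffuse by an 8-neighbour kernel and decay multiplicatively, producing
quasi-static exponential plumes around each prey.

Each time step the agent:

1. reads the three odor fields at two anterior sensors and log-scales
   them (`sample_sensors()`);
2. computes the somatic map, a signed laterality code in which logistic
   gates suppress the weaker signature odor (`somatic_map()`);
3. evaluates incentive from betaine and the learned associations `Vh`
   and `Vf` (`incentive()`);
4. evaluates satiation from nutrition (`satiation()`);
5. integrates both, plus the previous step's switch state, into the
   appetitive state (`app_state()`), and passes it through the steep
   approach-avoidance switch (`app_state_switch()`);
6. turns: a decision turn whose amplitude comes from the switch and
   somatic map (`turn_angle()`) when any odor is present, otherwise a
   uniform ±1° wander (`wander_turn()`); then advances at constant
   speed;
7. consumes any prey within the consumption radius of its mouth,
   gaining nutrition and updating `Vh`/`Vf` by the Rescorla-Wagner rule
   (`rw_update()`, `on_consumption()`); consumed prey respawn at random
   positions so populations are constant.

The decision structure produces the animal's signature behaviours: an
inverted-U of approach as a function of satiation, consumption of
learned-noxious prey near starvation, and avoidance of attractive prey
when satiated.

## Parameters

Three groups of parameters exist, with very different provenance.

**Fixed by the source model's text** (do not change these if you want
the published protocol): the Rescorla-Wagner parameters `alpha = 0.5`,
`beta = 1`, `lambda = 1`; nutrition decay `0.0005` per step and gain
`0.3` per prey; initial nutrition `0.8`; appetitive-state baseline
`0.01`; switch threshold `0.245`; the `3` multiplying the somatic map in
the turn equation; the ±1° wander; 150,000 steps and 6 trials per
experimental condition; prey censuses of 10 Flab + 3 Hermi, 13 Flab, or
13 Hermi.

**Gain constants `k0`–`k9`** (`cs_constants()`): the published equations
use these coefficients but their numeric values live only in the
original interactive implementation, which this package does not copy.
The defaults shipped here were calibrated once, by simulation against
the published behavioural patterns, and then frozen; they are not
fitted per run. Their roles:

| constant | role | default |
|---|---|---|
| `k0` | surround-suppression gate steepness in the somatic map | 2 |
| `k1` | divisive attenuation of betaine by the learned hermi term | 0.1 |
| `k3` | gain of the learned associative terms R⁺/R⁻ | 1.03 |
| `k4` | satiation curve shape (shifts the curve along nutrition) | 3 |
| `k5` | incentive gain in the appetitive-state sigmoid | 1.67 |
| `k6` | satiation gain in the appetitive-state sigmoid | 80 |
| `k7` | transient appetitive suppression per Eq. for App_State | 0.1 |
| `k8` | switch steepness around the 0.245 threshold | 40 |
| `k9` | maximal decision-turn amplitude (degrees/step) | 8 |

The calibration was anchored to behavioural identities rather than
curve-fitting: a permanently hungry agent must consume learned-noxious
prey freely (this caps `k5·k3`-type products), a moderately hungry agent
must refuse them (this sets `k6` against the satiation curve), and the
homeostatic equilibrium nutrition implied by each published consumption
rate fixes where the approach ceilings sit. `k7` doubles as an
avoidance latch: when appetitive state hovers at the threshold the
suppression term breaks the tie toward avoidance, which is what the
transient suppression during turning describes.

**Environment constants** (`arena_config()`, `sensor_geometry()`,
`scenario_config()`): arena 50×50 wrapping cells, diffusion rate 0.3,
decay rate 0.35, emission 0.5 per channel per step, prey step 0.05 with
±30° heading jitter, consumption radius 1.0 from the mouth, body length
4 cells, sensors at 0.45 body lengths and ±40°, agent speed 0.12
cells/step, sensor floor 1e-7. None of these are stated numerically in
the source text either. They were chosen so that (i) a lone prey's
plume is detectable roughly three body lengths away with a steep enough
log-gradient for stable chemotaxis, and (ii) the unrestrained agent's
consumption rate matches the published scale (hundreds of prey per
150,000-step trial). The arena is deliberately a dense "soup" —
inter-prey spacing a small multiple of the plume radius — which is the
regime in which short-range decisions, not long-range search, dominate
prey choice.

## Numerical and semantic choices

- **Log sensor transform.** The text says only "logarithmic functions".
  We use `max(0, log10(c / floor))` with floor 1e-7: zero at zero
  concentration, finite everywhere, and a 10× concentration ratio reads
  as exactly one unit. The floor also bounds plume detection range, and
  the same threshold defines "engagement" (decision turn vs. wander).
- **Eq. for App_State is self-referential** (it contains the switch,
  which depends on App_State). Resolved with a one-step time lag: the
  suppression term uses the previous step's switch. The term follows
  the printed formula literally — it vanishes at switch = +1 and is
  maximal at −1 — even though the prose says suppression accompanies
  avoidance; the formula is the authority here and the tension is
  documented rather than "fixed".
- **Turn side.** The turn equation's sign tracks the switch (negative in
  approach), so by itself it cannot steer toward stimuli on both sides.
  It is treated as a signed amplitude; the somatic map's sign supplies
  the side (heading change = −sign(somatic map) × turn angle, in a
  counterclockwise-positive convention). This reading — amplitude from
  the switch, somatotopy from the place code — follows the stated role
  of the somatic map as the template for turn direction and magnitude,
  and is the only variant of the sign conventions that produced stable
  approach homing *and* effective avoidance in simulation; single-signed
  alternatives orbit plumes indefinitely.
- **Diffusion operator.** The NetLogo-style `diffuse`: each cell shares
  `diffusion_rate` equally with its 8 neighbours, then decays. On a
  torus (default) and on reflecting-edge grids the operator conserves
  mass exactly at zero decay (edge cells keep undistributed shares);
  this is tested to 1e-9.
- **Mechanism inactivation.** "No learning" freezes `Vh = Vf = 0`. "No
  satiation" clamps the satiation input of the appetitive-state
  equation to its value at zero nutrition (a permanently ravenous
  animal) while nutrition itself keeps evolving; both clamps are
  config-exposed.
- **Faux-Flab.** The Batesian mimic emits Flab's odor but carries
  Hermi's consequences. Its consumption applies an extinction-style
  update of `Vf` toward 0 plus the normal nutrition gain. This is an
  interpretation (the source text does not give the mimic's update
  rule); it defaults to zero animals.
- **Determinism.** All randomness flows through R's RNG; the compiled
  trial loop draws from the same stream, in a documented order, so a
  trial is a pure function of its seed, and `run_battery()` derives
  per-trial seeds from one master seed and records them. A composed
  R-level implementation of the identical update cycle
  (`cyberslug:::step_forager()`) is held equal to the compiled loop by
  a trajectory-equality test.

## What the experiments show — and what they don't

The packaged battery (`standard_scenarios()`) reproduces the published
protocol: four learning-by-satiation conditions in the 10-Flab/3-Hermi
arena plus the two single-species arenas, 6 trials × 150,000 steps. With
the shipped constants the qualitative pattern is robust: selectivity is
several-fold higher with both mechanisms than with any other
combination, satiation throttles total intake, learning alone does not,
and the all-Hermi arena yields far more consumption than the all-Flab
arena. The acceptance script (`scripts/acceptance.R`) recomputes the
battery's summary numbers from one seed.

These are properties of a stylized world: deterministic plumes without
turbulence, point sensors without noise or adaptation, constant prey
densities with instantaneous respawn, an abstract time step with no
metabolic cost of locomotion, and no handling time or prey escape.
Passing the battery therefore shows the *decision architecture*
reproduces the animal-like selectivity pattern under the stated
conditions; it does not validate the environmental physics against real
chemical plumes, and quantities tied to environmental detail (absolute
consumption counts, plume shapes) should be read as calibrated, not
predicted. Known limitations inherited from the source model: no pain
pathway, no habituation/sensitization or extinction (outside the mimic
rule), a fixed switch threshold, and steering from two point sensors
only.

## Problem sizes used in the automated checks

The test suite exercises full-length (150,000-step) trials with 3 trials
per condition for the battery orderings, and shorter seeded runs
(hundreds to tens of thousands of steps) for behavioural and invariant
checks; the acceptance script runs the full 6-trial protocol. On a
current single core a full trial takes a few seconds.
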