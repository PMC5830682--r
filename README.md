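# cyberslug

An agent-based, headless simulation of approach-avoidance foraging
decisions in the predatory sea-slug *Pleurobranchaea californica*. A
single virtual predator forages on a 2D odor landscape among two virtual
prey species — "Hermi" (*Hermissenda*: benign, rewarding) and "Flab"
(*Flabellina*: noxious, aversive) — and decides, moment to moment, whether
to approach or avoid what it smells. The package is for computational
neuroethologists and behavioral modelers who want a seeded, scriptable,
fully testable version of this classic neuroeconomic agent: every
mechanism is a plain R function, every experiment a deterministic function
of one integer seed.

## The model

Behavioral choice is organized around a single affective variable, the
appetitive state, which integrates sensation, motivation and memory:

- **Learning.** Consumption events condition the prey signature odors by
  the Rescorla-Wagner rule, ΔV = αβ(λ − V), with α = 0.5, β = 1, λ = 1:
  `Vh` accumulates the positive association of the Hermi odor, `Vf` the
  negative association of the Flab odor.
- **Sensation.** Two anterior sensors (±40° off the body axis, just under
  half a body length ahead) read log-scaled odor intensities of betaine
  (an innate resource signal every prey emits) and the two signature
  odors. Their bilateral differences, gated by logistic surround
  suppression of the weaker odor, form a somatic map — a signed place
  code of stimulus laterality; their bilateral means drive valuation.
- **Incentive.** R⁺ = sns_betaine / (1 + k₁·Vh·sns_hermi) +
  k₃·Vh·sns_hermi and R⁻ = k₃·Vf·sns_flab combine as
  Incentive = R⁺ − R⁻: a naive animal tracks betaine; a trained one
  weights the learned odor valences.
- **Homeostat.** Nutrition decays by 0.0005 per step and jumps by 0.3 per
  prey consumed; Satiation = 1/(1 + k₄·e^(−4·Nutrition+2))² maps it to
  (0, 1).
- **Decision.** App_State = 0.01 + σ(k₅·Incentive − k₆·Satiation) +
  k₇·(switch − 1) feeds a steep sigmoid switch through the threshold
  0.245: the switch sits near −1 (approach) or +1 (avoid) and sets the
  sign of the decision turn, Turn_Angle = k₉·switch /
  (1 + e^(3·Somatic_Map − switch)), whose side is supplied by the somatic
  map. Out of odor, the agent wanders (heading jitter uniform in ±1°).

Hunger and learning interact exactly as in the animal: a starving agent
attacks even prey it has learned are noxious, a satiated one avoids even
attractive prey, and selective foraging emerges only when learning and
satiation operate together.

## A worked example

One short trial (20,000 steps) in the standard 10-Flab/3-Hermi arena with
both mechanisms enabled:

```r
library(cyberslug)
sc <- scenario_config(arena_config(n_flab = 10, n_hermi = 3),
                      n_steps = 20000)
r <- run_trial(sc, seed = 1)
print(as.data.frame(r), digits = 3)
#>   seed consumed_flab consumed_hermi consumed_fauxflab total pct_hermi
#> 1    1             5              7                 0    12      58.3
#>   selectivity
#> 1         1.4
```

Twelve prey were taken, 7 of them Hermi (58.3%), giving a selectivity
(Hermis per Flab consumed) of 1.4 — already well above the 0.30
Hermi:Flab ratio of the population, because the agent has learned both
associations and is only moderately hungry. Full-length trials (150,000
steps, `standard_scenarios()`) sharpen this contrast and add the control
conditions with learning and/or satiation inactivated.

Per-step interface readouts (position, Nutrition, Satiation, Incentive,
App_State, App_State_Switch, Turn_Angle, Vh, Vf) are available with
`run_trial(..., trace_every = 10)` as the `"trace"` attribute.

A command-line runner for batch experiments ships in
`inst/scripts/cyberslug.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/cyberslug.R", package="cyberslug"))')" \
  run --trials 6 --steps 150000 --seed 1 --out results/ --trace-every 100
```

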