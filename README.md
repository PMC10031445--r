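# diag360

A config-driven engine for the "360-degree" diagnosis of people with type 2
diabetes (T2D) in Dutch primary care. Beyond the usual clinical markers,
the health and quality of life of a person with T2D depend on mental
health, lifestyle behavior and the socioeconomic environment. diag360
implements a holistic diagnostic workflow for that setting: it ingests one
patient's clinical measurements and questionnaire responses across **four
domains** — *body*, *thinking and feeling*, *behavior*, *environment* —
classifies **21 parameters** into traffic-light statuses, renders the
**profile wheel** (four equal quadrants, one colored icon per parameter,
with click-through detail panels), matches flagged parameters to an
**intervention catalog**, represents the **15-card motivational-interviewing
consultation deck**, and compares baseline and follow-up assessments.

It is intended for digital-health researchers and developers who need a
testable, declarative re-implementation of this class of decision-support
scoring engine, including a seeded synthetic-patient generator so every
component is verifiable without real patient data.

## The model

Each *parameter* (e.g. blood pressure) consists of measurable *elements*
(systolic and diastolic pressure). Every element `e` with value `x` is
classified by an ordered set of cutoff bands

```
status(e) = color of the unique band B_i with x ∈ [l_i, u_i)
```

(bands are half-open and left-closed by default; inclusivity flags are
explicit config data so rules such as "score ≤ 50 is red" are expressible).
Element statuses are combined into the parameter status by a decision
rule; the default is worst-of over the severity order green < orange <
red, with any unmeasured (gray) element forcing the parameter gray:

```
status(p) = gray                         if any required element is gray
          = max_severity{status(e_j)}    otherwise
```

For blood pressure this reproduces the published 3×3 combined decision
table exactly (e.g. systolic 140–<160 with diastolic ≥100 → red).
Questionnaire parameters are scored first with the instruments' published
arithmetic: the WHO-5 well-being index is 4 × (item sum) on a 0–100
scale with red ⇔ score ≤ 50 (depression screen, no orange); the 10-item
Perceived Stress Scale is a sum with reverse-keyed positive items; PAID-5
is a 0–20 sum; alcohol use is the frequency–quantity average
`(weekday glasses × days + weekend glasses × days) / 7` plus a binge flag,
and so on. All cutoffs, scales and rules live in a versioned JSON config
(`inst/extdata/reference_config.json`), never in code.

## Worked example

```r
library(diag360)
cfg <- load_reference_config()
a   <- read_assessment(system.file("extdata", "demo_assessment.json",
                                   package = "diag360"), cfg)
p   <- build_profile(a, cfg)
print(p)
#> <diag360 profile: patient 'demo-001' at 2026-02-03 (config nl-default-1.0)>
#>   parameters: 9 green, 11 orange, 1 red, 0 gray

classify_blood_pressure(150, 95, cfg)
#> [1] "orange"
classify_mental_health(48, cfg)     # WHO-5 score of 48 -> depression screen
#> [1] "red"

head(profile_table(p, cfg), 3)
#>         parameter_id domain_id          label status
#> 1 glucose_metabolism      body    Blood sugar orange
#> 2     blood_pressure      body Blood pressure orange
#> 3        cholesterol      body    Cholesterol orange

advice <- match_interventions(p, load_reference_catalog(),
                              context = "nationwide_web")
advice[1:3, c("id", "priority", "matched_parameters")]
#>                          id priority matched_parameters
#> 1           mindfulness-app      red      mental_health
#> 2      sleep-stress-program      red      mental_health
#> 3 diabetes-education-center   orange   perceived_health
```

The demo patient screens red on mental health (WHO-5 = 48 ≤ 50), orange
on eleven parameters (elevated blood pressure, HbA1c, weight, ...), and the
matcher lists red-targeting interventions before orange-targeting ones.
`render_report(p, cfg, "report/")` writes the wheel SVG, 21 detail panels
and a linking HTML index; the same pipeline is scriptable via the CLI
(`inst/cli/diag360`): `score`, `render`, `advise`, `protocol`, `compare`,
`simulate`.

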