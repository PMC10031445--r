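---
title: "diag360: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diag360: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diag360)
```

## The diagnostic model

diag360 models a holistic ("360-degree") diagnosis for people with type 2
diabetes as a three-layer hierarchy, all declared in a versioned JSON rule
config:

* **Domains** (exactly 4): body; thinking and feeling; behavior;
  environment. For visualization and comprehensibility a domain carries at
  most 6 parameters — this is enforced at config load and again by the
  renderer, never silently truncated.
* **Parameters** (21 in the reference config: 5 + 5 + 6 + 5): changeable
  risk factors or barriers, e.g. blood pressure, mental health, alcohol
  consumption, housing. Each shows as one icon on the profile wheel.
* **Elements**: the measurable components of a parameter (blood pressure =
  systolic + diastolic). Parameters measured by a single instrument score
  (e.g. perceived stress) are modeled uniformly as single-element
  parameters whose element *is* the score.

Classification proceeds in a fixed order: instrument scoring → cutoff
banding per element → decision-rule combination per parameter. The whole
engine is deterministic given (assessment, config), and the config id is
recorded in every profile for provenance.

### Cutoff bands

Each numeric element declares a valid range and an ordered set of bands
(green / orange / red) that must be pairwise disjoint and jointly cover
the range — validated at load, so a value inside the range can never fall
through. Bands are half-open and left-closed by default, matching the
published blood-pressure table ("140 to <160" is orange, so 140 itself is
orange). Inclusivity flags are explicit per bound because one published
rule genuinely needs the other convention: WHO-5 well-being ≤ 50 is red,
> 50 is green, with *no orange anywhere* — a two-color screen for
depression. The printed source is internally inconsistent about diastolic
pressure at exactly 100 mm Hg (its per-element column says orange up to
100, its combined table says red from 100); we follow the combined table
and the uniform left-closed convention, so diastolic 100 is red.

Only the blood-pressure and WHO-5 cutoffs are published. Every other band
(glucose, lipids, weight, kidney, stress, diet, activity, environment) is
a documented default chosen once from common Dutch primary-care guideline
values (e.g. BMI ≥ 25 overweight, ≥ 30 obese; 150 minutes/week of
moderate activity; PSS-10 tertiles 14 and 27; PAID-5 distress cutoff 8,
another two-color scale). They are config data, flagged as defaults in the
config's own `note` field, and are expected to change with guidelines
without touching code.

### Decision rules

The default combiner is **worst-of**: the parameter takes the maximum
severity among its element statuses. Rationale: the only combined rule the
source prints (blood pressure, 3×3) is provably max-severity, and no other
combined table is given; the test suite asserts this equivalence
exhaustively. An `explicit_table` rule kind exists for parameters that
would need a non-monotone combination; the reference config uses worst-of
everywhere. Missing data propagate strictly: any required element gray
(unmeasured) makes the parameter gray. No partial-credit rule is defined —
the source shows gray icons when questions are unanswered, and we chose
the conservative reading over inventing an imputation.

### Instrument scoring

Instrument item counts and scales are config data. Scoring follows each
cited instrument's published arithmetic; where the source names an
instrument without details, the most common primary-care version was
chosen once:

* **WHO-5**: five items 0–5, score = 4 × sum (0–100). All items required.
* **PSS**: 10-item version assumed (the source does not state 4/10/14);
  sum 0–40 with reverse-keyed positive items (4, 5, 7, 8). All items
  required.
* **PAID-5**: five items 0–4, sum 0–20. The source reordered the response
  categories after usability testing; standard numeric coding is assumed
  unchanged.
* **Alcohol**: a five-question frequency–quantity schema (the cited item
  set is not reproduced, so this is an interpretation): abstinence
  auto-routes both outputs to zero; average glasses/day =
  (weekday glasses × weekday days + weekend glasses × weekend days) / 7;
  binge threshold ≥ 6 glasses per occasion (common Dutch heavy-drinking
  definition, configurable), and reported glasses at or above the
  threshold floor the binge-frequency answer at "weekly".
* **SQUASH-style activity**: guideline minutes/week summed over activity
  blocks; absent blocks count as 0 minutes, but a fully absent instrument
  is "unavailable" (gray), not 0.
* **Sitting**: Marshall-style weekday/weekend hours, 5:2 weighted average.
* **DSMQ**: two 4-item 0–3 subscales (glucose monitoring, medication
  adherence), each transformed to 0–10 as sum/(3·n)·10.
* **Single SF-36 items** (perceived health, pain) and the environment
  items are kept as ordinal categories 1–5, untransformed.

A missing required item always yields an explicit "score unavailable"
signal (`NA` → gray), never a silent number; malformed responses (wrong
count, out-of-range values) are errors.

One modeling ambiguity is flagged rather than hidden: the cholesterol row
lists "ratio HDL and triglycerides" as one element string; we model it as
two elements (total/HDL ratio and triglycerides), which is the clinically
standard reading.

## The profile wheel

The wheel is standalone SVG 1.1: four equal 90° quadrants in domain
order, up to six icons per quadrant placed at equal angles, fill color
from a four-color map (green/orange/red/gray). The figures of the original
tool do not specify quadrant order, starting angle or icon artwork, so
these are free layout choices: body starts top-left and quadrants proceed
clockwise; icons are simple circles with two-letter glyphs keyed by
`icon_id`. Every icon carries a stable id and a `data-detail` link target,
and the HTML report gives every parameter a click-through detail panel
(an explicit fix in the original's evaluation). Detail panels draw each
element as a horizontal bar with band-colored segments scaled to the
element's valid range, the score as a black number and a black triangle
marker at its position; unanswered elements get a "not answered"
annotation and no marker. Rendered text uses the config's lay labels
("Blood sugar", not "glucose") — a label-table property, asserted by
parsing the SVG, not hard-coded strings. Numeric labels print integers
without decimals and continuous values with one decimal; the decimal
separator is a layout option (default "."). Rendering is deterministic:
identical inputs give byte-identical SVG (fixed two-decimal coordinate
formatting, no timestamps).

## Advice matching

An intervention catalog entry has one of 7 categories and one of 3
availability classes (closed enumerations), plus target parameters. The
matcher returns entries that target at least one orange/red parameter and
whose availability is in the caller's context. The source gives no ranking
rule, so the minimal clinically sensible default is used and documented:
entries targeting a red parameter come first, ties keep catalog order.
The engine returns the ranked list; choosing a single intervention is a
human step in the consultation. The packaged 27-entry catalog is
synthetic but category-faithful (real intervention names and locations are
not reproduced).

## Consultation protocol and follow-up

The 15-card deck ships as packaged JSON with the printed titles, kinds
(front matter, MI skills, steps 1–5) and, for the rounding-up card, the
summary fields (current situation, goal parameter, chosen intervention,
backup plans, resources). Only two cards' prose is public, so card bodies
are paraphrased placeholders keyed to the titles, intended for
replacement. `render_protocol()` emits printable markdown; with a profile
it embeds the orange/red parameters into the step-1 agenda.

Follow-up comparison works at parameter granularity (the wheel's own
granularity): severity decrease = improved, increase = worsened, and the
gray transitions are reported as newly_measured / no_longer_measured /
still_unmeasured. Profiles from different config versions are
incomparable by design. No minimum interval is enforced — "about 3
months" is procedural guidance, not validation. Visualizing change over
time beyond the two-timepoint table is deliberately out of scope.

## Synthetic patients

The generator is **inverse sampling**, not an epidemiological model: per
parameter it draws a target status from the configured prevalence, then
samples element values uniformly inside a band of that color — for
questionnaire parameters it picks an attainable score in the band and
distributes it over items by a constrained sequential composition
(approximately, not exactly, uniform over compositions). For multi-element
parameters one eligible element carries the non-green target and the rest
are green, which is the canonical worst-of witness. This guarantees that
with no missingness `build_profile` recovers every drawn target exactly —
the module's core acceptance property — and that observed prevalences are
binomial around the spec.

Defaults state the simulated world once: prevalence green/orange/red =
0.60/0.25/0.15 (a plausible mix for a treated primary-care T2D
population; the source reports no prevalence), missing rate 0, and for
two-color parameters (WHO-5, PAID-5) the default orange mass folds into
green, while an *explicit* request for an unreachable status is a
validation error. Alcohol answers are drawn below the binge threshold
unless binge is the target, so the derived binge flag never overrides the
drawn status; activity draws are capped at the instrument's distribution
capacity (5 single-day blocks × 720 minutes). Patient *i* seeds its own
stream from `seed + i`, so records are independent of `n_patients`.

What a green test therefore establishes: the scoring–banding–combining
pipeline is exactly invertible and prevalence-calibrated under the stated
config. What it does not establish: realism of between-domain correlation,
response styles, or measurement error — none are emulated.

## Numerical and I/O choices

* Canonical JSON everywhere: recursively sorted keys, full numeric
  precision, `null` for absent, newline-terminated — this is what makes
  the serialize→parse→serialize byte-identity tests possible. Dates are
  ISO-8601; serialized numbers always use the decimal point.
* Band coverage validation requires exact bound adjacency with exactly one
  closed side per boundary; no tolerance is applied (cutoffs are exact by
  definition).
* Unknown schema versions are rejected, never coerced; assessment
  validation reports *all* violations at once, naming each field.
* Config documents are JSON (the environment's R stack has no YAML
  parser); the schema is format-agnostic and unchanged.

## Known limitations

* All non-published cutoffs are defaults, not clinically validated for
  any population; the package is a research artifact, not a medical
  device.
* Card-deck prose and icon artwork are placeholders.
* The generator's independence assumptions make it unsuitable for
  epidemiological simulation.
* Trend analysis over more than two timepoints is out of scope.
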