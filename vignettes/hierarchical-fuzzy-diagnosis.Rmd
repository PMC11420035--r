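---
title: "Hierarchical fuzzy diagnosis of migraine and tension-type headache"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical fuzzy diagnosis of migraine and tension-type headache}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyichd)
```

## The diagnostic model

The engine diagnoses the four ICHD-3 labels in scope — migraine without
aura (MO), probable migraine (PM), tension-type headache (TTH) and
probable tension-type headache (PTTH) — from ten features of a single
patient record: attack count, attack duration (hours, possibly a range),
VAS intensity (0–10), location, quality, aggravation by activity, and four
accompanying symptoms. It assumes secondary headaches, migraine with aura,
cluster and chronic headaches have been excluded upstream; it offers no
treatment advice.

Two stages cooperate:

* a **crisp backbone** that applies the ICHD-3 criteria verbatim
  (`rule_based_diagnose()`), including the "probable" semantics of all-but-one
  failed criterion, and
* a **three-level fuzzy stage** (`fuzzy_diagnose()`) used whenever the
  backbone reaches no definite diagnosis. We trigger the fuzzy stage on
  *any* non-definite outcome, not only on a crisp probable diagnosis: the
  motivating boundary cases (e.g. 4 attacks of 2–12 h) fail *two* crisp
  criteria yet clearly deserve a fuzzy look, and a definite crisp diagnosis
  is never overridden (a tested invariant).

The fuzzy stage evaluates pain-characteristic criterion C as a small
Mamdani system (level 1), accompanying-symptom criterion D with two-valued
logic (level 2), and combines their binary outcomes with the fuzzified
attack count and duration in a generated rule base (level 3). Rule
activation is the min t-norm; same-consequent activations are **summed**
(not maxed — the worked examples produce per-term activations above 1,
which only summation can yield); the weighted-average defuzzifier over the
output constants (definite 2, probable 1, others 0) gives a crisp score per
output variable. C enters level 3 through its binary fulfilment
(degree ≥ 0.5), matching the way the published example rules are written;
its continuous degree is kept in the trace.

## Membership-function reconstruction

Only a handful of numeric facts about the membership functions are
published: 5 and 10 attacks are boundary values, μ_low(4) = 1/3 and
μ_moderate(4) = 1/2 for the attack count, and the worked cases' activation
vectors. The shipped breakpoints are the simplest piecewise-linear family
consistent with all of them, under one design rule: **each ramp reaches its
criterion-satisfying value exactly at the ICHD boundary**, so a feature at
the boundary behaves crisply and only sub-threshold values are softened.

* Attack count: low (2,1)→(5,0); moderate (3,0)→(5,1), plateau to 8,
  (8,1)→(10,0); high (8,0)→(10,1). The two anchor degrees at 4 force the
  low/moderate ramps; the width-2 ramps at the 10-attack boundary mirror
  the rise into 5.
* Duration: very short (0,1)→(0.5,0); short rises over (0,0.5), falls
  (4/3,1)→(4,0); moderate (4/3,0)→(4,1), plateau to 72, (72,1)→(96,0);
  long (72,0)→(96,1), plateau to 168, (168,1)→(224,0); very long
  (168,0)→(224,1). The (4/3, 4) ramp is *forced* by worked case 1
  (μ_short(2) = 0.75 with the boundary at 4 h); the upper ramps use the
  same relative width (a third above the boundary), reflecting recall
  error that scales with magnitude.
* Intensity: the conventional VAS bands mild ≤ 3, moderate 4–6,
  severe 7–10, with unit-width linear shoulders (crossing 0.5 at 3.5 and
  6.5). No published number constrains these; the crisp backbone uses the
  0.5-crossings as its band cutoffs so the two stages agree by
  construction.

The five duration terms partition the axis, so we did not ship the coarse
catch-all duration term that appears in one published example rule; rule
generation over the five terms covers the same combinations explicitly.

**Duration ranges are fuzzified at their lower endpoint.** A symmetric
midpoint may look more natural, but criterion B requires *every* attack
inside the window and short attacks are the common failure mode; the
worked case (2 h–half a day) only reproduces under the lower endpoint
(degrees 0.75 short / 0.25 moderate at 2 h), while its geometric midpoint
(4.9 h) lies inside the migraine window and cannot. The crisp backbone
still requires the whole range inside the window.

With these choices, worked case 1 reproduces end-to-end to four decimals:
migraine activations (0.25, 0.75, 0.3333), f = 0.9375 → PM; tension-type
(0, 0, 1.33333), f = 0. Worked case 2 reproduces in label (PTTH,
f_migraine = 0) but not in its published activation values (we obtain
α₂ = 2/3, α₃ = 1/3, f_tth = 0.6667 against published 0.7333/0.6666/0.5238).
Those three numbers cannot be attributed to any principled breakpoint set
we found — matching them requires the low-attack support to end at 4.83
rather than 5 and sub-half-hour memberships summing to 1.4 — so we document
the residual rather than tune to it. Both engine conclusions, which is what
the defuzzified scores exist to produce, agree with the expert panel.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| output constants | 2 / 1 / 0 | fixed by the published defuzzifier |
| fulfilment threshold for C | 0.5 | midpoint of fit/unfit; the crisp backbone's band cutoffs coincide with the 0.5-crossings |
| label mapping | nearest constant | ties toward the lower-severity label (non-diagnosis is the safe default) |
| output tie f_mig = f_tth > 0 | migraine | higher prevalence in both validation cohorts |
| degree comparisons | 1e-9 absolute | floating-point guard only |

Degenerate inputs: if no rule fires for either output the defuzzifier is
0/0; `defuzzify_weighted_average()` signals a
`fuzzyichd_no_applicable_rule` warning and returns `NA`, and the engine
maps the case to `others` rather than fabricating a score of 0. Ratios
with empty denominators in the evaluation layer are reported as undefined
(`NA`), never as 0.

## Evaluation layer

Per-class metrics collapse the 5×4 agreement table to 2×2 with every
non-positive prediction (including the engine's `others`) counted
negative. Cohen's kappa uses the same collapse; its standard error is the
Fleiss–Cohen–Everitt large-sample formula and the significance test uses
the null (κ = 0) standard error. Recomputing the published retrospective
per-class kappas this way matches TTH (0.991), PM (0.916) and PTTH (0.932)
to three decimals; MO computes to 0.981 against a published 0.984, a
~0.003 discrepancy whose origin (collapse convention or software settings)
is not recoverable — the tests assert it as a known deviation. The
published Youden entries are formed from the 2-dp rounded percentage
sensitivity and specificity, and the tests reproduce them through that
identity. Published confidence-interval *bounds* match neither exact
Clopper–Pearson nor Wilson on spot checks; both methods are provided
(Clopper–Pearson default) and the bounds are not treated as a
reproduction surface.

## Synthetic cohorts

`generate_cohort()` draws features **independently** from the validation
cohorts' published marginal summaries (sex, age, duration, attack-count
bins, location, quality, VAS, symptom prevalences) — no joint distribution
is published, so no dependence structure is imposed. Age, duration and VAS
are truncated normal (inverse-CDF); attack counts draw a bin
(below 5 / 6–9 / 10+) and then an integer uniformly inside it (1–4, 6–9,
10–60). The published duration summary (mean 17.0 h, SD 28.2) implies
strong right skew; the truncated normal is a declared stand-in, and tests
therefore compare sample means to the *truncated* distribution's closed
form. Archetype presets (`typical_mo`, `typical_tth`) clamp the
criterion-relevant features so every draw satisfies the definite criteria
by construction — these exist to smoke-test the engine, and passing them
shows internal consistency, not performance on real patients. Because
features are independent, synthetic cohorts do not reproduce the
label-conditional structure of the clinical tables and are not meant to.

Problem sizes used by the shipped tests: 1,000 random rule/input pairs and
1,000 random matrices for the property suites, cohorts of 10,000 for the
marginal checks (3 standard errors), 400 archetype cases for the label
smoke property. The whole suite runs in under two minutes on one CPU.

## Known limitations

* Worked case 2's activation vector is not reproduced (above); any
  breakpoint set that does so conflicts with the stated boundary values.
* The published cohort-level kappas and CI bounds as functions of raw
  patient records are not reproducible here: the records are unavailable
  and the CI method is unstated.
* Weighting of individual features or rules is not modelled; all clauses
  enter the min t-norm equally.
* Only MO/PM/TTH/PTTH are in scope; other primary and all secondary
  headaches must be excluded before the engine is consulted.
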