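# Reference engine configuration.
#
# Membership breakpoints are piecewise-linear (x positions with degrees);
# evaluation extends the terminal degree constantly beyond the range. Ramps
# end exactly at the ICHD-3 boundary values (5 and 10 attacks; 0.5, 4, 72
# and 168 hours), so a value at a boundary satisfies its criterion with
# degree 1 while values short of it degrade linearly. The attack-count ramps
# are fixed by the published anchor degrees mu_low(4) = 1/3 and
# mu_moderate(4) = 1/2.
tolerance: 1.0e-9

output_constants:
  migraine:     {definite: 2, probable: 1, others: 0}
  tension_type: {definite: 2, probable: 1, others: 0}

variables:
  number_of_attacks:
    unit: attacks
    terms:
      low:      {x: [2, 5],        degree: [1, 0]}
      moderate: {x: [3, 5, 8, 10], degree: [0, 1, 1, 0]}
      high:     {x: [8, 10],       degree: [0, 1]}
  duration:
    unit: hours
    terms:
      very short: {x: [0, 0.5],                          degree: [1, 0]}
      short:      {x: [0, 0.5, 1.333333333333333, 4],    degree: [0, 1, 1, 0]}
      moderate:   {x: [1.333333333333333, 4, 72, 96],    degree: [0, 1, 1, 0]}
      long:       {x: [72, 96, 168, 224],                degree: [0, 1, 1, 0]}
      very long:  {x: [168, 224],                        degree: [0, 1]}
  intensity:
    unit: VAS
    terms:
      mild:     {x: [3, 4],       degree: [1, 0]}
      moderate: {x: [3, 4, 6, 7], degree: [0, 1, 1, 0]}
      severe:   {x: [6, 7],       degree: [0, 1]}

# Pain-characteristic sets of criterion C ("at least two of four").
characteristics:
  migraine:
    location: unilateral
    quality: pulsating
    intensity_terms: [moderate, severe]
    aggravation_by_activity: "yes"
  tension_type:
    location: bilateral
    quality: non-pulsating
    intensity_terms: [mild, moderate]
    aggravation_by_activity: "no"

# Qualifying linguistic terms for criteria A (attack count) and B (duration)
# used when generating the third-level rule base: zero failed criteria give
# a definite consequent, exactly one gives probable, more give others.
criteria:
  migraine:
    attacks_terms: [moderate, high]
    duration_terms: [moderate]
  tension_type:
    attacks_terms: [high]
    duration_terms: [short, moderate, long]

# Crisp windows used by the rule-based backbone.
crisp:
  migraine:     {min_attacks: 5,  duration_window: [4, 72]}
  tension_type: {min_attacks: 10, duration_window: [0.5, 168]}
  intensity_cutoffs: {mild_max: 3.5, moderate_max: 6.5}
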