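# Default 34-item deficit codebook.
#
# Structure mirrors the published deficit-accumulation instrument for this
# cohort: 6 symptoms/signs, 15 comorbidities, 12 activities of daily living,
# 1 healthcare-utilization item.  Ordinal items use evenly spaced values in
# [0, 1]; binary items use {0, 1}.  The item wording here is a synthetic
# structural stand-in for the original (undeposited) survey codebook and can
# be replaced verbatim via read_codebook().
version: 1
items:
  # --- symptoms and signs (6) ---
  - id: feels_full_of_life
    domain: symptoms_signs
    levels:
      "all of the time": 0.0
      "most of the time": 0.25
      "some of the time": 0.5
      "a little of the time": 0.75
      "none of the time": 1.0
  - id: everything_an_effort
    domain: symptoms_signs
    levels:
      "none of the time": 0.0
      "a little of the time": 0.25
      "some of the time": 0.5
      "most of the time": 0.75
      "all of the time": 1.0
  - id: bodily_pain
    domain: symptoms_signs
    levels:
      "none": 0.0
      "very mild": 0.2
      "mild": 0.4
      "moderate": 0.6
      "severe": 0.8
      "very severe": 1.0
  - id: trouble_sleeping
    domain: symptoms_signs
    levels:
      "no": 0.0
      "yes": 1.0
  - id: dizziness
    domain: symptoms_signs
    levels:
      "no": 0.0
      "yes": 1.0
  - id: poor_appetite
    domain: symptoms_signs
    levels:
      "no": 0.0
      "yes": 1.0
  # --- comorbidities (15), all binary ---
  - id: osteoarthritis
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: rheumatoid_arthritis
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: osteoporosis_dx
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: hypertension
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: heart_disease
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: stroke
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: diabetes
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: copd
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: asthma
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: cancer
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: kidney_disease
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: ulcer_stomach_disease
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: thyroid_disease
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: depression_dx
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  - id: neurological_condition
    domain: comorbidity
    levels: {"no": 0.0, "yes": 1.0}
  # --- activities of daily living (12), 3-level ---
  - id: adl_vigorous_activities
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_moderate_activities
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_lifting_groceries
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_climbing_stairs
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_bending_kneeling
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_walking_several_blocks
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_bathing
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_dressing
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_shopping
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_light_housework
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_heavy_housework
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  - id: adl_preparing_meals
    domain: adl
    levels: {"no difficulty": 0.0, "some difficulty": 0.5, "unable": 1.0}
  # --- healthcare utilization (1) ---
  - id: overnight_hospitalizations
    domain: healthcare_utilization
    levels: {"0": 0.0, "1": 0.5, "2 or more": 1.0}
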