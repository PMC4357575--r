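# Cohort table column manifest (version 1).
#
# One row per participant.  Ordinal columns carry their response labels
# verbatim; the missing sentinel in CSV files is the empty string.  The 34
# deficit columns are not listed here: their names and levels come from the
# deficit codebook supplied alongside this schema.
version: 1
columns:
  - {name: participant_id, type: id}
  - {name: age, type: numeric, min: 55}
  - {name: bmi, type: numeric, min_exclusive: 0}
  - {name: smoker, type: binary}
  - {name: drinks_per_week, type: ordinal, levels: ["0", "<7", "7-13", ">=14"]}
  - {name: education, type: ordinal,
     levels: ["high school or less", "more than high school"]}
  - {name: baseline_falls, type: ordinal, levels: ["0", "1", ">=2"]}
  - {name: prior_fracture, type: binary}
  - {name: family_history_fracture, type: binary}
  - {name: sf36_pf_01, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_02, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_03, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_04, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_05, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_06, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_07, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_08, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_09, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: sf36_pf_10, type: ordinal,
     levels: ["limited a lot", "limited a little", "not limited at all"]}
  - {name: vit_worn_out, type: ordinal,
     levels: ["all of the time", "most of the time", "some of the time",
              "a little of the time", "none of the time"]}
  - {name: vit_full_of_life, type: ordinal,
     levels: ["all of the time", "most of the time", "some of the time",
              "a little of the time", "none of the time"]}
  - {name: vit_tired, type: ordinal,
     levels: ["all of the time", "most of the time", "some of the time",
              "a little of the time", "none of the time"]}
  - {name: vit_energy, type: ordinal,
     levels: ["all of the time", "most of the time", "some of the time",
              "a little of the time", "none of the time"]}
  - {name: walk20_days, type: integer, min: 0, max: 30}
  - {name: weight_loss_10lb, type: binary}
  - {name: fall_year3, type: binary, allow_missing: true}
  - {name: fracture_event, type: binary}
  - {name: fracture_time, type: numeric, min_exclusive: 0, max: 3.05}
  - {name: death, type: binary}
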