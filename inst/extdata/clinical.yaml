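# Printed two-arm trial tables: event counts per group and per-group
# clinical symptom score summaries (EG: herbal-combination arm, CG:
# methylprednisolone arm).
tables:
  - outcome: operation
    eg_events: 25
    eg_n: 80
    cg_events: 47
    cg_n: 80
  - outcome: recurrence
    eg_events: 3
    eg_n: 80
    cg_events: 10
    cg_n: 80
  - outcome: adverse_events
    eg_events: 5
    eg_n: 80
    cg_events: 9
    cg_n: 80
summaries:
  - measure: symptom_score_baseline
    eg: {n_patients: 80, mean: 13.90, sd: 2.37}
    cg: {n_patients: 80, mean: 13.423, sd: 2.70}
  - measure: symptom_score_post_treatment
    eg: {n_patients: 80, mean: 4.68, sd: 3.40}
    cg: {n_patients: 80, mean: 5.98, sd: 3.68}
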