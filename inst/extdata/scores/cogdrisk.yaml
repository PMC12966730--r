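# CogDrisk (Cognitive Health and Dementia Risk Assessment, Anstey et al.
# 2022). Editable transcription; the published tool grades several
# exposures more finely than the harmonized binary variables used here.
name: cogdrisk
description: >
  Multi-domain risk assessment covering cardio-metabolic, lifestyle,
  sensory and psychosocial factors with protective engagement weights.
items:
  - name: age
    type: banded
    source: age_baseline
    demographic: true
    bands:
      - {upper: 64.99, points: 0}
      - {upper: 69.99, points: 2}
      - {upper: 74.99, points: 4}
      - {upper: 79.99, points: 7}
      - {upper: .inf, points: 10}
  - name: sex
    type: categorical
    source: sex
    demographic: true
    mapping: {female: 0, male: 1}
  - name: education
    type: banded
    source: education
    demographic: true
    bands:
      - {upper: 11.99, points: 2}
      - {upper: .inf, points: 0}
  - {name: diabetes, type: binary, points_present: 2}
  - {name: depression, type: binary, points_present: 2}
  - {name: smoking, type: binary, points_present: 2}
  - {name: high_cholesterol, type: binary, points_present: 1}
  - {name: hypertension, type: binary, points_present: 1}
  - {name: obesity, type: binary, points_present: 1}
  - {name: heart_disease, type: binary, points_present: 1}
  - {name: stroke, type: binary, points_present: 2}
  - {name: tbi, type: binary, points_present: 1}
  - {name: sleep_problems, type: binary, points_present: 1}
  - {name: hearing_loss, type: binary, points_present: 1}
  - {name: alcohol_high, type: binary, points_present: 1}
  - {name: social_isolation, type: binary, points_present: 1}
  - {name: physical_inactivity, type: binary, points_present: 1, points_absent: -1}
  - {name: low_cognitive_activity, type: binary, points_present: 0, points_absent: -2}
  - {name: unhealthy_diet, type: binary, points_present: 0, points_absent: -1}
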