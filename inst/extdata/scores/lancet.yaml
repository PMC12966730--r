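# Lancet Commission based risk score: each of the 14 modifiable risk
# factors of the 2024 Commission coded absent (0) or present (1 x weight),
# weighted by its commission risk ratio and summed. The framework contains
# no age or sex factor, so ANU-ADRI age and sex point tables are borrowed
# for head-to-head comparison. Risk-ratio weights are an editable
# transcription from the commission report.
name: lancet
description: Risk-ratio weighted sum of the 14 Lancet Commission factors.
augment_demographics_from: anu_adri
augment_items: [age, sex]
items:
  - name: low_education
    type: banded
    source: education
    demographic: true
    bands:
      - {upper: 9.99, points: 1.6}
      - {upper: .inf, points: 0}
  - {name: hearing_loss, type: binary, points_present: 1.4}
  - {name: high_cholesterol, type: binary, points_present: 1.3}
  - {name: depression, type: binary, points_present: 1.9}
  - {name: tbi, type: binary, points_present: 1.7}
  - {name: physical_inactivity, type: binary, points_present: 1.4}
  - {name: diabetes, type: binary, points_present: 1.7}
  - {name: smoking, type: binary, points_present: 1.6}
  - {name: hypertension, type: binary, points_present: 1.6}
  - {name: obesity, type: binary, points_present: 1.3}
  - {name: alcohol_high, type: binary, points_present: 1.2}
  - {name: social_isolation, type: binary, points_present: 1.6}
  - {name: air_pollution, type: binary, points_present: 1.1}
  - {name: visual_impairment, type: binary, points_present: 1.5}
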