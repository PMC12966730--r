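# UKBDRS (UK Biobank Dementia Risk Score). Age and education carry linear
# per-unit weights; their theoretical-maximum contributions are by
# convention evaluated at 100 years of age and 20 years of education
# (education is protective, so its anchored contribution is negative).
# Editable transcription of the published logistic weights.
name: ukbdrs
description: Regression-derived dementia risk score with linear age/education.
items:
  - name: age
    type: linear
    source: age_baseline
    slope: 0.12
    anchor: 100
    demographic: true
  - name: education
    type: linear
    source: education
    slope: -0.05
    anchor: 20
    demographic: true
  - name: sex
    type: categorical
    source: sex
    demographic: true
    mapping: {female: 0, male: 0.35}
  - {name: diabetes, type: binary, points_present: 0.58}
  - {name: depression, type: binary, points_present: 0.49}
  - {name: stroke, type: binary, points_present: 0.67}
  - {name: hypertension, type: binary, points_present: 0.28}
  - {name: high_cholesterol, type: binary, points_present: 0.17}
  - {name: deprivation, type: binary, points_present: 0.32}
  - {name: family_history_dementia, type: binary, points_present: 0.42}
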