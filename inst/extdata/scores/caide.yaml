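# CAIDE (Cardiovascular Risk Factors, Aging and Incidence of Dementia,
# Kivipelto et al. 2006). This configuration encodes the original integer
# point model without APOE (age, education, sex, blood pressure, BMI,
# cholesterol, physical activity); it does not attempt to reproduce
# beta-coefficient weighted variants.
name: caide
description: Midlife cardiovascular risk point score, integer point model.
items:
  - name: age
    type: banded
    source: age_baseline
    demographic: true
    bands:
      - {upper: 46.99, points: 0}
      - {upper: 53.0, points: 3}
      - {upper: .inf, points: 4}
  - name: education
    type: banded
    source: education
    demographic: true
    bands:
      - {upper: 6.99, points: 3}
      - {upper: 9.99, points: 2}
      - {upper: .inf, points: 0}
  - name: sex
    type: categorical
    source: sex
    demographic: true
    mapping: {female: 0, male: 1}
  - {name: hypertension, type: binary, points_present: 2}
  - {name: obesity, type: binary, points_present: 2}
  - {name: high_cholesterol, type: binary, points_present: 2}
  - {name: physical_inactivity, type: binary, points_present: 1}
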