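# ANU-ADRI (Australian National University Alzheimer's Disease Risk Index,
# Anstey et al. 2013). Editable transcription; the published index uses
# sex-specific age point tables and several exposure-level gradations that
# are collapsed here into single bands per harmonized cohort variable.
# Audit against the source publication before substantive reuse.
name: anu_adri
description: >
  Point-based multi-domain risk index with strong age weighting and
  protective weights for cognitive, physical and social engagement.
items:
  - name: age
    type: banded
    source: age_baseline
    demographic: true
    bands:
      - {upper: 64.99, points: 0}
      - {upper: 69.99, points: 3}
      - {upper: 74.99, points: 6}
      - {upper: 79.99, points: 10}
      - {upper: 84.99, points: 14}
      - {upper: .inf, points: 18}
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
      - {upper: 8.99, points: 6}
      - {upper: 12.99, points: 3}
      - {upper: .inf, points: 0}
  - {name: obesity, type: binary, points_present: 2}
  - {name: diabetes, type: binary, points_present: 3}
  - {name: depression, type: binary, points_present: 2}
  - {name: high_cholesterol, type: binary, points_present: 3}
  - {name: tbi, type: binary, points_present: 2}
  - {name: smoking, type: binary, points_present: 4}
  # light-to-moderate drinking is protective; heavy drinking carries risk
  - {name: alcohol_high, type: binary, points_present: 2, points_absent: -3}
  - {name: physical_inactivity, type: binary, points_present: 2, points_absent: -2}
  - {name: low_cognitive_activity, type: binary, points_present: 0, points_absent: -6}
  - {name: social_isolation, type: binary, points_present: 2, points_absent: -1}
  - {name: unhealthy_diet, type: binary, points_present: 0, points_absent: -2}
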