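# UKBDRS-APOE: the UKBDRS item set expanded with APOE-e4 carriership.
# See ukbdrs.yaml for conventions; editable transcription.
name: ukbdrs_apoe
description: UKBDRS with APOE-e4 genotype item.
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
  - {name: apoe4, type: binary, points_present: 0.83}
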