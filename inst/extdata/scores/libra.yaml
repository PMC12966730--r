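# LIBRA (LIfestyle for BRAin health index, Deckers et al. 2015).
# Weights are the published relative-risk derived item weights; LIBRA has
# no native demographic items, so age and sex point tables are borrowed
# from the ANU-ADRI configuration for head-to-head comparison (the
# demographics-stripped replication removes them again).
name: libra
description: Modifiable-factor brain-health index, published 2015 weights.
augment_demographics_from: anu_adri
augment_items: [age, sex]
items:
  - {name: diabetes, type: binary, points_present: 1.3}
  - {name: heart_disease, type: binary, points_present: 1.0}
  - {name: hypertension, type: binary, points_present: 1.6}
  - {name: high_cholesterol, type: binary, points_present: 1.4}
  - {name: smoking, type: binary, points_present: 1.5}
  - {name: obesity, type: binary, points_present: 1.6}
  - {name: depression, type: binary, points_present: 2.1}
  - {name: physical_inactivity, type: binary, points_present: 1.1}
  - {name: renal_disease, type: binary, points_present: 1.1}
  # protective weights: healthy (Mediterranean-style) diet, low-to-moderate
  # alcohol use, high cognitive activity
  - {name: unhealthy_diet, type: binary, points_present: 0, points_absent: -1.7}
  - {name: alcohol_high, type: binary, points_present: 0, points_absent: -1.0}
  - {name: low_cognitive_activity, type: binary, points_present: 0, points_absent: -3.2}
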