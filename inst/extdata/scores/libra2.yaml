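# LIBRA2 (updated LIfestyle for BRAin health index). Provisional editable
# transcription: the update widens the factor set (hearing, sleep, social
# contact, head injury, vision, heavy alcohol as risk); verify the item
# weights against the source publication before substantive reuse.
name: libra2
description: Updated modifiable-factor brain-health index (provisional weights).
augment_demographics_from: anu_adri
augment_items: [age, sex]
items:
  - {name: diabetes, type: binary, points_present: 1.4}
  - {name: heart_disease, type: binary, points_present: 1.1}
  - {name: hypertension, type: binary, points_present: 1.4}
  - {name: high_cholesterol, type: binary, points_present: 1.2}
  - {name: smoking, type: binary, points_present: 1.3}
  - {name: obesity, type: binary, points_present: 1.2}
  - {name: depression, type: binary, points_present: 1.9}
  - {name: physical_inactivity, type: binary, points_present: 1.3}
  - {name: renal_disease, type: binary, points_present: 1.0}
  - {name: hearing_loss, type: binary, points_present: 1.4}
  - {name: sleep_problems, type: binary, points_present: 1.3}
  - {name: social_isolation, type: binary, points_present: 1.4}
  - {name: tbi, type: binary, points_present: 1.5}
  - {name: alcohol_high, type: binary, points_present: 1.2}
  - {name: visual_impairment, type: binary, points_present: 1.1}
  - {name: unhealthy_diet, type: binary, points_present: 0, points_absent: -1.5}
  - {name: low_cognitive_activity, type: binary, points_present: 0, points_absent: -2.5}
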