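# Four simulated communities exposed to lead via soil/dust ingestion,
# spanning a wealthiest-to-EJ spectrum. Body weights and intake rates are
# stored both as values and as multiplicative factors on the wealthiest
# community's baseline (BW 80 kg, IR 50 mg/day); the reader checks the two
# for consistency. unit_conversion 1e-3 scales the C x IR product so doses
# come out in mg/kg-day under the reporting convention used here.
unit_conversion: 1.0e-3
base:
  body_weight: 80
  intake_rate: 50
scenarios:
  - name: Wealthiest Community
    concentration: 5
    intake_rate: 50
    intake_rate_factor: 1.0
    exposed_hours_per_day: 3
    body_weight: 80
    body_weight_factor: 1.0
    narrative_tags: [above-poverty, grocery-access]
  - name: Middle Community 1
    concentration: 50
    intake_rate: 60
    intake_rate_factor: 1.2
    exposure_factor: 0.25
    body_weight: 82.4
    body_weight_factor: 1.03
  - name: Middle Community 2
    concentration: 500
    intake_rate: 75
    intake_rate_factor: 1.5
    exposure_factor: 0.5
    body_weight: 83.2
    body_weight_factor: 1.04
  - name: EJ Community
    concentration: 5000
    intake_rate: 85
    intake_rate_factor: 1.7
    exposure_factor: 1
    body_weight: 84
    body_weight_factor: 1.05
    narrative_tags: [proximity-to-NPL, poverty, food-desert, pica]
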