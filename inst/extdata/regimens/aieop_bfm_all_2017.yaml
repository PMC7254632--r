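# AIEOP-BFM ALL 2017: 30 mg/m2 doxorubicin over 1 h.
# Dose modifications stay on the BSA basis: 67% of the BSA-based dose below
# 6 months, 75% from 6 to 12 months.
name: aieop_bfm_all_2017
label: AIEOP-BFM ALL 2017
standard_dose: 30          # mg/m2
infusion_duration: 1       # h
bw_conversion_divisor: 30  # (mg/m2) per (mg/kg)
rules:
  - label: "< 6 months: 67% of BSA-based dose"
    age_max: 0.5
    age_max_inclusive: false
    basis: BSA
    fraction: 0.67
  - label: "6-12 months: 75% of BSA-based dose"
    age_min: 0.5
    age_min_inclusive: true
    age_max: 1
    age_max_inclusive: false
    basis: BSA
    fraction: 0.75
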