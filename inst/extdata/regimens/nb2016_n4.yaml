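# NB Registry 2016 N4: 15 mg/m2 doxorubicin over 0.5 h.
# Dose modification: children < 12 months or < 10 kg receive 100% of the
# body-weight-based dose.
name: nb2016_n4
label: NB Registry 2016 N4
standard_dose: 15          # mg/m2
infusion_duration: 0.5     # h
bw_conversion_divisor: 30  # (mg/m2) per (mg/kg)
rules:
  - label: "< 12 months: 100% of BW-based dose"
    age_max: 1
    age_max_inclusive: false
    basis: BW
    fraction: 1.0
  - label: "< 10 kg: 100% of BW-based dose"
    weight_max: 10
    weight_max_inclusive: false
    basis: BW
    fraction: 1.0
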