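# CWS-SoTiSaR guidance: 20 mg/m2 doxorubicin over 3 h.
# Dose modifications: children < 6 months receive 67% of the body-weight-based
# dose; children >= 6 months but <= 10 kg receive 100% of the body-weight-based
# dose. BSA-based dose converted to per-kg with the conventional divisor 30.
name: cws_sotisar
label: CWS-SoTiSaR
standard_dose: 20          # mg/m2
infusion_duration: 3       # h
bw_conversion_divisor: 30  # (mg/m2) per (mg/kg)
rules:
  - label: "< 6 months: 67% of BW-based dose"
    age_max: 0.5
    age_max_inclusive: false
    basis: BW
    fraction: 0.67
  - label: ">= 6 months but <= 10 kg: 100% of BW-based dose"
    age_min: 0.5
    age_min_inclusive: true
    weight_max: 10
    weight_max_inclusive: true
    basis: BW
    fraction: 1.0
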