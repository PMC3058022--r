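# SOFA (Sequential Organ Failure Assessment) point table.
# Transcribed from the original 1996 consensus description of the score
# (six organ systems, 0-4 points each, daily total 0-24).
# Band convention throughout this directory: lo inclusive, hi exclusive.
system: SOFA
max_total: 24
items:
  respiratory:
    # PaO2/FiO2 ratio in mmHg; strata 3 and 4 require respiratory support
    # (mechanical ventilation); without support points are capped at 2.
    input: pf_ratio
    cap_without_support: 2
    bands:
      - {lo: 400, hi: .inf, points: 0}
      - {lo: 300, hi: 400, points: 1}
      - {lo: 200, hi: 300, points: 2}
      - {lo: 100, hi: 200, points: 3}
      - {lo: -.inf, hi: 100, points: 4}
  coagulation:
    input: platelets   # 10^3/uL, daily minimum
    bands:
      - {lo: 150, hi: .inf, points: 0}
      - {lo: 100, hi: 150, points: 1}
      - {lo: 50, hi: 100, points: 2}
      - {lo: 20, hi: 50, points: 3}
      - {lo: -.inf, hi: 20, points: 4}
  hepatic:
    input: bilirubin   # mg/dL, daily maximum
    bands:
      - {lo: -.inf, hi: 1.2, points: 0}
      - {lo: 1.2, hi: 2.0, points: 1}
      - {lo: 2.0, hi: 6.0, points: 2}
      - {lo: 6.0, hi: 12.0, points: 3}
      - {lo: 12.0, hi: .inf, points: 4}
  cardiovascular:
    # Hierarchy: vasoactive support dominates hypotension.
    # catecholamine_dose_class: 0 none, 1 low-dose (dopamine <= 5 or any
    # dobutamine), 2 mid-dose (dopamine > 5 or epi/norepi <= 0.1), 3
    # high-dose (dopamine > 15 or epi/norepi > 0.1); ug/kg/min.
    input: cardiovascular
    catecholamine_points: {'1': 2, '2': 3, '3': 4}
    hypotension_map_below: 70
    hypotension_points: 1
  cns:
    input: gcs   # daily minimum Glasgow Coma Scale
    bands:
      - {lo: 15, hi: .inf, points: 0}
      - {lo: 13, hi: 15, points: 1}
      - {lo: 10, hi: 13, points: 2}
      - {lo: 6, hi: 10, points: 3}
      - {lo: -.inf, hi: 6, points: 4}
  renal:
    # Worse of creatinine stratum and urine-output stratum.
    input: renal
    creatinine_bands:   # mg/dL, daily maximum
      - {lo: -.inf, hi: 1.2, points: 0}
      - {lo: 1.2, hi: 2.0, points: 1}
      - {lo: 2.0, hi: 3.5, points: 2}
      - {lo: 3.5, hi: 5.0, points: 3}
      - {lo: 5.0, hi: .inf, points: 4}
    urine_bands:        # mL/day total
      - {lo: 500, hi: .inf, points: 0}
      - {lo: 200, hi: 500, points: 3}
      - {lo: -.inf, hi: 200, points: 4}
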