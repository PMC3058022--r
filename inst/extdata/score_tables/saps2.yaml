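# SAPS II point table.
# Transcribed from the original 1993 publication: 17 items (12 physiology
# variables scored on the most abnormal value of the window, age, admission
# type, three chronic diseases), plus the published logit converting the
# total to a hospital-mortality probability. Total 0-163.
# Band convention: lo inclusive, hi exclusive. Bidirectional items are
# scored on both daily extremes; the engine keeps the larger point value.
system: SAPS2
max_total: 163
items:
  heart_rate:    # worst /min
    bidirectional: true
    bands:
      - {lo: -.inf, hi: 40, points: 11}
      - {lo: 40, hi: 70, points: 2}
      - {lo: 70, hi: 120, points: 0}
      - {lo: 120, hi: 160, points: 4}
      - {lo: 160, hi: .inf, points: 7}
  sbp:           # systolic blood pressure, mmHg
    bidirectional: true
    bands:
      - {lo: -.inf, hi: 70, points: 13}
      - {lo: 70, hi: 100, points: 5}
      - {lo: 100, hi: 200, points: 0}
      - {lo: 200, hi: .inf, points: 2}
  temperature:   # highest, degrees C
    bands:
      - {lo: -.inf, hi: 39, points: 0}
      - {lo: 39, hi: .inf, points: 3}
  pf_ratio:
    # PaO2/FiO2 in mmHg; scored only on mechanical ventilation or CPAP.
    requires_ventilation: true
    bands:
      - {lo: -.inf, hi: 100, points: 11}
      - {lo: 100, hi: 200, points: 9}
      - {lo: 200, hi: .inf, points: 6}
  urine_output:  # mL/day total
    bands:
      - {lo: -.inf, hi: 500, points: 11}
      - {lo: 500, hi: 1000, points: 4}
      - {lo: 1000, hi: .inf, points: 0}
  urea:          # serum urea, mmol/L, daily maximum
    bands:
      - {lo: -.inf, hi: 10, points: 0}
      - {lo: 10, hi: 30, points: 6}
      - {lo: 30, hi: .inf, points: 10}
  leukocytes:    # 10^3/uL
    bidirectional: true
    bands:
      - {lo: -.inf, hi: 1, points: 12}
      - {lo: 1, hi: 20, points: 0}
      - {lo: 20, hi: .inf, points: 3}
  potassium:     # mmol/L
    bidirectional: true
    bands:
      - {lo: -.inf, hi: 3, points: 3}
      - {lo: 3, hi: 5, points: 0}
      - {lo: 5, hi: .inf, points: 3}
  sodium:        # mmol/L
    bidirectional: true
    bands:
      - {lo: -.inf, hi: 125, points: 5}
      - {lo: 125, hi: 145, points: 0}
      - {lo: 145, hi: .inf, points: 1}
  bicarbonate:   # mmol/L, daily minimum
    bands:
      - {lo: -.inf, hi: 15, points: 6}
      - {lo: 15, hi: 20, points: 3}
      - {lo: 20, hi: .inf, points: 0}
  bilirubin:     # mg/dL, daily maximum
    bands:
      - {lo: -.inf, hi: 4, points: 0}
      - {lo: 4, hi: 6, points: 4}
      - {lo: 6, hi: .inf, points: 9}
  gcs:           # daily minimum
    bands:
      - {lo: -.inf, hi: 6, points: 26}
      - {lo: 6, hi: 9, points: 13}
      - {lo: 9, hi: 11, points: 7}
      - {lo: 11, hi: 14, points: 5}
      - {lo: 14, hi: 16, points: 0}
age_points:
  - {lo: -.inf, hi: 40, points: 0}
  - {lo: 40, hi: 60, points: 7}
  - {lo: 60, hi: 70, points: 12}
  - {lo: 70, hi: 75, points: 15}
  - {lo: 75, hi: 80, points: 16}
  - {lo: 80, hi: .inf, points: 18}
chronic_disease:
  # Highest applicable condition scores.
  metastatic_cancer: 9
  hematologic_malignancy: 10
  aids: 17
admission_type:
  scheduled_surgical: 0
  medical: 6
  unscheduled_surgical: 8
probability_transform:
  # logit = intercept + beta_score * S + beta_log * ln(S + 1);
  # p(hospital death) = exp(logit) / (1 + exp(logit))
  intercept: -7.7631
  beta_score: 0.0737
  beta_log: 0.9971
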