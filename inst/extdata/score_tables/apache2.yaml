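# APACHE II point table.
# Transcribed from the original 1985 publication: 12-item acute physiology
# score (APS, worst value of the scoring window, 0-4 points per item,
# creatinine doubled in acute renal failure), age points and chronic health
# points. Total 0-71.
# Bidirectional items are scored on both daily extremes; the engine keeps the
# larger point value. Band convention: lo inclusive, hi exclusive.
system: APACHE2
max_total: 71
aps_items:
  temperature:   # degrees C (core)
    bidirectional: true
    bands:
      - {lo: 41, hi: .inf, points: 4}
      - {lo: 39, hi: 41, points: 3}
      - {lo: 38.5, hi: 39, points: 1}
      - {lo: 36, hi: 38.5, points: 0}
      - {lo: 34, hi: 36, points: 1}
      - {lo: 32, hi: 34, points: 2}
      - {lo: 30, hi: 32, points: 3}
      - {lo: -.inf, hi: 30, points: 4}
  map:           # mean arterial pressure, mmHg
    bidirectional: true
    bands:
      - {lo: 160, hi: .inf, points: 4}
      - {lo: 130, hi: 160, points: 3}
      - {lo: 110, hi: 130, points: 2}
      - {lo: 70, hi: 110, points: 0}
      - {lo: 50, hi: 70, points: 2}
      - {lo: -.inf, hi: 50, points: 4}
  heart_rate:    # ventricular rate, /min
    bidirectional: true
    bands:
      - {lo: 180, hi: .inf, points: 4}
      - {lo: 140, hi: 180, points: 3}
      - {lo: 110, hi: 140, points: 2}
      - {lo: 70, hi: 110, points: 0}
      - {lo: 55, hi: 70, points: 2}
      - {lo: 40, hi: 55, points: 3}
      - {lo: -.inf, hi: 40, points: 4}
  respiratory_rate:   # /min, ventilated or not
    bidirectional: true
    bands:
      - {lo: 50, hi: .inf, points: 4}
      - {lo: 35, hi: 50, points: 3}
      - {lo: 25, hi: 35, points: 1}
      - {lo: 12, hi: 25, points: 0}
      - {lo: 10, hi: 12, points: 1}
      - {lo: 6, hi: 10, points: 2}
      - {lo: -.inf, hi: 6, points: 4}
  oxygenation:
    # FiO2 >= 0.5: use alveolar-arterial O2 gradient
    # AaDO2 = FiO2*713 - PaCO2/0.8 - PaO2 (mmHg, sea level);
    # FiO2 < 0.5: use PaO2 directly.
    aado2_bands:
      - {lo: 500, hi: .inf, points: 4}
      - {lo: 350, hi: 500, points: 3}
      - {lo: 200, hi: 350, points: 2}
      - {lo: -.inf, hi: 200, points: 0}
    pao2_bands:
      - {lo: 71, hi: .inf, points: 0}
      - {lo: 61, hi: 71, points: 1}
      - {lo: 55, hi: 61, points: 3}
      - {lo: -.inf, hi: 55, points: 4}
  ph:            # arterial pH; serum bicarbonate bands used when no pH
    bidirectional: true
    bands:
      - {lo: 7.7, hi: .inf, points: 4}
      - {lo: 7.6, hi: 7.7, points: 3}
      - {lo: 7.5, hi: 7.6, points: 1}
      - {lo: 7.33, hi: 7.5, points: 0}
      - {lo: 7.25, hi: 7.33, points: 2}
      - {lo: 7.15, hi: 7.25, points: 3}
      - {lo: -.inf, hi: 7.15, points: 4}
  bicarbonate:   # mmol/L, fallback acid-base item when pH unavailable
    fallback_for: ph
    bidirectional: true
    bands:
      - {lo: 52, hi: .inf, points: 4}
      - {lo: 41, hi: 52, points: 3}
      - {lo: 32, hi: 41, points: 1}
      - {lo: 22, hi: 32, points: 0}
      - {lo: 18, hi: 22, points: 2}
      - {lo: 15, hi: 18, points: 3}
      - {lo: -.inf, hi: 15, points: 4}
  sodium:        # mmol/L
    bidirectional: true
    bands:
      - {lo: 180, hi: .inf, points: 4}
      - {lo: 160, hi: 180, points: 3}
      - {lo: 155, hi: 160, points: 2}
      - {lo: 150, hi: 155, points: 1}
      - {lo: 130, hi: 150, points: 0}
      - {lo: 120, hi: 130, points: 2}
      - {lo: 111, hi: 120, points: 3}
      - {lo: -.inf, hi: 111, points: 4}
  potassium:     # mmol/L
    bidirectional: true
    bands:
      - {lo: 7, hi: .inf, points: 4}
      - {lo: 6, hi: 7, points: 3}
      - {lo: 5.5, hi: 6, points: 1}
      - {lo: 3.5, hi: 5.5, points: 0}
      - {lo: 3, hi: 3.5, points: 1}
      - {lo: 2.5, hi: 3, points: 2}
      - {lo: -.inf, hi: 2.5, points: 4}
  creatinine:    # mg/dL; points doubled in acute renal failure
    bidirectional: true
    double_if_acute_renal_failure: true
    bands:
      - {lo: 3.5, hi: .inf, points: 4}
      - {lo: 2.0, hi: 3.5, points: 3}
      - {lo: 1.5, hi: 2.0, points: 2}
      - {lo: 0.6, hi: 1.5, points: 0}
      - {lo: -.inf, hi: 0.6, points: 2}
  hematocrit:    # %
    bidirectional: true
    bands:
      - {lo: 60, hi: .inf, points: 4}
      - {lo: 50, hi: 60, points: 2}
      - {lo: 46, hi: 50, points: 1}
      - {lo: 30, hi: 46, points: 0}
      - {lo: 20, hi: 30, points: 2}
      - {lo: -.inf, hi: 20, points: 4}
  leukocytes:    # 10^3/uL
    bidirectional: true
    bands:
      - {lo: 40, hi: .inf, points: 4}
      - {lo: 20, hi: 40, points: 2}
      - {lo: 15, hi: 20, points: 1}
      - {lo: 3, hi: 15, points: 0}
      - {lo: 1, hi: 3, points: 2}
      - {lo: -.inf, hi: 1, points: 4}
  gcs:
    # Acute physiology contribution is 15 - GCS.
    rule: fifteen_minus_gcs
age_points:
  - {lo: -.inf, hi: 45, points: 0}
  - {lo: 45, hi: 55, points: 2}
  - {lo: 55, hi: 65, points: 3}
  - {lo: 65, hi: 75, points: 5}
  - {lo: 75, hi: .inf, points: 6}
chronic_health:
  # Applied when a history of severe organ insufficiency or immunocompromise
  # is documented (cirrhosis, NYHA class IV, severe COPD, immunocompromise,
  # AIDS, hematologic malignancy, metastatic cancer).
  qualifying_flags: [cirrhosis, nyha4, copd, immunocompromise, aids,
                     hematologic_malignancy, metastatic_cancer]
  elective_postoperative: 2
  emergency_or_nonoperative: 5
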