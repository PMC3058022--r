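# CASUS (Cardiac Surgery Score) point table.
# SYNTHETIC RECONSTRUCTION: the original 2005 publication was not available
# when this table was transcribed. The descriptor set (ten routinely
# available descriptors: the pressure-adjusted heart rate combining heart
# rate, central venous pressure and mean arterial pressure; PaO2/FiO2;
# lactate; bilirubin; creatinine; platelets; neurologic state; renal
# replacement therapy; intra-aortic balloon pump; ventricular assist
# device) follows the published descriptions of the score; the band
# boundaries and device weights below are this package's reconstruction
# in the published 0-4-per-descriptor style and should be diffed against
# the original source before clinical use.
# Band convention: lo inclusive, hi exclusive.
system: CASUS
max_total: 37
items:
  pf_ratio:      # PaO2/FiO2, mmHg (worst of the day)
    bands:
      - {lo: 250, hi: .inf, points: 0}
      - {lo: 200, hi: 250, points: 1}
      - {lo: 150, hi: 200, points: 2}
      - {lo: 100, hi: 150, points: 3}
      - {lo: -.inf, hi: 100, points: 4}
  par:
    # Pressure-adjusted heart rate = heart rate * CVP / MAP, computed from
    # the day's most abnormal combination (max HR, max CVP, min MAP).
    bands:
      - {lo: -.inf, hi: 10, points: 0}
      - {lo: 10, hi: 15, points: 1}
      - {lo: 15, hi: 20, points: 2}
      - {lo: 20, hi: 30, points: 3}
      - {lo: 30, hi: .inf, points: 4}
  lactate:       # mmol/L, daily maximum
    bands:
      - {lo: -.inf, hi: 2, points: 0}
      - {lo: 2, hi: 4, points: 1}
      - {lo: 4, hi: 8, points: 2}
      - {lo: 8, hi: 12, points: 3}
      - {lo: 12, hi: .inf, points: 4}
  bilirubin:     # mg/dL, daily maximum
    bands:
      - {lo: -.inf, hi: 1.2, points: 0}
      - {lo: 1.2, hi: 3.5, points: 1}
      - {lo: 3.5, hi: 7, points: 2}
      - {lo: 7, hi: 14, points: 3}
      - {lo: 14, hi: .inf, points: 4}
  creatinine:    # mg/dL, daily maximum
    bands:
      - {lo: -.inf, hi: 1.3, points: 0}
      - {lo: 1.3, hi: 2.1, points: 1}
      - {lo: 2.1, hi: 3.5, points: 2}
      - {lo: 3.5, hi: 5, points: 3}
      - {lo: 5, hi: .inf, points: 4}
  platelets:     # 10^3/uL, daily minimum
    bands:
      - {lo: 120, hi: .inf, points: 0}
      - {lo: 80, hi: 120, points: 1}
      - {lo: 50, hi: 80, points: 2}
      - {lo: 20, hi: 50, points: 3}
      - {lo: -.inf, hi: 20, points: 4}
  neurologic_state:
    # Ordinal clinical assessment, scored directly:
    # 0 awake and oriented, 1 confused/agitated, 2 deeply sedated,
    # 3 focal neurologic deficit, 4 unresponsive coma.
    rule: identity
    max_points: 4
  dialysis:      # renal replacement therapy running that day
    flag_points: 3
  iabp:          # intra-aortic balloon pump in place
    flag_points: 2
  vad:           # ventricular assist device in place
    flag_points: 4
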