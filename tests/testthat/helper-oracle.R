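# Hand-scored oracle panels: each fixture was scored manually against the
# packaged point tables (band by band), and the expected total frozen here.
# The per-fixture comments show the manual lookups.

# SOFA: components respiratory/coagulation/hepatic/cardiovascular/cns/renal
sofaOracle <- function() list(
  # all normal -> 0
  list(panel = makePanel(), expected = 0L),
  # PF = 90/0.30 = 300 -> 1 (no ventilation needed below stratum 3)
  list(panel = makePanel(pao2_min = 90, fio2_max = 0.30), expected = 1L),
  # PF = 60/0.6 = 100 -> 3 (ventilated); platelets 45 -> 3
  list(panel = makePanel(pao2_min = 60, fio2_max = 0.60,
                         mech_ventilation = TRUE, platelets_min = 45),
       expected = 6L),
  # PF = 55/0.8 = 68.75 -> stratum 4 but NOT ventilated -> capped at 2
  list(panel = makePanel(pao2_min = 55, fio2_max = 0.80), expected = 2L),
  # bilirubin 2.0 -> 2; MAP 65 without catecholamines -> 1
  list(panel = makePanel(bilirubin_max = 2.0, map_min = 65), expected = 3L),
  # mid-dose catecholamines -> 3; GCS 12 -> 2
  list(panel = makePanel(catecholamine_dose_class = 2L, gcs = 12L),
       expected = 5L),
  # high-dose catecholamines -> 4; creatinine 3.6 -> 3
  list(panel = makePanel(catecholamine_dose_class = 3L,
                         creatinine_max = 3.6), expected = 7L),
  # urine 150 mL/d -> renal 4; GCS 6 -> 3
  list(panel = makePanel(urine_output = 150, gcs = 6L), expected = 7L),
  # platelets 18 -> 4; bilirubin 12.5 -> 4
  list(panel = makePanel(platelets_min = 18, bilirubin_max = 12.5),
       expected = 8L),
  # urine 450 -> renal 3; GCS 14 -> 1
  list(panel = makePanel(urine_output = 450, gcs = 14L), expected = 4L),
  # every organ at its worst stratum -> 24
  list(panel = makePanel(pao2_min = 40, fio2_max = 1.0,
                         mech_ventilation = TRUE, platelets_min = 10,
                         bilirubin_max = 15, catecholamine_dose_class = 3L,
                         gcs = 3L, creatinine_max = 6), expected = 24L))

# APACHE II: fixtures carry their stay (age / admission / chronic flags)
apache2Oracle <- function() list(
  # age 40 (0), elective, all physiology normal, GCS 15 -> 0
  list(panel = makePanel(), stay = makeStay(age = 40), expected = 0L),
  # GCS 10 -> APS 15-10 = 5
  list(panel = makePanel(gcs = 10L), stay = makeStay(age = 40),
       expected = 5L),
  # age 70 -> 5 age points only
  list(panel = makePanel(), stay = makeStay(age = 70), expected = 5L),
  # age 70 (5) + NYHA IV, elective postoperative -> chronic 2
  list(panel = makePanel(), stay = makeStay(age = 70, nyha4 = TRUE),
       expected = 7L),
  # age 70 (5) + COPD, medical admission -> chronic 5
  list(panel = makePanel(),
       stay = makeStay(age = 70, copd = TRUE,
                       admission_category = "medical"), expected = 10L),
  # age 50 (2); temp 39.5 -> 3; HR 140 -> 3
  list(panel = makePanel(temperature_max = 39.5, heart_rate_max = 140),
       stay = makeStay(age = 50), expected = 8L),
  # MAP 48 -> 4; pH 7.20 -> 3
  list(panel = makePanel(map_min = 48, ph_min = 7.20),
       stay = makeStay(age = 40), expected = 7L),
  # creatinine 2.5 -> 3, doubled under renal replacement -> 6
  list(panel = makePanel(creatinine_max = 2.5, dialysis = TRUE),
       stay = makeStay(age = 40), expected = 6L),
  # FiO2 0.6 >= 0.5: AaDO2 = 0.6*713 - 40/0.8 - 70 = 307.8 -> 2
  list(panel = makePanel(fio2_max = 0.60, pao2_min = 70),
       stay = makeStay(age = 40), expected = 2L),
  # FiO2 0.4 < 0.5: PaO2 58 -> 3
  list(panel = makePanel(fio2_max = 0.40, pao2_min = 58),
       stay = makeStay(age = 40), expected = 3L),
  # age 80 (6); Na 156 -> 2; K 2.8 -> 2; WBC 22 -> 2; Hct 28 -> 2
  list(panel = makePanel(sodium_max = 156, potassium_min = 2.8,
                         leukocytes_max = 22, hematocrit_min = 28),
       stay = makeStay(age = 80), expected = 14L),
  # resp rate 36 -> 3; GCS 13 -> 2
  list(panel = makePanel(respiratory_rate_max = 36, gcs = 13L),
       stay = makeStay(age = 40), expected = 5L))

# SAPS II
saps2Oracle <- function() list(
  # age 35 (0), scheduled surgical, all physiology normal -> 0
  list(panel = makePanel(), stay = makeStay(age = 35), expected = 0L),
  # ventilated, PF = 95/0.21 = 452 >= 200 -> 6
  list(panel = makePanel(mech_ventilation = TRUE),
       stay = makeStay(age = 35), expected = 6L),
  # identical but not ventilated -> oxygenation item not applied -> 0
  list(panel = makePanel(mech_ventilation = FALSE),
       stay = makeStay(age = 35), expected = 0L),
  # age 45 -> 7; HR 125 -> 4
  list(panel = makePanel(heart_rate_max = 125), stay = makeStay(age = 45),
       expected = 11L),
  # age 62 -> 12; SBP 95 -> 5
  list(panel = makePanel(sbp_min = 95), stay = makeStay(age = 62),
       expected = 17L),
  # temp 39.2 -> 3; urine 800 mL -> 4
  list(panel = makePanel(temperature_max = 39.2, urine_output = 800),
       stay = makeStay(age = 35), expected = 7L),
  # urea 32 mmol/L -> 10; bicarbonate 14 -> 6
  list(panel = makePanel(urea_max = 32, bicarbonate_min = 14),
       stay = makeStay(age = 35), expected = 16L),
  # bilirubin 4.5 -> 4; GCS 13 -> 5
  list(panel = makePanel(bilirubin_max = 4.5, gcs = 13L),
       stay = makeStay(age = 35), expected = 9L),
  # age 76 -> 16; metastatic cancer -> 9; medical admission -> 6
  list(panel = makePanel(),
       stay = makeStay(age = 76, metastatic_cancer = TRUE,
                       admission_category = "medical"), expected = 31L),
  # age 81 -> 18; unscheduled surgical -> 8; Na 122 -> 5; K 5.4 -> 3
  list(panel = makePanel(sodium_min = 122, potassium_max = 5.4),
       stay = makeStay(age = 81,
                       admission_category = "unscheduled_surgical"),
       expected = 34L),
  # WBC 0.8 -> 12; urine 400 -> 11
  list(panel = makePanel(leukocytes_min = 0.8, urine_output = 400),
       stay = makeStay(age = 35), expected = 23L),
  # GCS 5 -> 26; SBP 65 -> 13
  list(panel = makePanel(gcs = 5L, sbp_min = 65), stay = makeStay(age = 35),
       expected = 39L))

# CASUS
casusOracle <- function() list(
  # all descriptors normal, no devices -> 0
  list(panel = makePanel(), expected = 0L),
  # IABP alone -> 2
  list(panel = makePanel(iabp = TRUE), expected = 2L),
  # VAD (4) + renal replacement (3)
  list(panel = makePanel(vad = TRUE, dialysis = TRUE), expected = 7L),
  # lactate 4.5 -> 2
  list(panel = makePanel(lactate_max = 4.5), expected = 2L),
  # PF = 60/0.40 = 150 -> 2
  list(panel = makePanel(pao2_min = 60, fio2_max = 0.40), expected = 2L),
  # PAR = 110*12/60 = 22 -> 3
  list(panel = makePanel(heart_rate_max = 110, cvp_max = 12, map_min = 60),
       expected = 3L),
  # neurologic state 2 -> 2; platelets 70 -> 2
  list(panel = makePanel(neurologic_state = 2L, platelets_min = 70),
       expected = 4L),
  # creatinine 2.5 -> 2; bilirubin 7.5 -> 3
  list(panel = makePanel(creatinine_max = 2.5, bilirubin_max = 7.5),
       expected = 5L),
  # PF = 45/0.9 = 50 -> 4; lactate 13 -> 4; coma -> 4
  list(panel = makePanel(pao2_min = 45, fio2_max = 0.90, lactate_max = 13,
                         neurologic_state = 4L), expected = 12L),
  # PAR = 130*18/55 = 42.5 -> 4; dialysis -> 3; creatinine 5.5 -> 4
  list(panel = makePanel(heart_rate_max = 130, cvp_max = 18, map_min = 55,
                         dialysis = TRUE, creatinine_max = 5.5),
       expected = 11L),
  # every descriptor at its maximum -> 37 (the table's published range)
  list(panel = makePanel(pao2_min = 40, fio2_max = 1.0, heart_rate_max = 130,
                         cvp_max = 18, map_min = 55, lactate_max = 15,
                         bilirubin_max = 20, creatinine_max = 6,
                         platelets_min = 10, neurologic_state = 4L,
                         dialysis = TRUE, iabp = TRUE, vad = TRUE),
       expected = 37L))

# Run one engine over a fixture list, returning engine vs expected totals.
runOracle <- function(system, fixtures) {
  vapply(fixtures, function(f) {
    panel <- f$panel
    total <- switch(system,
      SOFA = scoreSofa(panel)$total,
      CASUS = scoreCasus(panel)$total,
      APACHE2 = scoreApache2(panel, f$stay)$total,
      SAPS2 = scoreSaps2(panel, f$stay)$total)
    c(engine = total, expected = f$expected)
  }, numeric(2))
}
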