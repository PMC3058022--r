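## Controlled vocabulary for the cohort data model.
##
## Variables fall into five reduction groups, which determine how raw
## repeated measurements are collapsed into the daily worst-value panel:
##   continuous  -> keep (daily min, daily max); engines pick the extreme
##                  that maximises their points ("most abnormal per score")
##   cumulative  -> summed over the day (urine output)
##   gcs         -> daily minimum (worst consciousness)
##   ordinal     -> daily maximum (worst class)
##   flag        -> logical OR over the day

.CONTINUOUS_VARS <- c(
  "map", "sbp", "heart_rate", "cvp", "lactate", "pao2", "fio2", "paco2",
  "respiratory_rate", "ph", "creatinine", "urea", "bilirubin", "platelets",
  "leukocytes", "hematocrit", "sodium", "potassium", "bicarbonate",
  "temperature"
)
.CUMULATIVE_VARS <- "urine_output"
.GCS_VAR <- "gcs"
.ORDINAL_VARS <- c("neurologic_state", "catecholamine_dose_class")
.FLAG_VARS <- c("mech_ventilation", "iabp", "vad", "dialysis")

.ALL_VARS <- c(.CONTINUOUS_VARS, .CUMULATIVE_VARS, .GCS_VAR,
               .ORDINAL_VARS, .FLAG_VARS)

## Normal (zero-point) values used by assume-normal imputation. Each value
## scores 0 points in every engine that consumes the variable.
.NORMAL_VALUES <- c(
  map = 85, sbp = 120, heart_rate = 80, cvp = 6, lactate = 1.0,
  pao2 = 95, fio2 = 0.21, paco2 = 40, respiratory_rate = 14, ph = 7.40,
  creatinine = 0.9, urea = 5.0, bilirubin = 0.6, platelets = 250,
  leukocytes = 8, hematocrit = 40, sodium = 140, potassium = 4.2,
  bicarbonate = 24, temperature = 37.0, urine_output = 2000, gcs = 15,
  neurologic_state = 0, catecholamine_dose_class = 0,
  mech_ventilation = 0, iabp = 0, vad = 0, dialysis = 0
)

.SURGERY_TYPES <- c(
  "cabg", "isolated_valve", "cabg_valve", "aorta", "aorta_valve",
  "aorta_coronary", "transplant", "other"
)

.ADMISSION_CATEGORIES <- c("scheduled_surgical", "unscheduled_surgical",
                           "medical")

.CHRONIC_FLAGS <- c("immunocompromise", "metastatic_cancer",
                    "hematologic_malignancy", "aids", "nyha4", "copd",
                    "cirrhosis")

.OUTCOMES <- c("icu_death", "icu_survival")

.SCORE_SYSTEMS <- c("CASUS", "SOFA", "SAPS2", "APACHE2")

#' Controlled vocabulary of daily observation variables
#'
#' Returns the variable names accepted in the long-format observations
#' table, grouped by how repeated daily measurements are reduced into the
#' worst-value panel.
#'
#' @return A named list of character vectors: `continuous` (reduced to daily
#'   min and max), `cumulative` (summed; urine output), `gcs` (daily
#'   minimum), `ordinal` (daily maximum; neurologic state and catecholamine
#'   dose class) and `flag` (logical OR; ventilation and device support).
#' @examples
#' observationVocabulary()$flag
#' @export
observationVocabulary <- function() {
  list(continuous = .CONTINUOUS_VARS, cumulative = .CUMULATIVE_VARS,
       gcs = .GCS_VAR, ordinal = .ORDINAL_VARS, flag = .FLAG_VARS)
}

## condition helpers ---------------------------------------------------------

.stopClassed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "icubench_error")))
}
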