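# Shared test fixtures, all built in code.

# A worst-value panel row with every variable at its normal (zero-point)
# value; override any column by name (e.g. makePanel(map_min = 55)).
makePanel <- function(..., stay_id = "s1", day = 1L) {
  normals <- c(
    map = 85, sbp = 120, heart_rate = 80, cvp = 6, lactate = 1.0,
    pao2 = 95, fio2 = 0.21, paco2 = 40, respiratory_rate = 14, ph = 7.40,
    creatinine = 0.9, urea = 5.0, bilirubin = 0.6, platelets = 250,
    leukocytes = 8, hematocrit = 40, sodium = 140, potassium = 4.2,
    bicarbonate = 24, temperature = 37.0)
  p <- list(stay_id = stay_id, day = day)
  for (v in names(normals)) {
    p[[paste0(v, "_min")]] <- normals[[v]]
    p[[paste0(v, "_max")]] <- normals[[v]]
  }
  p$urine_output <- 2000
  p$gcs <- 15L
  p$neurologic_state <- 0L
  p$catecholamine_dose_class <- 0L
  p$mech_ventilation <- FALSE
  p$iabp <- FALSE
  p$vad <- FALSE
  p$dialysis <- FALSE
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  as.data.frame(p, stringsAsFactors = FALSE)
}

# A stay record with neutral scoring attributes (age 40, elective surgery,
# no chronic conditions) unless overridden.
makeStay <- function(stay_id = "s1", age = 40, sex = "male",
                     surgery_type = "cabg",
                     admission_category = "scheduled_surgical",
                     outcome = "icu_survival", iculos = 1L, ...) {
  st <- data.frame(stay_id = stay_id, age = age, sex = sex,
                   surgery_type = surgery_type,
                   admission_category = admission_category,
                   outcome = outcome, iculos = iculos,
                   stringsAsFactors = FALSE)
  flags <- c("immunocompromise", "metastatic_cancer",
             "hematologic_malignancy", "aids", "nyha4", "copd", "cirrhosis")
  for (fl in flags) st[[fl]] <- FALSE
  over <- list(...)
  for (nm in names(over)) st[[nm]] <- over[[nm]]
  st
}

# Write a tiny two-stay cohort (stays + long observations) to CSV files;
# returns the two paths. Used by the loader and files-mode tests.
writeTwoStayFixture <- function(dir = tempfile("fixture_")) {
  dir.create(dir, showWarnings = FALSE)
  stays <- rbind(
    makeStay("s1", age = 55, sex = "female", outcome = "icu_death",
             iculos = 2L),
    makeStay("s2", age = 70, admission_category = "unscheduled_surgical",
             iculos = 1L))
  obs <- data.frame(
    stay_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    day = c(1L, 1L, 2L, 2L, 1L, 1L, 1L),
    variable = c("map", "creatinine", "map", "lactate",
                 "map", "gcs", "mech_ventilation"),
    value = c(70, 1.8, 55, 3.2, 90, 14, 1),
    unit = c("mmHg", "mg/dL", "mmHg", "mmol/L", "mmHg", "points", "flag"),
    stringsAsFactors = FALSE)
  sp <- file.path(dir, "stays.csv"); op <- file.path(dir, "observations.csv")
  write.csv(stays, sp, row.names = FALSE)
  write.csv(obs, op, row.names = FALSE)
  c(stays = sp, observations = op)
}

# Small deterministic logistic cohort (continuous predictor).
simLogisticData <- function(n, intercept, slope, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(intercept + slope * x))
  list(x = x, y = y)
}
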