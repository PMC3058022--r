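#' Daily SOFA score
#'
#' Applies the six-organ-system SOFA table (respiratory, coagulation,
#' hepatic, cardiovascular, central nervous, renal; 0-4 points each, total
#' 0-24) to worst-value panels. The respiratory strata 3-4 require
#' mechanical ventilation; without it points are capped at 2. The
#' cardiovascular component scores vasoactive support by dose class and
#' falls back to hypotension (MAP < 70 mmHg) when none is given.
#'
#' @param panels Worst-value panel data.frame from [reduceDailyWorst()]
#'   (one or many stay-days).
#' @param gcsPolicy `"recorded"` scores the recorded (possibly sedated)
#'   Glasgow Coma Scale; `"assume15"` substitutes the assumed pre-sedation
#'   value of 15, removing the CNS contribution.
#' @return data.frame: `stay_id`, `day`, `system`, one column per organ
#'   component, `total`.
#' @examples
#' coh <- generateCohort(generatorConfig(n_stays = 3, seed = 7))
#' head(scoreSofa(coh$panels))
#' @export
scoreSofa <- function(panels, gcsPolicy = c("recorded", "assume15")) {
  gcsPolicy <- match.arg(gcsPolicy)
  tab <- loadScoreTable("SOFA")$items
  pf <- panels$pao2_min / panels$fio2_max
  resp <- .bandPoints(pf, tab$respiratory$bands)
  cap <- tab$respiratory$cap_without_support
  resp <- ifelse(!panels$mech_ventilation & resp > cap, cap, resp)
  coag <- .bandPoints(panels$platelets_min, tab$coagulation$bands)
  hep <- .bandPoints(panels$bilirubin_max, tab$hepatic$bands)
  cpts <- tab$cardiovascular$catecholamine_points
  cls <- as.character(panels$catecholamine_dose_class)
  cardio <- ifelse(cls %in% names(cpts),
                   as.numeric(unlist(cpts)[cls]),
                   ifelse(panels$map_min < tab$cardiovascular$hypotension_map_below,
                          tab$cardiovascular$hypotension_points, 0))
  gcs <- if (gcsPolicy == "assume15") rep(15L, nrow(panels)) else panels$gcs
  cns <- .bandPoints(gcs, tab$cns$bands)
  renal <- pmax(.bandPoints(panels$creatinine_max, tab$renal$creatinine_bands),
                .bandPoints(panels$urine_output, tab$renal$urine_bands))
  out <- data.frame(stay_id = panels$stay_id, day = panels$day,
                    system = "SOFA", respiratory = resp, coagulation = coag,
                    hepatic = hep, cardiovascular = cardio, cns = cns,
                    renal = renal)
  out$total <- as.integer(resp + coag + hep + cardio + cns + renal)
  out
}

#' Daily APACHE II score
#'
#' Applies the APACHE II table daily: the 12-item acute physiology score
#' (each item on the day's most abnormal value, GCS contributing
#' `15 - GCS`, creatinine points doubled under renal replacement), age
#' points, and chronic health points (2 for scheduled surgical admissions
#' with a qualifying severe chronic condition, 5 otherwise). Although the
#' score was defined on the first 24 h, serial daily application scores
#' every ICU day; admission-type and chronic-health contributions are held
#' constant across days.
#'
#' @inheritParams scoreSofa
#' @param stays Stays table supplying `age`, `admission_category` and the
#'   chronic-health flags (matched to `panels` by `stay_id`).
#' @return data.frame: `stay_id`, `day`, `system`, components
#'   `acute_physiology`, `age`, `chronic_health`, and `total`.
#' @export
scoreApache2 <- function(panels, stays, gcsPolicy = c("recorded", "assume15")) {
  gcsPolicy <- match.arg(gcsPolicy)
  tab <- loadScoreTable("APACHE2")
  it <- tab$aps_items
  bp <- function(v) .bandPointsBidir(panels[[paste0(v, "_min")]],
                                     panels[[paste0(v, "_max")]],
                                     it[[v]]$bands)
  aps <- bp("temperature") + bp("map") + bp("heart_rate") +
    bp("respiratory_rate") + bp("sodium") + bp("potassium") +
    bp("hematocrit") + bp("leukocytes")
  # acid-base: arterial pH when available, serum bicarbonate as fallback
  ph_pts <- .bandPointsBidir(panels$ph_min, panels$ph_max, it$ph$bands)
  hco3_pts <- .bandPointsBidir(panels$bicarbonate_min, panels$bicarbonate_max,
                               it$bicarbonate$bands)
  aps <- aps + ifelse(is.na(ph_pts), hco3_pts, ph_pts)
  crea <- .bandPointsBidir(panels$creatinine_min, panels$creatinine_max,
                           it$creatinine$bands)
  aps <- aps + ifelse(panels$dialysis, 2 * crea, crea)
  # oxygenation: A-a gradient on high FiO2, PaO2 otherwise
  aado2 <- panels$fio2_max * 713 - panels$paco2_min / 0.8 - panels$pao2_min
  aps <- aps + ifelse(panels$fio2_max >= 0.5,
                      .bandPoints(aado2, it$oxygenation$aado2_bands),
                      .bandPoints(panels$pao2_min, it$oxygenation$pao2_bands))
  gcs <- if (gcsPolicy == "assume15") rep(15L, nrow(panels)) else panels$gcs
  aps <- aps + (15 - gcs)

  m <- match(panels$stay_id, stays$stay_id)
  agep <- .bandPoints(stays$age[m], tab$age_points)
  qual <- Reduce(`|`, lapply(tab$chronic_health$qualifying_flags,
                             function(f) stays[[f]][m] %in% TRUE))
  chronic <- ifelse(qual,
                    ifelse(stays$admission_category[m] == "scheduled_surgical",
                           tab$chronic_health$elective_postoperative,
                           tab$chronic_health$emergency_or_nonoperative),
                    0)
  out <- data.frame(stay_id = panels$stay_id, day = panels$day,
                    system = "APACHE2", acute_physiology = aps, age = agep,
                    chronic_health = chronic)
  out$total <- as.integer(aps + agep + chronic)
  out
}

#' Daily SAPS II score
#'
#' Applies the 17-item SAPS II table (12 physiology items on the day's most
#' abnormal values -- the oxygenation item only under mechanical
#' ventilation -- plus age, admission type and chronic disease). The
#' published logit converting the total to a hospital mortality probability
#' is available separately as [saps2Probability()] and is deliberately not
#' used by the evaluation harness, which recalibrates all four systems
#' uniformly.
#'
#' @inheritParams scoreApache2
#' @return data.frame: `stay_id`, `day`, `system`, one column per item,
#'   `total`.
#' @export
scoreSaps2 <- function(panels, stays, gcsPolicy = c("recorded", "assume15")) {
  gcsPolicy <- match.arg(gcsPolicy)
  tab <- loadScoreTable("SAPS2")
  it <- tab$items
  hr <- .bandPointsBidir(panels$heart_rate_min, panels$heart_rate_max,
                         it$heart_rate$bands)
  sbp <- .bandPointsBidir(panels$sbp_min, panels$sbp_max, it$sbp$bands)
  temp <- .bandPoints(panels$temperature_max, it$temperature$bands)
  pf <- ifelse(panels$mech_ventilation,
               .bandPoints(panels$pao2_min / panels$fio2_max,
                           it$pf_ratio$bands), 0)
  uo <- .bandPoints(panels$urine_output, it$urine_output$bands)
  urea <- .bandPoints(panels$urea_max, it$urea$bands)
  wbc <- .bandPointsBidir(panels$leukocytes_min, panels$leukocytes_max,
                          it$leukocytes$bands)
  k <- .bandPointsBidir(panels$potassium_min, panels$potassium_max,
                        it$potassium$bands)
  na_ <- .bandPointsBidir(panels$sodium_min, panels$sodium_max,
                          it$sodium$bands)
  hco3 <- .bandPoints(panels$bicarbonate_min, it$bicarbonate$bands)
  bili <- .bandPoints(panels$bilirubin_max, it$bilirubin$bands)
  gcsv <- if (gcsPolicy == "assume15") rep(15L, nrow(panels)) else panels$gcs
  gcs <- .bandPoints(gcsv, it$gcs$bands)

  m <- match(panels$stay_id, stays$stay_id)
  agep <- .bandPoints(stays$age[m], tab$age_points)
  cd <- tab$chronic_disease
  chronic <- pmax(
    ifelse(stays$metastatic_cancer[m] %in% TRUE, cd$metastatic_cancer, 0),
    ifelse(stays$hematologic_malignancy[m] %in% TRUE,
           cd$hematologic_malignancy, 0),
    ifelse(stays$aids[m] %in% TRUE, cd$aids, 0))
  adm <- unlist(tab$admission_type)[
    chartr(".", "_", stays$admission_category[m])]
  adm <- as.numeric(adm)

  out <- data.frame(stay_id = panels$stay_id, day = panels$day,
                    system = "SAPS2", heart_rate = hr, sbp = sbp,
                    temperature = temp, oxygenation = pf, urine_output = uo,
                    urea = urea, leukocytes = wbc, potassium = k,
                    sodium = na_, bicarbonate = hco3, bilirubin = bili,
                    gcs = gcs, age = agep, chronic_disease = chronic,
                    admission_type = adm)
  out$total <- as.integer(hr + sbp + temp + pf + uo + urea + wbc + k + na_ +
                            hco3 + bili + gcs + agep + chronic + adm)
  out
}

#' Published SAPS II mortality probability transform
#'
#' Converts SAPS II totals to the published hospital-mortality probability:
#' `logit = -7.7631 + 0.0737 * S + 0.9971 * ln(S + 1)`. Provided for
#' completeness; the evaluation harness uses uniform logistic
#' recalibration instead (two of the four systems have no native
#' probability, so only recalibrated probabilities are comparable).
#'
#' @param total Numeric vector of SAPS II totals.
#' @return Probabilities in (0, 1).
#' @examples
#' saps2Probability(c(0, 29, 40, 77))
#' @export
saps2Probability <- function(total) {
  tr <- loadScoreTable("SAPS2")$probability_transform
  lg <- tr$intercept + tr$beta_score * total + tr$beta_log * log(total + 1)
  plogis(lg)
}

#' Daily CASUS score
#'
#' Applies the ten-descriptor cardiac surgery score: PaO2/FiO2,
#' pressure-adjusted heart rate (heart rate x CVP / MAP), lactate,
#' bilirubin, creatinine, platelets, neurologic state, and the renal
#' replacement, intra-aortic balloon pump and ventricular assist device
#' flags. The packaged point table is a documented reconstruction (see the
#' YAML header in `inst/extdata/score_tables/casus.yaml`).
#'
#' @inheritParams scoreSofa
#' @return data.frame: `stay_id`, `day`, `system`, one column per
#'   descriptor, `total`.
#' @export
scoreCasus <- function(panels) {
  it <- loadScoreTable("CASUS")$items
  pf <- .bandPoints(panels$pao2_min / panels$fio2_max, it$pf_ratio$bands)
  par_ <- .bandPoints(panels$heart_rate_max * panels$cvp_max /
                        panels$map_min, it$par$bands)
  lac <- .bandPoints(panels$lactate_max, it$lactate$bands)
  bili <- .bandPoints(panels$bilirubin_max, it$bilirubin$bands)
  crea <- .bandPoints(panels$creatinine_max, it$creatinine$bands)
  plt <- .bandPoints(panels$platelets_min, it$platelets$bands)
  neuro <- pmin(panels$neurologic_state, it$neurologic_state$max_points)
  dial <- ifelse(panels$dialysis, it$dialysis$flag_points, 0)
  iabp <- ifelse(panels$iabp, it$iabp$flag_points, 0)
  vad <- ifelse(panels$vad, it$vad$flag_points, 0)
  out <- data.frame(stay_id = panels$stay_id, day = panels$day,
                    system = "CASUS", pf_ratio = pf, par = par_,
                    lactate = lac, bilirubin = bili, creatinine = crea,
                    platelets = plt, neurologic_state = neuro,
                    dialysis = dial, iabp = iabp, vad = vad)
  out$total <- as.integer(pf + par_ + lac + bili + crea + plt + neuro +
                            dial + iabp + vad)
  out
}

#' Score a cohort with one or more systems
#'
#' Runs the selected engines over every stay-day panel of a cohort.
#'
#' @param cohort A [cohortTable()].
#' @param systems Character subset of `c("CASUS", "SOFA", "SAPS2",
#'   "APACHE2")`.
#' @param gcsPolicy Passed to the engines, see [scoreSofa()].
#' @return An object of class `scoreTable`: list with `totals` (data.frame
#'   `stay_id`, `day`, `system`, `total`) and `components` (named list of
#'   the per-system component data.frames).
#' @examples
#' coh <- generateCohort(generatorConfig(n_stays = 10, seed = 1))
#' st <- scoreCohort(coh)
#' head(st$totals)
#' @export
scoreCohort <- function(cohort, systems = .SCORE_SYSTEMS,
                        gcsPolicy = c("recorded", "assume15")) {
  gcsPolicy <- match.arg(gcsPolicy)
  systems <- match.arg(systems, .SCORE_SYSTEMS, several.ok = TRUE)
  comp <- list()
  for (sys in systems) {
    comp[[sys]] <- switch(sys,
      CASUS = scoreCasus(cohort$panels),
      SOFA = scoreSofa(cohort$panels, gcsPolicy),
      SAPS2 = scoreSaps2(cohort$panels, cohort$stays, gcsPolicy),
      APACHE2 = scoreApache2(cohort$panels, cohort$stays, gcsPolicy))
  }
  totals <- do.call(rbind, lapply(comp, function(d)
    d[, c("stay_id", "day", "system", "total")]))
  rownames(totals) <- NULL
  structure(list(totals = totals, components = comp), class = "scoreTable")
}

#' @export
print.scoreTable <- function(x, ...) {
  cat(sprintf("scoreTable: %d stay-day scores, systems: %s\n",
              nrow(x$totals), paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' Mean- and Max-score of one stay
#'
#' The Max-score is the worst (largest) daily total over the whole ICU
#' stay; the Mean-score is the sum of all daily totals divided by the ICU
#' length of stay in days.
#'
#' @param daily_totals Numeric vector of daily score totals, days
#'   `1..iculos` of one stay.
#' @return list with `mean_score`, `max_score`, `iculos`.
#' @examples
#' deriveSummary(c(4, 6, 2))   # mean 4, max 6
#' @export
deriveSummary <- function(daily_totals) {
  if (length(daily_totals) == 0L)
    .stopClassed("icubench_schema_error", "empty daily score list")
  list(mean_score = mean(daily_totals),
       max_score = max(daily_totals),
       iculos = length(daily_totals))
}

#' Mean-/Max-score derivatives for every stay and system
#'
#' @param scores A `scoreTable` from [scoreCohort()], or its `totals`
#'   data.frame.
#' @return data.frame: `stay_id`, `system`, `mean_score`, `max_score`,
#'   `iculos` (number of scored days, which equals the stay's ICU length
#'   of stay).
#' @export
scoreSummaries <- function(scores) {
  totals <- if (inherits(scores, "scoreTable")) scores$totals else scores
  dt <- as.data.table(totals)
  out <- dt[, .(mean_score = mean(total), max_score = max(total),
                iculos = .N), by = .(stay_id, system)]
  as.data.frame(out)
}
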