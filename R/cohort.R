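#' Construct a cohort table
#'
#' Bundles per-stay admission records and per-day worst-value panels into a
#' validated `cohortTable`, the container consumed by the scoring engines
#' and the evaluation harness.
#'
#' @param stays data.frame of stay records: `stay_id`, `age` (years, 18-120),
#'   `sex` (`"female"`/`"male"`), `surgery_type`, `admission_category`
#'   (`"scheduled_surgical"`, `"unscheduled_surgical"`, `"medical"`), one
#'   logical column per chronic-health flag (see
#'   [observationVocabulary()] details), `outcome` (`"icu_death"`/
#'   `"icu_survival"`), `iculos` (days, >= 1) and optional
#'   `euroscore_additive` / `euroscore_logistic` columns (supplied, never
#'   computed here).
#' @param panels data.frame of daily worst-value panels as produced by
#'   [reduceDailyWorst()], one row per stay-day.
#' @return An object of class `cohortTable`: a list with elements `stays`
#'   and `panels`.
#' @details Validation enforces: unique `stay_id`s; every panel's `stay_id`
#'   present in `stays`; each stay contributing panels for exactly days
#'   `1..iculos`; `min <= max` for every continuous variable.
#' @seealso [loadCohort()], [generateCohort()]
#' @examples
#' coh <- generateCohort(generatorConfig(n_stays = 5, seed = 1))
#' coh
#' @export
cohortTable <- function(stays, panels) {
  stays <- .validateStays(as.data.frame(stays))
  panels <- as.data.frame(panels)
  .validatePanels(panels, stays)
  structure(list(stays = stays, panels = panels), class = "cohortTable")
}

#' @export
print.cohortTable <- function(x, ...) {
  dead <- sum(x$stays$outcome == "icu_death")
  cat(sprintf("cohortTable: %d stays, %d stay-day panels\n",
              nrow(x$stays), nrow(x$panels)))
  cat(sprintf("  ICU mortality %.1f%%; ICULOS mean %.1f, median %.0f days\n",
              100 * dead / nrow(x$stays), mean(x$stays$iculos),
              median(x$stays$iculos)))
  invisible(x)
}

.validateStays <- function(stays) {
  required <- c("stay_id", "age", "sex", "surgery_type",
                "admission_category", "outcome", "iculos")
  miss <- setdiff(required, names(stays))
  if (length(miss))
    .stopClassed("icubench_schema_error",
                 "stays table missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(stays$stay_id))
    .stopClassed("icubench_schema_error",
                 "duplicate stay_id after first-admission filtering: %s",
                 paste(unique(stays$stay_id[duplicated(stays$stay_id)]),
                       collapse = ", "))
  bad <- which(!(stays$iculos >= 1 & stays$iculos == round(stays$iculos)))
  if (length(bad))
    .stopClassed("icubench_schema_error",
                 "iculos must be an integer >= 1 (stay %s)",
                 stays$stay_id[bad[1]])
  bad <- which(stays$age < 18 | stays$age > 120)
  if (length(bad))
    .stopClassed("icubench_schema_error",
                 "age outside [18, 120] (stay %s)", stays$stay_id[bad[1]])
  for (col in c("sex", "surgery_type", "admission_category", "outcome")) {
    allowed <- switch(col, sex = c("female", "male"),
                      surgery_type = .SURGERY_TYPES,
                      admission_category = .ADMISSION_CATEGORIES,
                      outcome = .OUTCOMES)
    bad <- which(!stays[[col]] %in% allowed)
    if (length(bad))
      .stopClassed("icubench_schema_error",
                   "invalid %s '%s' (stay %s)", col, stays[[col]][bad[1]],
                   stays$stay_id[bad[1]])
  }
  # absent chronic flags default to FALSE
  for (fl in .CHRONIC_FLAGS) {
    if (!fl %in% names(stays)) stays[[fl]] <- rep(FALSE, nrow(stays))
    stays[[fl]] <- as.logical(stays[[fl]]) %in% TRUE
  }
  stays
}

.validatePanels <- function(panels, stays) {
  if (!all(c("stay_id", "day") %in% names(panels)))
    .stopClassed("icubench_schema_error", "panels need stay_id and day")
  orphan <- setdiff(panels$stay_id, stays$stay_id)
  if (length(orphan))
    .stopClassed("icubench_consistency_error",
                 "panel references unknown stay_id: %s",
                 paste(head(orphan, 5), collapse = ", "))
  cnt <- table(factor(panels$stay_id, levels = stays$stay_id))
  bad <- which(as.integer(cnt) != stays$iculos)
  if (length(bad))
    .stopClassed("icubench_consistency_error",
                 "stay %s has %d panel day(s) but iculos %d",
                 stays$stay_id[bad[1]], as.integer(cnt)[bad[1]],
                 stays$iculos[bad[1]])
  for (v in .CONTINUOUS_VARS) {
    lo <- panels[[paste0(v, "_min")]]; hi <- panels[[paste0(v, "_max")]]
    if (!is.null(lo) && !is.null(hi) && any(lo > hi, na.rm = TRUE))
      .stopClassed("icubench_consistency_error",
                   "panel has %s_min > %s_max", v, v)
  }
  invisible(TRUE)
}

#' Read the unit-conversion configuration
#'
#' @param path Path to a YAML file mapping each variable to its canonical
#'   unit and the accepted input units with linear conversion
#'   (`canonical = value * factor + offset`). `NULL` uses the packaged
#'   table (conventional clinical units: creatinine and bilirubin in mg/dL,
#'   lactate in mmol/L, PaO2 in mmHg, FiO2 as a fraction, urine output in
#'   mL).
#' @return Nested list keyed by variable name.
#' @export
readUnitsConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "units.yaml", package = "icubench")
  yaml::read_yaml(path)
}

.convertUnits <- function(obs, units) {
  unknown <- setdiff(unique(obs$variable), .ALL_VARS)
  if (length(unknown)) {
    row <- which(obs$variable == unknown[1])[1]
    .stopClassed("icubench_schema_error",
                 "unknown variable '%s' (observations row %d)",
                 unknown[1], row)
  }
  out <- obs$value
  for (v in unique(obs$variable)) {
    idx <- which(obs$variable == v)
    spec <- units[[v]]
    for (u in unique(obs$unit[idx])) {
      conv <- spec$accepted[[u]]
      if (is.null(conv)) {
        row <- idx[obs$unit[idx] == u][1]
        .stopClassed("icubench_unit_error",
                     "unit '%s' not convertible for variable '%s' (row %d)",
                     u, v, row)
      }
      j <- idx[obs$unit[idx] == u]
      off <- if (is.null(conv$offset)) 0 else conv$offset
      out[j] <- obs$value[j] * conv$factor + off
    }
    obs$unit[idx] <- spec$canonical
  }
  obs$value <- out
  obs
}

#' Load a cohort from stays and observations CSV files
#'
#' Reads the two long-format CSV files, converts observation values to
#' canonical clinical units, reduces repeated daily measurements to
#' worst-value panels and returns a validated [cohortTable()].
#'
#' @param stays_path CSV with one row per ICU stay (columns as in
#'   [cohortTable()]; an `admission_datetime`/`patient_id` pair is accepted
#'   and used by [filterFirstAdmission()] when present).
#' @param observations_path Long-format CSV with columns `stay_id`, `day`
#'   (1 = operative/admission day), `variable` (controlled vocabulary, see
#'   [observationVocabulary()]), `value`, `unit`.
#' @param unit_config Optional path to a units YAML (default: packaged
#'   table, see [readUnitsConfig()]).
#' @param impute `"normal"` (default) fills variables never observed on a
#'   stay-day with their normal, zero-point value and records each
#'   imputation in the `imputations` attribute of the result; `"strict"`
#'   raises an error instead.
#' @return A [cohortTable()]. Attribute `imputations` is a data.frame
#'   (`stay_id`, `day`, `variable`) listing assumed-normal fills.
#' @export
loadCohort <- function(stays_path, observations_path, unit_config = NULL,
                       impute = c("normal", "strict")) {
  impute <- match.arg(impute)
  for (p in c(stays_path, observations_path))
    if (!file.exists(p))
      .stopClassed("icubench_io_error", "file not found: %s", p)
  stays <- read.csv(stays_path, stringsAsFactors = FALSE)
  stays$stay_id <- as.character(stays$stay_id)
  if (all(c("patient_id", "admission_datetime") %in% names(stays)))
    stays <- filterFirstAdmission(stays)
  obs <- read.csv(observations_path, stringsAsFactors = FALSE)
  need <- c("stay_id", "day", "variable", "value", "unit")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    .stopClassed("icubench_schema_error",
                 "observations missing column(s): %s",
                 paste(miss, collapse = ", "))
  obs$stay_id <- as.character(obs$stay_id)
  if (!is.numeric(obs$value))
    .stopClassed("icubench_schema_error",
                 "non-numeric observation value (row %d)",
                 which(is.na(suppressWarnings(as.numeric(obs$value))))[1])
  obs <- .convertUnits(obs, readUnitsConfig(unit_config))
  stays <- .validateStays(stays)
  panels <- reduceDailyWorst(obs, stays = stays, impute = impute)
  out <- cohortTable(stays, panels)
  attr(out, "imputations") <- attr(panels, "imputations")
  out
}

#' Keep only each patient's first ICU admission
#'
#' Readmissions during the study period are dropped: for every
#' `patient_id`, only the stay with the earliest `admission_datetime` is
#' retained, in the original row order.
#'
#' @param stays data.frame with at least `patient_id` and
#'   `admission_datetime` (ISO-8601 strings or anything with a total
#'   order).
#' @return The filtered stays data.frame.
#' @section Errors: two admissions of the same patient with an identical
#'   timestamp cannot be ordered and raise an ambiguity error.
#' @examples
#' st <- data.frame(stay_id = c("a", "b", "c"),
#'                  patient_id = c("p1", "p1", "p2"),
#'                  admission_datetime = c("2007-01-10T08:00:00",
#'                                         "2007-02-19T10:00:00",
#'                                         "2007-01-11T09:00:00"))
#' filterFirstAdmission(st)$stay_id   # "a", "c"
#' @export
filterFirstAdmission <- function(stays) {
  if (!all(c("patient_id", "admission_datetime") %in% names(stays)))
    .stopClassed("icubench_schema_error",
                 "filterFirstAdmission needs patient_id and admission_datetime")
  dup <- duplicated(stays[c("patient_id", "admission_datetime")])
  if (any(dup))
    .stopClassed("icubench_ambiguity_error",
                 "patient %s has two admissions with identical timestamp %s",
                 stays$patient_id[dup][1], stays$admission_datetime[dup][1])
  keep <- rep(FALSE, nrow(stays))
  for (p in unique(stays$patient_id)) {
    idx <- which(stays$patient_id == p)
    keep[idx[order(stays$admission_datetime[idx])[1]]] <- TRUE
  }
  stays[keep, , drop = FALSE]
}

#' Reduce raw daily observations to worst-value panels
#'
#' Collapses repeated measurements on each stay-day into the panel consumed
#' by the scoring engines: continuous variables keep both the daily minimum
#' and maximum (each engine later selects the extreme that yields the most
#' points, which makes "most abnormal value per day" well defined per
#' score), urine output is summed, the Glasgow Coma Scale takes the daily
#' minimum, ordinal states the daily maximum, and support/device flags are
#' OR-ed over the day.
#'
#' @param observations Long-format data.frame (`stay_id`, `day`, `variable`,
#'   `value`) in canonical units; one or many stay-days.
#' @param stays Optional stays table. When given, the output contains one
#'   panel row for every day `1..iculos` of every stay (missing stay-days
#'   are imputed whole), and observations beyond a stay's `iculos` raise a
#'   consistency error.
#' @param impute `"normal"` or `"strict"`, see [loadCohort()].
#' @return data.frame with one row per stay-day: `stay_id`, `day`,
#'   `<var>_min`/`<var>_max` for each continuous variable, `urine_output`,
#'   `gcs`, `neurologic_state`, `catecholamine_dose_class` and the logical
#'   flags. Attribute `imputations` lists assumed-normal fills.
#' @examples
#' obs <- data.frame(stay_id = "s1", day = 1,
#'                   variable = c("map", "map", "sodium", "sodium"),
#'                   value = c(70, 55, 128, 152))
#' p <- reduceDailyWorst(obs)
#' p[, c("map_min", "map_max", "sodium_min", "sodium_max")]
#' @export
reduceDailyWorst <- function(observations, stays = NULL,
                             impute = c("normal", "strict")) {
  impute <- match.arg(impute)
  if (NROW(observations) == 0L)
    .stopClassed("icubench_schema_error", "empty observation set")
  obs <- as.data.table(observations)[, .(stay_id = as.character(stay_id),
                                         day = as.integer(day),
                                         variable, value)]
  if (!is.numeric(obs$value) || anyNA(obs$value))
    .stopClassed("icubench_schema_error", "non-numeric observation value")
  unknown <- setdiff(unique(obs$variable), .ALL_VARS)
  if (length(unknown))
    .stopClassed("icubench_schema_error", "unknown variable '%s'",
                 unknown[1])
  if (any(obs$day < 1))
    .stopClassed("icubench_schema_error", "observation day < 1")
  gcsbad <- obs[variable == "gcs" & (value < 3 | value > 15)]
  if (nrow(gcsbad))
    .stopClassed("icubench_schema_error",
                 "gcs value %g outside 3..15 (stay %s day %d)",
                 gcsbad$value[1], gcsbad$stay_id[1], gcsbad$day[1])

  if (!is.null(stays)) {
    orphan <- setdiff(unique(obs$stay_id), stays$stay_id)
    if (length(orphan))
      .stopClassed("icubench_consistency_error",
                   "observation references unknown stay_id '%s'", orphan[1])
    los <- setNames(stays$iculos, stays$stay_id)
    over <- obs[day > los[stay_id]]
    if (nrow(over))
      .stopClassed("icubench_consistency_error",
                   "observation on day %d beyond iculos %d (stay %s)",
                   over$day[1], los[over$stay_id[1]], over$stay_id[1])
    grid <- data.table(
      stay_id = rep(stays$stay_id, stays$iculos),
      day = unlist(lapply(stays$iculos, seq_len), use.names = FALSE))
  } else {
    grid <- unique(obs[, .(stay_id, day)])
  }
  setkey(grid, stay_id, day)

  agg <- obs[, .(vmin = min(value), vmax = max(value), vsum = sum(value),
                 n_obs = .N),
             by = .(stay_id, day, variable)]

  panels <- grid
  imput <- list()
  pull <- function(v, stat) {
    x <- agg[variable == v]
    col <- merge(grid, x, by = c("stay_id", "day"), all.x = TRUE)
    setkey(col, stay_id, day)
    val <- switch(stat, min = col$vmin, max = col$vmax, sum = col$vsum)
    nas <- is.na(val)
    if (any(nas)) {
      if (impute == "strict")
        .stopClassed("icubench_missing_error",
                     "variable '%s' missing on stay %s day %d (strict mode)",
                     v, col$stay_id[nas][1], col$day[nas][1])
      imput[[v]] <<- data.frame(stay_id = col$stay_id[nas],
                                day = col$day[nas], variable = v)
      val[nas] <- .NORMAL_VALUES[[v]]
    }
    val
  }
  for (v in .CONTINUOUS_VARS) {
    panels[[paste0(v, "_min")]] <- pull(v, "min")
    panels[[paste0(v, "_max")]] <- pull(v, "max")
  }
  panels[["urine_output"]] <- pull("urine_output", "sum")
  panels[["gcs"]] <- as.integer(round(pull("gcs", "min")))
  for (v in .ORDINAL_VARS) panels[[v]] <- as.integer(round(pull(v, "max")))
  for (v in .FLAG_VARS) panels[[v]] <- pull(v, "max") > 0
  out <- as.data.frame(panels)
  imput <- if (length(imput)) do.call(rbind, unname(imput)) else
    data.frame(stay_id = character(), day = integer(),
               variable = character())
  rownames(imput) <- NULL
  attr(out, "imputations") <- imput
  out
}

#' Write a cohort back to the stays/observations CSV schemas
#'
#' Serializes the stays table and (when present in `attr(cohort,
#' "observations")`) the raw long-format observations, plus the worst-value
#' panels, as plain CSV files. Used by the benchmark driver and by the
#' synthetic generator's file mode.
#'
#' @param cohort A [cohortTable()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stays = file.path(dir, "stays.csv"),
             panels = file.path(dir, "panels.csv"))
  write.csv(cohort$stays, paths["stays"], row.names = FALSE)
  write.csv(cohort$panels, paths["panels"], row.names = FALSE)
  obs <- attr(cohort, "observations")
  if (!is.null(obs)) {
    paths <- c(paths, observations = file.path(dir, "observations.csv"))
    write.csv(obs, paths["observations"], row.names = FALSE)
  }
  invisible(paths)
}
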