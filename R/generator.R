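#' Synthetic-cohort generator configuration
#'
#' Builds a validated configuration for [generateCohort()]. Defaults come
#' from the packaged configuration, which is calibrated to the cohort
#' margins of a large postoperative cardiac-surgery ICU population
#' (mortality 5.2%, ICULOS mean 4.3 / median 2 days with a long tail, age
#' 66.9 +/- 10.7 years, 29.6% female, printed surgery mix); any field can
#' be overridden.
#'
#' @param n_stays Number of ICU stays to draw.
#' @param seed Integer seed; together with the configuration it fully
#'   determines every emitted byte.
#' @param ... Named overrides of top-level configuration fields (e.g.
#'   `death_model = list(intercept = -4, slope = 0)`; partial lists are
#'   merged over the defaults).
#' @param path Optional YAML file to use instead of the packaged defaults.
#' @return Object of class `generatorConfig` (a named list).
#' @details The generating process: each stay draws a latent baseline
#'   severity `s0 ~ Gamma(shape, scale)` and a latent course -- recovering
#'   vs deteriorating, with deterioration probability
#'   `plogis(escalation_model$intercept + escalation_model$slope * s0)` so
#'   that sicker arrivals deteriorate more often. Severity evolves
#'   daily as `s_d = drift + ar * s_(d-1) + N(0, innovation_sd)`, floored
#'   at 0. Each day the stay ends in ICU death with probability
#'   `plogis(death.intercept + death.slope * s_d)`, else is discharged
#'   alive with probability `plogis(discharge.intercept -
#'   discharge.slope * s_d)`, else continues. Physiological variables are
#'   emitted `readings_per_day` times per day through monotone linear
#'   links with Gaussian noise; device/support flags switch on when
#'   severity crosses configured thresholds.
#' @export
generatorConfig <- function(n_stays = NULL, seed = NULL, ..., path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "generator_default.yaml",
                        package = "icubench")
  cfg <- yaml::read_yaml(path)
  if (!is.null(n_stays)) cfg$n_stays <- n_stays
  if (!is.null(seed)) cfg$seed <- seed
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  .validateGeneratorConfig(cfg)
  structure(cfg, class = "generatorConfig")
}

.validateGeneratorConfig <- function(cfg) {
  stopifnot(cfg$n_stays >= 0, cfg$n_stays == round(cfg$n_stays))
  for (mix in c("surgery_mix", "admission_mix")) {
    p <- unlist(cfg[[mix]])
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      .stopClassed("icubench_config_error",
                   "%s probabilities must be >= 0 and sum to 1", mix)
  }
  if (cfg$female_prob < 0 || cfg$female_prob > 1)
    .stopClassed("icubench_config_error", "female_prob outside [0,1]")
  if (cfg$age$sd <= 0)
    .stopClassed("icubench_config_error", "age sd must be > 0")
  sds <- c(cfg$trajectory$innovation_sd,
           vapply(cfg$emission, function(e) e$noise, numeric(1)))
  if (any(sds < 0))
    .stopClassed("icubench_config_error", "noise sds must be >= 0")
  invisible(cfg)
}

#' @export
print.generatorConfig <- function(x, ...) {
  cat(sprintf(
    "generatorConfig: n_stays = %d, seed = %d\n", x$n_stays, x$seed))
  cat(sprintf(
    "  death hazard plogis(%.2f + %.2f s); discharge plogis(%.2f - %.2f s)\n",
    x$death_model$intercept, x$death_model$slope,
    x$discharge_model$intercept, x$discharge_model$slope))
  invisible(x)
}

## truncated-normal draw with a fixed number of RNG consumptions
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate a synthetic postoperative cardiac-surgery ICU cohort
#'
#' Draws `n_stays` independent stays from the process described in
#' [generatorConfig()]: demographics, a latent daily severity trajectory, a
#' coupled death/discharge process, and noisy repeated daily observations
#' of the full variable vocabulary. The same configuration and seed always
#' produce identical output.
#'
#' @param config A [generatorConfig()].
#' @param emit_days Optional emission horizon: raw observations are emitted
#'   only for days `<= emit_days` (the trajectory and outcome still run to
#'   completion). `NULL` (default) emits every day. Panels beyond the
#'   horizon are not produced, so downstream accounting must restrict to
#'   the emitted days; used to keep day-limited experiments cheap.
#' @return A [cohortTable()] whose panels are the worst-value reduction of
#'   the emitted observations. Attributes: `observations` (the raw
#'   long-format table) and `truth` (hidden ground truth, see
#'   [cohortTruth()]). With `emit_days` set, the panel/ICULOS consistency
#'   check is relaxed to the horizon.
#' @examples
#' coh <- generateCohort(generatorConfig(n_stays = 20, seed = 42))
#' coh
#' @export
generateCohort <- function(config, emit_days = NULL) {
  stopifnot(inherits(config, "generatorConfig"))
  if (!is.null(emit_days) && emit_days < 1)
    .stopClassed("icubench_config_error", "emit_days must be >= 1")
  set.seed(config$seed)
  n <- config$n_stays
  if (n == 0L) {
    empty <- cohortTable(
      data.frame(stay_id = character(), age = numeric(), sex = character(),
                 surgery_type = character(), admission_category = character(),
                 outcome = character(), iculos = integer()),
      data.frame(stay_id = character(), day = integer()))
    attr(empty, "truth") <- list()
    return(empty)
  }

  ## --- demographics -------------------------------------------------------
  stay_id <- sprintf("stay%05d", seq_len(n))
  age <- round(.rtruncnorm(n, config$age$mean, config$age$sd,
                           config$age$lo, config$age$hi))
  sex <- ifelse(runif(n) < config$female_prob, "female", "male")
  surgery_type <- sample(names(config$surgery_mix), n, replace = TRUE,
                         prob = unlist(config$surgery_mix))
  admission_category <- sample(names(config$admission_mix), n,
                               replace = TRUE,
                               prob = unlist(config$admission_mix))
  flags <- lapply(config$chronic_flag_probs, function(p) runif(n) < p)

  ## --- latent trajectory and death/discharge process ----------------------
  s0 <- rgamma(n, shape = config$baseline_severity$shape,
               scale = config$baseline_severity$scale)
  em <- config$escalation_model
  decliner <- runif(n) < plogis(em$intercept + em$slope * s0)
  drift <- ifelse(decliner, config$trajectory$escalation_drift,
                  config$trajectory$recovery_drift)
  tr <- config$trajectory
  dm <- config$death_model; cm <- config$discharge_model

  s_cur <- s0
  active <- seq_len(n)
  iculos <- integer(n)
  dead <- logical(n)
  traj_id <- vector("list", tr$max_days)
  traj_s <- vector("list", tr$max_days)
  traj_event <- vector("list", tr$max_days)  # death indicator per stay-day
  for (d in seq_len(tr$max_days)) {
    m <- length(active)
    if (m == 0L) break
    traj_id[[d]] <- active
    traj_s[[d]] <- s_cur
    p_die <- plogis(dm$intercept + dm$slope * s_cur)
    u1 <- runif(m)
    dies <- u1 < p_die
    p_dc <- plogis(cm$intercept - cm$slope * s_cur)
    u2 <- runif(m)
    leaves <- !dies & (u2 < p_dc | d == tr$max_days)
    traj_event[[d]] <- dies
    done <- dies | leaves
    iculos[active[done]] <- d
    dead[active[dies]] <- TRUE
    keep <- !done
    active <- active[keep]
    s_next <- drift[active] + tr$ar * s_cur[keep] +
      rnorm(length(active), 0, tr$innovation_sd)
    s_cur <- pmax(0, s_next)
  }

  truth_days <- data.frame(
    stay_id = stay_id[unlist(traj_id)],
    day = rep(seq_along(traj_id), vapply(traj_id, length, integer(1))),
    s = unlist(traj_s),
    died_on_day = unlist(traj_event))
  truth_days <- truth_days[order(truth_days$stay_id, truth_days$day), ,
                           drop = FALSE]
  rownames(truth_days) <- NULL

  ## --- toy preoperative risk fields (noisy monotone in s0) ----------------
  es <- config$euroscore
  euro_add <- pmin(pmax(round(es$additive$loc + es$additive$slope * s0 +
                                rnorm(n, 0, es$additive$noise)),
                        es$additive$lo), es$additive$hi)
  euro_log <- plogis(es$logistic$intercept + es$logistic$slope * s0 +
                       rnorm(n, 0, es$logistic$noise))

  stays <- data.frame(
    stay_id = stay_id, age = age, sex = sex, surgery_type = surgery_type,
    admission_category = admission_category,
    outcome = ifelse(dead, "icu_death", "icu_survival"),
    iculos = iculos,
    euroscore_additive = euro_add, euroscore_logistic = euro_log,
    stringsAsFactors = FALSE)
  for (fl in names(flags)) stays[[fl]] <- flags[[fl]]

  ## --- daily observation emission -----------------------------------------
  sd_tab <- data.table(stay_id = truth_days$stay_id, day = truth_days$day,
                       s = truth_days$s)
  if (!is.null(emit_days)) sd_tab <- sd_tab[day <= emit_days]
  k <- config$readings_per_day
  nrow_sd <- nrow(sd_tab)
  obs_list <- vector("list", length(config$emission) + 6L)
  i <- 0L
  emit <- function(variable, values, unit) {
    i <<- i + 1L
    obs_list[[i]] <<- data.table(
      stay_id = rep(sd_tab$stay_id, each = length(values) / nrow_sd),
      day = rep(sd_tab$day, each = length(values) / nrow_sd),
      variable = variable, value = values, unit = unit)
  }
  units_cfg <- readUnitsConfig()
  for (v in names(config$emission)) {
    e <- config$emission[[v]]
    base <- e$loc + e$slope * sd_tab$s
    vals <- rep(base, each = k) + rnorm(nrow_sd * k, 0, e$noise)
    vals <- pmin(pmax(vals, e$lo), e$hi)
    emit(v, round(vals, 3), units_cfg[[v]]$canonical)
  }
  uo <- config$urine_output
  uo_tot <- pmin(pmax(uo$loc + uo$slope * sd_tab$s, uo$lo), uo$hi)
  uo_vals <- pmax(rep(uo_tot / k, each = k) +
                    rnorm(nrow_sd * k, 0, uo$noise), 0)
  emit("urine_output", round(uo_vals, 1), "mL")
  g <- config$gcs
  gcs_vals <- round(rep(15 - g$slope * sd_tab$s, each = k) +
                      rnorm(nrow_sd * k, 0, g$noise))
  emit("gcs", pmin(pmax(gcs_vals, 3), 15), "points")
  neuro <- findInterval(sd_tab$s, config$neurologic_state_breaks)
  emit_daily <- function(variable, values, unit) {
    i <<- i + 1L
    obs_list[[i]] <<- data.table(stay_id = sd_tab$stay_id, day = sd_tab$day,
                                 variable = variable, value = values,
                                 unit = unit)
  }
  emit_daily("neurologic_state", neuro, "ordinal")
  emit_daily("catecholamine_dose_class",
             findInterval(sd_tab$s, config$catecholamine_breaks), "class")
  th <- config$flag_thresholds
  emit_daily("mech_ventilation",
             as.numeric(sd_tab$day == 1 | sd_tab$s >= th$mech_ventilation),
             "flag")
  for (fl in c("iabp", "vad", "dialysis"))
    emit_daily(fl, as.numeric(sd_tab$s >= th[[fl]]), "flag")
  observations <- as.data.frame(rbindlist(obs_list[seq_len(i)]))
  observations <- observations[order(observations$stay_id, observations$day,
                                     observations$variable), , drop = FALSE]
  rownames(observations) <- NULL

  panel_stays <- stays
  if (!is.null(emit_days)) {
    panel_stays$iculos <- pmin(stays$iculos, emit_days)
    panel_stays <- panel_stays[panel_stays$iculos >= 1, , drop = FALSE]
  }
  panels <- reduceDailyWorst(observations, stays = panel_stays)
  out <- cohortTable(panel_stays, panels)
  out$stays <- stays   # keep true iculos even under an emission horizon
  attr(out, "observations") <- observations
  attr(out, "truth") <- list(
    stays = data.frame(stay_id = stay_id, s0 = s0, decliner = decliner),
    days = truth_days,
    death_model = dm, discharge_model = cm, config_seed = config$seed)
  out
}

#' Hidden ground truth of a synthetic cohort
#'
#' Returns the latent truth table of a generated cohort: per-stay baseline
#' severity and course label, the per-day latent severities with the
#' day-of-death indicator, and the true hazard parameters. It is carried as
#' an attribute and never written into the public cohort CSV files, so
#' parameter-recovery tests read it through this separate accessor.
#'
#' @param cohort A cohort produced by [generateCohort()].
#' @return list with `stays`, `days`, `death_model`, `discharge_model`.
#' @export
cohortTruth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr))
    .stopClassed("icubench_schema_error",
                 "cohort carries no ground truth (not generated?)")
  tr
}

#' Draw a single synthetic stay
#'
#' Convenience wrapper around [generateCohort()] for one stay; useful for
#' inspecting the generating process.
#'
#' @param config A [generatorConfig()].
#' @param seed Optional seed override.
#' @return list with `stay` (one-row stays table), `observations` (raw
#'   long-format readings) and `trajectory` (per-day latent severity with
#'   the event indicator).
#' @export
sampleStay <- function(config, seed = NULL) {
  cfg <- config
  cfg$n_stays <- 1L
  if (!is.null(seed)) cfg$seed <- seed
  coh <- generateCohort(cfg)
  list(stay = coh$stays, observations = attr(coh, "observations"),
       trajectory = cohortTruth(coh)$days)
}

#' Cohort calibration report
#'
#' Summarizes the quantities the default generator is calibrated to:
#' ICU mortality, ICULOS distribution, age, sex, surgery mix and per-day
#' at-risk counts, for side-by-side comparison with the printed margins of
#' the emulated study population.
#'
#' @param cohort A [cohortTable()].
#' @param days Days for the at-risk counts (default `1:6`).
#' @return list of class `calibrationReport`.
#' @export
calibrationReport <- function(cohort, days = 1:6) {
  st <- cohort$stays
  if (nrow(st) == 0L)
    .stopClassed("icubench_schema_error", "empty cohort")
  mix <- table(factor(st$surgery_type, levels = .SURGERY_TYPES))
  rep_ <- list(
    n_stays = nrow(st),
    mortality_pct = 100 * mean(st$outcome == "icu_death"),
    iculos_mean = mean(st$iculos), iculos_sd = sd(st$iculos),
    iculos_median = median(st$iculos),
    iculos_p75 = unname(quantile(st$iculos, 0.75, type = 2)),
    iculos_range = range(st$iculos),
    age_mean = mean(st$age), age_sd = sd(st$age), age_range = range(st$age),
    female_pct = 100 * mean(st$sex == "female"),
    surgery_mix_pct = 100 * as.vector(mix) / nrow(st),
    surgery_types = names(mix),
    at_risk = vapply(days, function(d) sum(st$iculos >= d), integer(1)),
    at_risk_days = days)
  class(rep_) <- "calibrationReport"
  rep_
}

#' @export
print.calibrationReport <- function(x, ...) {
  cat(sprintf("Cohort calibration report (n = %d)\n", x$n_stays))
  cat(sprintf("  ICU mortality: %.1f%%\n", x$mortality_pct))
  cat(sprintf("  ICULOS: mean %.1f +/- %.1f d, median %.0f, p75 %.0f, range %d-%d\n",
              x$iculos_mean, x$iculos_sd, x$iculos_median, x$iculos_p75,
              x$iculos_range[1], x$iculos_range[2]))
  cat(sprintf("  Age: %.1f +/- %.1f y (range %d-%d); female %.1f%%\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
              x$female_pct))
  cat("  Surgery mix (%): ",
      paste(sprintf("%s %.1f", x$surgery_types, x$surgery_mix_pct),
            collapse = ", "), "\n", sep = "")
  cat("  At-risk by day: ",
      paste(sprintf("d%d=%d", x$at_risk_days, x$at_risk), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
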