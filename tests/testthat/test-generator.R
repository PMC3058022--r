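test_that("same configuration and seed reproduce the cohort byte for byte", {
  cfg <- generatorConfig(n_stays = 60, seed = 123)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$stays, b$stays)
  expect_identical(a$panels, b$panels)
  expect_identical(attr(a, "observations"), attr(b, "observations"))
  da <- tempfile(); db <- tempfile()
  writeCohortCSV(a, da); writeCohortCSV(b, db)
  for (f in c("stays.csv", "panels.csv", "observations.csv"))
    expect_identical(readBin(file.path(da, f), "raw", 1e7),
                     readBin(file.path(db, f), "raw", 1e7))
  # a different seed changes the draw
  expect_false(identical(
    generateCohort(generatorConfig(n_stays = 60, seed = 124))$stays, a$stays))
})

test_that("n_stays = 0 yields an empty cohort", {
  coh <- generateCohort(generatorConfig(n_stays = 0, seed = 1))
  expect_equal(nrow(coh$stays), 0L)
  expect_equal(nrow(coh$panels), 0L)
})

test_that("every stay ends in exactly one state and at-risk counts
           decrease with day", {
  coh <- generateCohort(generatorConfig(n_stays = 400, seed = 5),
                        emit_days = 1)
  expect_true(all(coh$stays$outcome %in% c("icu_death", "icu_survival")))
  at_risk <- vapply(1:10, function(d) sum(coh$stays$iculos >= d),
                    integer(1))
  expect_true(all(diff(at_risk) <= 0))
  expect_equal(at_risk[1], 400L)
})

test_that("an overwhelming death hazard kills every stay on day 1", {
  cfg <- generatorConfig(n_stays = 50, seed = 2,
                         death_model = list(intercept = 50, slope = 1))
  coh <- generateCohort(cfg)
  expect_true(all(coh$stays$outcome == "icu_death"))
  expect_true(all(coh$stays$iculos == 1L))
})

test_that("zero noise and zero drift emit identical values every day", {
  cfg0 <- generatorConfig()
  cfg <- generatorConfig(
    n_stays = 25, seed = 9,
    trajectory = list(ar = 1, recovery_drift = 0, escalation_drift = 0,
                      innovation_sd = 0),
    emission = lapply(cfg0$emission, function(e) list(noise = 0)),
    urine_output = list(noise = 0), gcs = list(noise = 0))
  coh <- generateCohort(cfg)
  obs <- attr(coh, "observations")
  spread <- tapply(obs$value, paste(obs$stay_id, obs$variable),
                   function(v) diff(range(v)))
  expect_true(all(spread[!grepl("mech_ventilation", names(spread))] == 0))
})

test_that("with zero emission noise daily SOFA tracks latent severity", {
  cfg0 <- generatorConfig()
  cfg <- generatorConfig(
    n_stays = 80, seed = 13,
    emission = lapply(cfg0$emission, function(e) list(noise = 0)),
    urine_output = list(noise = 0), gcs = list(noise = 0))
  coh <- generateCohort(cfg)
  sofa <- scoreSofa(coh$panels)
  truth <- cohortTruth(coh)$days
  m <- merge(sofa, truth, by = c("stay_id", "day"))
  # restrict to days beyond the operative day: the day-1 ventilation rule
  # adds support points that are not a function of severity alone
  m <- m[m$day > 1, ]
  for (id in unique(m$stay_id)) {
    mi <- m[m$stay_id == id, ]
    if (nrow(mi) < 2) next
    expect_true(all(diff(mi$total[order(mi$s)]) >= 0), label = id)
  }
})

test_that("the death process follows the configured severity hazard", {
  # pooled stay-days are Bernoulli(plogis(a + b s)): logistic regression on
  # the hidden truth recovers the planted slope
  cover <- 0L
  for (seed in 1:10) {
    coh <- generateCohort(generatorConfig(n_stays = 1200, seed = seed),
                          emit_days = 1)
    td <- cohortTruth(coh)$days
    fit <- glm(died_on_day ~ s, data = td, family = binomial())
    ci <- coef(fit)[2] + c(-1.96, 1.96) * sqrt(diag(vcov(fit)))[2]
    truth <- cohortTruth(coh)$death_model$slope
    if (ci[1] <= truth && truth <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover, 8L)
})

test_that("a severity-independent death hazard removes discrimination", {
  # the exit process must be severity-independent on both sides: with a
  # severity-dependent discharge, sicker stays would accumulate more
  # at-risk days and outcome would correlate with severity through
  # exposure time alone
  aucs <- vapply(1:8, function(seed) {
    coh <- generateCohort(generatorConfig(
      n_stays = 800, seed = seed,
      death_model = list(intercept = -3.2, slope = 0),
      discharge_model = list(intercept = 1.0, slope = 0)), emit_days = 1)
    sofa <- scoreSofa(coh$panels)
    y <- as.integer(coh$stays$outcome == "icu_death")
    rocAuc(sofa$total[match(coh$stays$stay_id, sofa$stay_id)], y)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the latent severity discriminates at least as well as any
           noisy score derived from it", {
  for (seed in c(3, 7)) {
    coh <- generateCohort(generatorConfig(n_stays = 900, seed = seed),
                          emit_days = 1)
    y <- as.integer(coh$stays$outcome == "icu_death")
    truth <- cohortTruth(coh)
    s1 <- truth$days$s[truth$days$day == 1]
    auc_latent <- rocAuc(s1[match(coh$stays$stay_id,
                                  truth$days$stay_id[truth$days$day == 1])],
                         y)$auc
    st <- scoreCohort(coh)
    for (sys in c("CASUS", "SOFA", "SAPS2", "APACHE2")) {
      tot <- st$totals[st$totals$system == sys, ]
      auc_score <- rocAuc(tot$total[match(coh$stays$stay_id, tot$stay_id)],
                          y)$auc
      expect_lte(auc_score, auc_latent + 0.02, label = sys)
    }
  }
})

test_that("calibration report is hand-checkable on a fixed mini-cohort", {
  stays <- rbind(
    makeStay("s1", age = 60, sex = "female", outcome = "icu_death",
             iculos = 3L),
    makeStay("s2", age = 70, iculos = 1L))
  panels <- rbind(makePanel(stay_id = "s1", day = 1L),
                  makePanel(stay_id = "s1", day = 2L),
                  makePanel(stay_id = "s1", day = 3L),
                  makePanel(stay_id = "s2", day = 1L))
  rep_ <- calibrationReport(cohortTable(stays, panels), days = 1:3)
  expect_equal(rep_$mortality_pct, 50)
  expect_equal(rep_$iculos_mean, 2)
  expect_equal(rep_$iculos_median, 2)
  expect_equal(rep_$age_mean, 65)
  expect_equal(rep_$female_pct, 50)
  expect_equal(rep_$at_risk, c(2L, 1L, 1L))
  expect_error(calibrationReport(cohortTable(stays[0, ], panels[0, ])),
               class = "icubench_schema_error")
})

test_that("sampleStay exposes one stay with its latent trajectory", {
  st <- sampleStay(generatorConfig(n_stays = 500, seed = 77))
  expect_equal(nrow(st$stay), 1L)
  expect_equal(nrow(st$trajectory), st$stay$iculos)
  expect_true(all(st$trajectory$s >= 0))
  expect_equal(unique(st$observations$stay_id), st$stay$stay_id)
})
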