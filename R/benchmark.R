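#' Benchmark run configuration
#'
#' Assembles and validates every knob of a full benchmark run:
#' generation (or file input), scoring, evaluation and report output.
#'
#' @param mode `"synthetic"` (default; draws a cohort from
#'   `generator`) or `"files"` (reads `stays_path`/`observations_path`).
#' @param generator A [generatorConfig()] (synthetic mode).
#' @param stays_path,observations_path Input CSVs (files mode).
#' @param systems Scoring systems to run (default all four).
#' @param days Day horizon for the per-day evaluation (default `1:6`).
#' @param min_n Minimum at-risk set size per day (default 100).
#' @param hl_groups Hosmer-Lemeshow groups (default 10).
#' @param occ_cutoff OCC probability cutoff (default 0.5).
#' @param ci_method AUC CI method (`"delong"`/`"hanley"`).
#' @param gcsPolicy GCS handling, see [scoreSofa()].
#' @param out_dir Output directory for report files.
#' @param seed Seed for synthetic mode (overrides the generator config's).
#' @return list of class `runConfig`.
#' @export
runConfig <- function(mode = c("synthetic", "files"), generator = NULL,
                      stays_path = NULL, observations_path = NULL,
                      systems = .SCORE_SYSTEMS, days = 1:6, min_n = 100,
                      hl_groups = 10, occ_cutoff = 0.5,
                      ci_method = c("delong", "hanley"),
                      gcsPolicy = c("recorded", "assume15"),
                      out_dir = tempfile("icubench_run_"), seed = NULL) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  gcsPolicy <- match.arg(gcsPolicy)
  systems <- match.arg(systems, .SCORE_SYSTEMS, several.ok = TRUE)
  if (length(days) < 1 || any(days < 1))
    .stopClassed("icubench_config_error", "field 'days': horizon must be >= 1")
  if (mode == "files") {
    if (is.null(stays_path) || is.null(observations_path))
      .stopClassed("icubench_config_error",
                   "field 'stays_path'/'observations_path': required in files mode")
  } else if (is.null(generator)) {
    generator <- generatorConfig()
  }
  if (!is.null(seed) && mode == "synthetic") generator$seed <- seed
  structure(list(mode = mode, generator = generator,
                 stays_path = stays_path,
                 observations_path = observations_path, systems = systems,
                 days = days, min_n = min_n, hl_groups = hl_groups,
                 occ_cutoff = occ_cutoff, ci_method = ci_method,
                 gcsPolicy = gcsPolicy, out_dir = out_dir),
            class = "runConfig")
}

#' Run the full scoring-and-validation benchmark
#'
#' One reproducible pass: obtain a cohort (synthetic or from files), score
#' it daily with the requested systems, derive Mean-/Max-scores, evaluate
#' per day and per derivative, and write all report files to
#' `config$out_dir`:
#' \describe{
#'   \item{`scores.csv`}{daily totals per stay/system}
#'   \item{`summaries.csv`}{Mean-/Max-score per stay/system}
#'   \item{`evaluation_daily.csv`}{per-day evaluation rows}
#'   \item{`evaluation_derivatives.csv`}{Mean-/Max-score evaluation rows}
#'   \item{`calibration_report.txt`}{cohort descriptives}
#'   \item{`report.md`}{human-readable rendering of both tables}
#'   \item{`manifest.json`}{configuration digest, seed, package version}
#' }
#' The same configuration and seed yield byte-identical report files.
#'
#' @param config A [runConfig()].
#' @param quiet Suppress stage logging (default FALSE).
#' @return Invisibly, a list with the cohort, score table, summaries, both
#'   evaluation tables and the paths written.
#' @export
runBenchmark <- function(config = runConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (config$mode == "synthetic") {
    say("generating synthetic cohort: n_stays = %d, seed = %d",
        config$generator$n_stays, config$generator$seed)
    cohort <- generateCohort(config$generator)
  } else {
    say("loading cohort from %s", config$stays_path)
    cohort <- loadCohort(config$stays_path, config$observations_path)
  }
  nimp <- nrow(attr(cohort, "imputations") %||%
                 data.frame())
  say("cohort: %d stays, %d panels, %d imputations",
      nrow(cohort$stays), nrow(cohort$panels), nimp)

  scores <- scoreCohort(cohort, systems = config$systems,
                        gcsPolicy = config$gcsPolicy)
  summaries <- scoreSummaries(scores)
  say("scored %d stay-days with %d system(s)",
      nrow(cohort$panels), length(config$systems))

  daily <- evaluatePerDay(cohort, scores, systems = config$systems,
                          days = config$days, min_n = config$min_n,
                          hl_groups = config$hl_groups,
                          occ_cutoff = config$occ_cutoff,
                          ci_method = config$ci_method)
  deriv <- evaluateDerivatives(cohort, summaries, systems = config$systems,
                               min_n = config$min_n,
                               hl_groups = config$hl_groups,
                               occ_cutoff = config$occ_cutoff,
                               ci_method = config$ci_method)
  say("evaluated %d daily and %d derivative rows", nrow(daily), nrow(deriv))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    scores = file.path(config$out_dir, "scores.csv"),
    summaries = file.path(config$out_dir, "summaries.csv"),
    daily = file.path(config$out_dir, "evaluation_daily.csv"),
    derivatives = file.path(config$out_dir, "evaluation_derivatives.csv"),
    calibration = file.path(config$out_dir, "calibration_report.txt"),
    report = file.path(config$out_dir, "report.md"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write.csv(scores$totals, paths["scores"], row.names = FALSE)
  write.csv(summaries, paths["summaries"], row.names = FALSE)
  write.csv(as.data.frame(daily), paths["daily"], row.names = FALSE)
  write.csv(as.data.frame(deriv), paths["derivatives"], row.names = FALSE)
  writeLines(utils::capture.output(print(calibrationReport(cohort))),
             paths["calibration"])
  writeLines(c(renderTables(daily, title = "Per-day evaluation"), "",
               renderTables(deriv, title = "Derivative evaluation")),
             paths["report"])
  manifest <- list(
    package = "icubench",
    version = as.character(packageVersion("icubench")),
    mode = config$mode,
    seed = if (config$mode == "synthetic") config$generator$seed else NA,
    systems = config$systems, days = config$days, min_n = config$min_n,
    hl_groups = config$hl_groups, occ_cutoff = config$occ_cutoff,
    ci_method = config$ci_method, gcsPolicy = config$gcsPolicy,
    n_stays = nrow(cohort$stays),
    config_digest = .configDigest(config))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(cohort = cohort, scores = scores, summaries = summaries,
                 daily = daily, derivatives = deriv, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stable digest of the run configuration (no external digest dependency:
## deterministic serialization folded through a 31-bit polynomial hash)
.configDigest <- function(config) {
  raw <- serialize(unclass(config), connection = NULL, version = 3)
  h <- 17
  for (b in as.integer(raw[seq(1, length(raw), by = 7)]))
    h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render evaluation rows as a plain-text table
#'
#' Markdown-style rendering of an evaluation table in the layout of the
#' classic score-validation reports: one line per row with n, odds ratio
#' (95% CI), OCC, Hosmer-Lemeshow chi-squared and p (rows with p < 0.05
#' flagged with `*`, mirroring the convention of printing significant
#' miscalibration in bold), and AUC (95% CI). Unevaluable cells are left
#' blank, never printed as zeros.
#'
#' @param rows An `evaluationTable` from [evaluatePerDay()] or
#'   [evaluateDerivatives()].
#' @param title Optional heading.
#' @return Character vector of lines.
#' @export
renderTables <- function(rows, title = NULL) {
  if (NROW(rows) < 1)
    .stopClassed("icubench_schema_error", "no evaluation rows to render")
  fmt <- function(x, digits = 2)
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  ci <- function(lo, hi, digits = 2)
    ifelse(is.na(lo), "", sprintf("%s-%s", fmt(lo, digits), fmt(hi, digits)))
  flag <- ifelse(!is.na(rows$hl_p) & rows$hl_p < 0.05, "*", " ")
  header <- sprintf("| %-16s | %-8s | %5s | %5s | %11s | %6s | %6s | %7s | %5s | %11s |",
                    "Label", "System", "n", "OR", "OR 95%-CI", "OCC%",
                    "HL chi2", "HL p", "AUC", "AUC 95%-CI")
  sep <- gsub("[^|]", "-", header)
  body <- sprintf(
    "| %-16s | %-8s | %5d | %5s | %11s | %6s | %6s | %6s%s | %5s | %11s |",
    rows$label, rows$system, rows$n, fmt(rows$odds_ratio),
    ci(rows$or_ci_low, rows$or_ci_high), fmt(rows$occ_pct, 1),
    fmt(rows$hl_chi2), fmt(rows$hl_p, 3), flag, fmt(rows$auc),
    ci(rows$auc_ci_low, rows$auc_ci_high))
  c(if (!is.null(title)) c(paste("##", title), ""), header, sep, body)
}
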