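## The day-wise / derivative evaluation harness: one row per (system, day)
## or (system, derivative), each carrying the odds ratio from logistic
## recalibration, OCC, Hosmer-Lemeshow calibration and ROC discrimination.

.emptyEvalRow <- function(label, system, n, n_deaths, note = "") {
  data.frame(label = label, system = system, n = n, n_deaths = n_deaths,
             odds_ratio = NA_real_, or_ci_low = NA_real_,
             or_ci_high = NA_real_, occ_pct = NA_real_,
             hl_chi2 = NA_real_, hl_df = NA_integer_, hl_p = NA_real_,
             auc = NA_real_, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
             significant_miscalibration = NA, evaluable = FALSE,
             note = note, stringsAsFactors = FALSE)
}

.evalOne <- function(label, system, scores, outcomes, hl_groups, occ_cutoff,
                     ci_method, alpha = 0.05) {
  fit <- fitScoreLogistic(scores, outcomes)
  hl <- suppressWarnings(hosmerLemeshow(fit$predicted, outcomes,
                                        g = hl_groups))
  ro <- rocAuc(scores, outcomes, ci_method = ci_method)
  data.frame(label = label, system = system, n = fit$n,
             n_deaths = fit$n_deaths,
             odds_ratio = fit$odds_ratio, or_ci_low = fit$or_ci_low,
             or_ci_high = fit$or_ci_high,
             occ_pct = occ(fit$predicted, outcomes, cutoff = occ_cutoff),
             hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p_value,
             auc = ro$auc, auc_ci_low = ro$ci_low, auc_ci_high = ro$ci_high,
             significant_miscalibration = isTRUE(hl$p_value < alpha),
             evaluable = TRUE, note = "", stringsAsFactors = FALSE)
}

#' Per-day evaluation of daily scores against ICU mortality
#'
#' For each ICU day `d` within the horizon, the at-risk set is every stay
#' with `iculos >= d`. The day-`d` totals of each requested system are
#' recalibrated by univariate logistic regression against ICU death; the
#' row reports the per-point odds ratio with Wald 95% CI, the overall
#' correct classification of the recalibrated probabilities, the
#' Hosmer-Lemeshow test on those probabilities, and the ROC AUC of the raw
#' totals with its CI. The day horizon (default 6) and the minimum at-risk
#' size guard against unstable small-sample statistics: days with fewer
#' at-risk stays than `min_n` are reported as unevaluable rather than
#' silently computed.
#'
#' @param cohort A [cohortTable()].
#' @param scores A `scoreTable` from [scoreCohort()] (or its `totals`
#'   data.frame).
#' @param systems Systems to evaluate (default: all present).
#' @param days Integer vector of ICU days (default `1:6`).
#' @param min_n Minimum at-risk set size (default 100).
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @param occ_cutoff Probability cutoff for OCC (default 0.5).
#' @param ci_method AUC CI method, `"delong"` or `"hanley"`.
#' @param alpha Significance threshold for flagging miscalibration
#'   (default 0.05).
#' @return data.frame of class `evaluationTable`, one row per
#'   (day, system); columns as in [renderTables()].
#' @examples
#' coh <- generateCohort(generatorConfig(n_stays = 300, seed = 4))
#' ev <- evaluatePerDay(coh, scoreCohort(coh, "SOFA"), min_n = 50)
#' ev[, c("label", "system", "n", "odds_ratio", "auc")]
#' @export
evaluatePerDay <- function(cohort, scores, systems = NULL, days = 1:6,
                           min_n = 100, hl_groups = 10, occ_cutoff = 0.5,
                           ci_method = c("delong", "hanley"), alpha = 0.05) {
  ci_method <- match.arg(ci_method)
  totals <- if (inherits(scores, "scoreTable")) scores$totals else scores
  if (is.null(systems)) systems <- unique(totals$system)
  out <- list()
  for (d in sort(days)) {
    at_risk <- cohort$stays[cohort$stays$iculos >= d, , drop = FALSE]
    y <- as.integer(at_risk$outcome == "icu_death")
    lab <- sprintf("ICU-Day %d", d)
    for (sys in systems) {
      td <- totals[totals$day == d & totals$system == sys, , drop = FALSE]
      x <- td$total[match(at_risk$stay_id, td$stay_id)]
      row <- if (nrow(at_risk) < min_n) {
        .emptyEvalRow(lab, sys, nrow(at_risk), sum(y),
                      sprintf("at-risk n below minimum %d", min_n))
      } else if (anyNA(x)) {
        .emptyEvalRow(lab, sys, nrow(at_risk), sum(y),
                      "missing daily totals for at-risk stays")
      } else {
        tryCatch(
          .evalOne(lab, sys, x, y, hl_groups, occ_cutoff, ci_method, alpha),
          icubench_error = function(e)
            .emptyEvalRow(lab, sys, nrow(at_risk), sum(y), conditionMessage(e)))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("evaluationTable", "data.frame")
  res
}

#' Evaluation of Mean- and Max-score derivatives
#'
#' Applies the same statistical battery as [evaluatePerDay()] to the
#' Mean-score and Max-score of every stay (all stays are at risk, so every
#' row has `n` equal to the cohort size).
#'
#' @param cohort A [cohortTable()].
#' @param summaries data.frame from [scoreSummaries()].
#' @inheritParams evaluatePerDay
#' @return data.frame of class `evaluationTable`, one row per
#'   (derivative, system), labels `"Mean-<system>"` and `"Max-<system>"`.
#' @export
evaluateDerivatives <- function(cohort, summaries, systems = NULL,
                                min_n = 100, hl_groups = 10,
                                occ_cutoff = 0.5,
                                ci_method = c("delong", "hanley"),
                                alpha = 0.05) {
  ci_method <- match.arg(ci_method)
  if (is.null(systems)) systems <- unique(summaries$system)
  y_all <- as.integer(cohort$stays$outcome == "icu_death")
  out <- list()
  for (deriv in c("Mean", "Max")) {
    col <- if (deriv == "Mean") "mean_score" else "max_score"
    for (sys in systems) {
      sd_ <- summaries[summaries$system == sys, , drop = FALSE]
      x <- sd_[[col]][match(cohort$stays$stay_id, sd_$stay_id)]
      lab <- sprintf("%s-%s", deriv, sys)
      row <- if (nrow(cohort$stays) < min_n) {
        .emptyEvalRow(lab, sys, nrow(cohort$stays), sum(y_all),
                      sprintf("n below minimum %d", min_n))
      } else if (anyNA(x)) {
        .emptyEvalRow(lab, sys, nrow(cohort$stays), sum(y_all),
                      "missing summaries for some stays")
      } else {
        tryCatch(
          .evalOne(lab, sys, x, y_all, hl_groups, occ_cutoff, ci_method,
                   alpha),
          icubench_error = function(e)
            .emptyEvalRow(lab, sys, nrow(cohort$stays), sum(y_all),
                          conditionMessage(e)))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("evaluationTable", "data.frame")
  res
}

#' @export
print.evaluationTable <- function(x, ...) {
  need <- c("label", "system", "n", "odds_ratio", "or_ci_low", "or_ci_high",
            "occ_pct", "hl_chi2", "hl_p", "auc", "auc_ci_low", "auc_ci_high")
  if (all(need %in% names(x))) cat(renderTables(x), sep = "\n")
  else print.data.frame(x, ...)
  invisible(x)
}
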