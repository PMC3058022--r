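#' Univariate logistic recalibration of a score
#'
#' Maximum-likelihood fit of `P(death) = logit^-1(a + b * score)`. The
#' exponentiated slope is the odds ratio of ICU death per score point; its
#' 95% confidence interval is Wald (`exp(b +/- 1.96 * SE)`). The fitted
#' per-subject probabilities feed the Hosmer-Lemeshow test and the overall
#' correct classification downstream, giving all four scoring systems a
#' comparable probability scale (two of them have no native one).
#'
#' @param scores Numeric vector of score points.
#' @param outcomes 0/1 vector (1 = ICU death), same length.
#' @return Object of class `logisticFit`: `intercept`, `slope`, `slope_se`,
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `predicted`, `n`, `n_deaths`.
#' @section Errors: fewer than two subjects in either outcome class,
#'   all-identical scores, or complete separation (every non-survivor
#'   scoring strictly beyond every survivor) raise classed errors; no
#'   silently huge odds ratio is ever returned.
#' @examples
#' set.seed(1)
#' x <- rpois(200, 8)
#' y <- rbinom(200, 1, plogis(-4 + 0.3 * x))
#' fitScoreLogistic(x, y)
#' @export
fitScoreLogistic <- function(scores, outcomes) {
  if (length(scores) != length(outcomes))
    .stopClassed("icubench_schema_error", "scores/outcomes length mismatch")
  if (!all(outcomes %in% c(0, 1)))
    .stopClassed("icubench_schema_error", "outcomes must be 0/1")
  if (sum(outcomes == 1) < 2 || sum(outcomes == 0) < 2)
    .stopClassed("icubench_degenerate_error",
                 "need at least two subjects of each outcome class")
  if (length(unique(scores)) == 1L)
    .stopClassed("icubench_degenerate_error", "scores are all identical")
  if (min(scores[outcomes == 1]) > max(scores[outcomes == 0]) ||
      max(scores[outcomes == 1]) < min(scores[outcomes == 0]))
    .stopClassed("icubench_separation_error",
                 "complete separation: logistic slope is unbounded")
  fit <- suppressWarnings(glm(outcomes ~ scores, family = binomial()))
  if (!fit$converged || abs(coef(fit)[2]) > 20)
    .stopClassed("icubench_separation_error",
                 "logistic recalibration did not converge")
  b <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))[2]
  structure(list(
    intercept = b[1], slope = b[2], slope_se = unname(se),
    odds_ratio = exp(b[2]),
    or_ci_low = exp(b[2] - 1.96 * se), or_ci_high = exp(b[2] + 1.96 * se),
    predicted = unname(fitted(fit)),
    n = length(outcomes), n_deaths = sum(outcomes == 1)),
    class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
  cat(sprintf(
    "logisticFit: n = %d (%d deaths); OR per point %.3f (95%% CI %.3f-%.3f)\n",
    x$n, x$n_deaths, x$odds_ratio, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by predicted probability into `g` near-equal-size
#' groups (deciles of risk by default; ties share a group), and
#' `chi2 = sum_g (O_g - E_g)^2 / (E_g * (1 - E_g / n_g))` is referred to a
#' chi-squared distribution with `g - 2` degrees of freedom. Calibration is
#' considered good when the statistic is low and `p > 0.05`.
#'
#' @param predicted Probabilities in (0, 1).
#' @param outcomes 0/1 vector (1 = death).
#' @param g Number of risk groups (default 10).
#' @return Object of class `hlResult`: `chi2`, `df`, `p_value` and a
#'   per-group data.frame `groups` (`n`, `observed`, `expected`,
#'   `mean_predicted`).
#' @section Errors and edge cases: `n < g` is an error. A group whose
#'   expected death count is zero (or one, on the survivor side) is merged
#'   into its neighbour with a warning; heavy ties can also reduce the
#'   group count, and the degrees of freedom follow the realized number of
#'   groups.
#' @export
hosmerLemeshow <- function(predicted, outcomes, g = 10) {
  n <- length(predicted)
  if (n != length(outcomes))
    .stopClassed("icubench_schema_error", "length mismatch")
  if (n < g)
    .stopClassed("icubench_degenerate_error",
                 "n = %d below the number of groups g = %d", n, g)
  if (any(predicted <= 0 | predicted >= 1))
    .stopClassed("icubench_schema_error",
                 "predicted probabilities must lie strictly in (0,1)")
  br <- unique(quantile(predicted, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < 3)
    .stopClassed("icubench_degenerate_error",
                 "predicted probabilities too tied to form risk groups")
  grp <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(
    n = as.vector(tapply(outcomes, grp, length)),
    observed = as.vector(tapply(outcomes, grp, sum)),
    expected = as.vector(tapply(predicted, grp, sum)),
    mean_predicted = as.vector(tapply(predicted, grp, mean)))
  # merge groups whose expected count (either side) vanishes
  repeat {
    denom <- tab$expected * (1 - tab$expected / tab$n)
    bad <- which(denom < .Machine$double.eps^0.5)
    if (!length(bad) || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    warning("merging a risk group with vanishing expected count",
            call. = FALSE)
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$mean_predicted[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, , drop = FALSE]
  }
  denom <- tab$expected * (1 - tab$expected / tab$n)
  chi2 <- sum((tab$observed - tab$expected)^2 / denom)
  df <- nrow(tab) - 2L
  p <- if (df >= 1) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  rownames(tab) <- NULL
  structure(list(chi2 = chi2, df = df, p_value = p, groups = tab),
            class = "hlResult")
}

#' @export
print.hlResult <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.2f on %d df, p = %.3g (%d groups)\n",
              x$chi2, x$df, x$p_value, nrow(x$groups)))
  invisible(x)
}

#' ROC area under the curve with confidence interval
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen
#' non-survivor scores above a randomly chosen survivor, ties counted one
#' half; computed from mid-ranks. An anti-discriminating score yields
#' AUC < 0.5 and is reported as-is (never folded to `1 - AUC`). The 95%
#' confidence interval uses DeLong's method by default (via \pkg{pROC}) or
#' the Hanley-McNeil normal approximation.
#'
#' @param scores Numeric score values (higher = predicted worse outcome).
#' @param outcomes 0/1 vector (1 = death).
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @return Object of class `rocResult`: `auc`, `ci_low`, `ci_high`,
#'   `ci_method`, `n_pos`, `n_neg`.
#' @examples
#' rocAuc(c(1, 3, 2, 4), c(0, 0, 1, 1))  # AUC 0.75
#' @export
rocAuc <- function(scores, outcomes, ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  if (length(scores) != length(outcomes))
    .stopClassed("icubench_schema_error", "length mismatch")
  n_pos <- sum(outcomes == 1); n_neg <- sum(outcomes == 0)
  if (n_pos == 0 || n_neg == 0)
    .stopClassed("icubench_degenerate_error",
                 "both outcome classes must be present")
  r <- rank(scores)   # mid-ranks handle ties as 1/2
  auc <- (sum(r[outcomes == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (ci_method == "delong") {
    ro <- pROC::roc(response = outcomes, predictor = scores,
                    direction = "<", levels = c(0, 1), quiet = TRUE)
    # pROC prints an advisory for degenerate (AUC = 1) curves; the
    # zero-width interval it returns is exactly what we report
    ci <- as.numeric(suppressWarnings(pROC::ci.auc(ro, method = "delong")))
    lo <- ci[1]; hi <- ci[3]
  } else {
    a <- auc
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                  (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
    lo <- max(0, a - 1.96 * se); hi <- min(1, a + 1.96 * se)
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi,
                 ci_method = ci_method, n_pos = n_pos, n_neg = n_neg),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f, %s), %d/%d pos/neg\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Overall correct classification
#'
#' Percentage of subjects whose predicted class (death when the predicted
#' probability reaches the cutoff, survival otherwise) matches the observed
#' outcome.
#'
#' @param predicted Probabilities in \[0, 1\].
#' @param outcomes 0/1 vector (1 = death).
#' @param cutoff Classification cutoff on the probability scale
#'   (default 0.5).
#' @return Percentage in \[0, 100\].
#' @examples
#' occ(c(0.9, 0.2, 0.6, 0.1), c(1, 0, 0, 0))  # 75
#' @export
occ <- function(predicted, outcomes, cutoff = 0.5) {
  if (length(predicted) == 0L)
    .stopClassed("icubench_schema_error", "empty input")
  100 * mean((predicted >= cutoff) == (outcomes == 1))
}
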