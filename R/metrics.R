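#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials non-negative integers, `successes <= trials`,
#'   `trials > 0`.
#' @param level two-sided confidence level in `(0, 1)` (default 0.95).
#' @return numeric vector `c(lower, upper)` in `[0, 1]`; always contains the
#'   point estimate `successes/trials`.
#' @examples
#' wilson_interval(278, 373)      # about (0.70, 0.79)
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  check_scalar_number(trials, "trials", lower = 1, integer = TRUE)
  check_scalar_number(successes, "successes", lower = 0, upper = trials,
                      integer = TRUE)
  check_scalar_number(level, "level", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  # closed-form bounds are exactly 0/1 at the boundaries; avoid fp residue
  lower <- if (successes == 0) 0 else max(0, centre - half)
  upper <- if (successes == trials) 1 else min(1, centre + half)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy report from a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, diagnostic accuracy (each with a Wilson score interval), Youden's
#' J, and the binary-classifier AUC. For a binary (single operating point)
#' test the ROC curve has two non-trivial points, and its area is exactly
#' `(sensitivity + specificity) / 2`; the AUC interval is a normal
#' approximation combining the binomial variances of sensitivity and
#' specificity.
#'
#' A metric whose denominator is zero (e.g. PPV when the rule classifies
#' nobody positive) is reported as `NA` and listed in `$undefined`; the
#' remaining metrics are still returned.
#'
#' @param cm a [confusion_matrix()].
#' @param ci_level two-sided confidence level (default 0.95).
#' @return object of class `diagnostic_report`: a list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `auc` (each
#'   `c(estimate, lower, upper)` as fractions), `youden_j`, `n`,
#'   `prevalence`, `undefined` and `ci_level`.
#' @examples
#' metrics_from_cm(confusion_matrix(278, 208, 95, 1564))
#' @export
metrics_from_cm <- function(cm, ci_level = 0.95) {
  if (!inherits(cm, "confusion_matrix"))
    stop_field("cm", "must be a confusion_matrix")
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n <= 0) stop_field("cm", "empty confusion matrix")
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0)
    stop_field("cm", "both reference classes must be present")

  prop <- function(x, m) {
    if (m == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    ci <- wilson_interval(x, m, ci_level)
    c(estimate = x / m, lower = unname(ci[1L]), upper = unname(ci[2L]))
  }
  se <- prop(cm$tp, cm$tp + cm$fn)
  sp <- prop(cm$tn, cm$tn + cm$fp)
  ppv <- prop(cm$tp, cm$tp + cm$fp)
  npv <- prop(cm$tn, cm$tn + cm$fn)
  acc <- prop(cm$tp + cm$tn, n)

  auc_est <- (se[["estimate"]] + sp[["estimate"]]) / 2
  var_se <- se[["estimate"]] * (1 - se[["estimate"]]) / (cm$tp + cm$fn)
  var_sp <- sp[["estimate"]] * (1 - sp[["estimate"]]) / (cm$tn + cm$fp)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  auc_half <- z * sqrt((var_se + var_sp) / 4)
  auc <- c(estimate = auc_est,
           lower = max(0, auc_est - auc_half),
           upper = min(1, auc_est + auc_half))

  metrics <- list(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
                  accuracy = acc, auc = auc)
  undefined <- names(metrics)[vapply(metrics, function(m) is.na(m[["estimate"]]),
                                     logical(1L))]
  structure(c(metrics,
              list(youden_j = se[["estimate"]] + sp[["estimate"]] - 1,
                   n = n,
                   prevalence = (cm$tp + cm$fn) / n,
                   undefined = undefined,
                   ci_level = ci_level)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pct <- function(m) {
    if (is.na(m[["estimate"]])) return("undefined")
    sprintf("%d (%d-%d)",
            round_half_up(100 * m[["estimate"]]),
            round_half_up(100 * m[["lower"]]),
            round_half_up(100 * m[["upper"]]))
  }
  cat("Diagnostic accuracy (n = ", x$n, ", ",
      round_half_up(100 * x$ci_level), "% CI)\n", sep = "")
  cat(sprintf("  %-20s %s\n", "Sensitivity", pct(x$sensitivity)))
  cat(sprintf("  %-20s %s\n", "Specificity", pct(x$specificity)))
  cat(sprintf("  %-20s %s\n", "PPV", pct(x$ppv)))
  cat(sprintf("  %-20s %s\n", "NPV", pct(x$npv)))
  cat(sprintf("  %-20s %s\n", "Diagnostic accuracy", pct(x$accuracy)))
  cat(sprintf("  %-20s %.2f (%.2f-%.2f)\n", "AUC",
              round_half_up(x$auc[["estimate"]], 2),
              round_half_up(x$auc[["lower"]], 2),
              round_half_up(x$auc[["upper"]], 2)))
  cat(sprintf("  %-20s %.3f\n", "Youden J", x$youden_j))
  invisible(x)
}

#' Youden's J of a confusion matrix
#'
#' `J = sensitivity + specificity - 1`.
#'
#' @param cm a [confusion_matrix()].
#' @return J in `[-1, 1]`.
#' @export
youden_j <- function(cm) {
  cm$tp / (cm$tp + cm$fn) - cm$fp / (cm$fp + cm$tn)
}
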