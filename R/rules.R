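#' Staged (three-zone) classification rule
#'
#' A staged rule classifies a patient negative when stenosis is below the
#' band, positive when stenosis is above the band, and inside the band
#' positive exactly when plaque burden (PAV) reaches the threshold. All
#' comparisons are inclusive: the band is `[lower, upper]` and the PAV test
#' is `pav >= pav_threshold`. `upper = Inf` gives the gated form (negative
#' below `lower`, PAV decides everywhere above — "Model 2"). A degenerate
#' band (`upper < lower`) is interpreted as a pure binary stenosis cutoff at
#' `lower`, so a plain cutoff rule ("Model 1") lives in the same algebra.
#'
#' @param lower rule-out stenosis bound, percent in `[0, 100]`.
#' @param upper rule-in stenosis bound, percent in `[0, 100]` or `Inf`.
#' @param pav_threshold PAV threshold applied inside the band, percent in
#'   `[0, 100]`.
#' @return object of class `staged_rule`.
#' @examples
#' model3 <- staged_rule(30, 70, 12.2)
#' classify_staged(c(20, 50, 80), c(40, 12.2, 0), model3)
#' @export
staged_rule <- function(lower, upper = Inf, pav_threshold) {
  check_scalar_number(lower, "lower", lower = 0, upper = 100)
  if (!(is.numeric(upper) && length(upper) == 1L &&
        (is.infinite(upper) && upper > 0 || (is.finite(upper) && upper >= 0 && upper <= 100))))
    stop_field("upper", "must lie in [0, 100] or be Inf")
  check_scalar_number(pav_threshold, "pav_threshold", lower = 0, upper = 100)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 pav_threshold = as.numeric(pav_threshold)),
            class = "staged_rule")
}

#' @export
format.staged_rule <- function(x, ...) {
  if (x$upper < x$lower)
    sprintf("stenosis >= %g%% (binary; degenerate band)", x$lower)
  else
    sprintf("stenosis band [%g, %s]%% with PAV >= %g%%",
            x$lower, if (is.finite(x$upper)) format(x$upper) else "Inf",
            x$pav_threshold)
}

#' @export
print.staged_rule <- function(x, ...) {
  cat("<staged_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a rule from its compact string form
#'
#' `"30:70:12.2"` is the staged rule with band `[30, 70]` and PAV threshold
#' 12.2; `"50:inf:16.8"` the gated form.
#'
#' @param text string `lower:upper:pav_threshold`; `upper` may be `inf`.
#' @return a [staged_rule()].
#' @export
parse_rule <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop_field("rule", "expected 'lower:upper:pav_threshold'")
  upper <- if (tolower(parts[2L]) %in% c("inf", "+inf")) Inf else as.numeric(parts[2L])
  staged_rule(as.numeric(parts[1L]), upper, as.numeric(parts[3L]))
}

rule_to_list <- function(rule) {
  list(lower = rule$lower,
       upper = if (is.finite(rule$upper)) rule$upper else "inf",
       pav_threshold = rule$pav_threshold)
}

rule_from_list <- function(x) {
  upper <- x$upper
  if (is.character(upper)) upper <- Inf
  staged_rule(x$lower, upper, x$pav_threshold)
}

#' Binary stenosis classification
#'
#' @param stenosis percent stenosis values in `[0, 100]` (vectorized).
#' @param cutoff percent cutoff in `(0, 100)`; the comparison is inclusive
#'   (`stenosis >= cutoff` is positive).
#' @return logical vector, `TRUE` = positive.
#' @examples
#' classify_binary(c(49.9, 50), 50)
#' @export
classify_binary <- function(stenosis, cutoff = 50) {
  check_scalar_number(cutoff, "cutoff", lower = 0, upper = 100,
                      open_lower = TRUE, open_upper = TRUE)
  if (!is.numeric(stenosis) || any(stenosis < 0 | stenosis > 100, na.rm = TRUE))
    stop_field("stenosis", "must lie in [0, 100]")
  stenosis >= cutoff
}

#' Apply a staged rule
#'
#' @param stenosis,pav percent values (vectorized, equal length or length 1).
#' @param rule a [staged_rule()].
#' @return logical vector, `TRUE` = positive.
#' @export
classify_staged <- function(stenosis, pav, rule) {
  if (!inherits(rule, "staged_rule")) stop_field("rule", "must be a staged_rule")
  if (rule$upper < rule$lower)      # degenerate band: pure cutoff at `lower`
    return(stenosis >= rule$lower)
  ifelse(stenosis < rule$lower, FALSE,
         ifelse(stenosis > rule$upper, TRUE, pav >= rule$pav_threshold))
}

#' Confusion matrix of a classifier against the reference label
#'
#' @param tp,fp,fn,tn non-negative integer counts (test-positive true
#'   positives, false positives, false negatives, true negatives).
#' @return object of class `confusion_matrix` (a named list).
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!is.numeric(cells) || length(cells) != 4L || any(is.na(cells)) ||
      any(cells < 0) || any(cells != floor(cells)))
    stop_field("confusion_matrix", "cells must be non-negative integers")
  structure(as.list(as.numeric(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("ref+", "ref-")))
  print(m)
  invisible(x)
}

#' Evaluate a rule on a cohort
#'
#' Cross-tabulates the rule's classification against the reference label.
#'
#' @param cohort data frame with columns `stenosis`, `pav` and the label
#'   column.
#' @param rule a [staged_rule()] or a single numeric binary cutoff.
#' @param label name of the logical/0-1 reference column (default
#'   `"ischemia"`; use `"latent_ischemia"` for verification-bias-free
#'   evaluation of simulated cohorts).
#' @return a [confusion_matrix()].
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 200, seed = 3))
#' evaluate_rule(cohort, staged_rule(30, 70, 12.2))
#' @export
evaluate_rule <- function(cohort, rule, label = "ischemia") {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_field("cohort", "must be a non-empty data frame")
  need <- c("stenosis", "pav", label)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_field("cohort", paste("missing column(s):",
                               paste(missing_cols, collapse = ", ")))
  pred <- if (inherits(rule, "staged_rule"))
    classify_staged(cohort$stenosis, cohort$pav, rule)
  else
    classify_binary(cohort$stenosis, rule)
  ref <- as.logical(cohort[[label]])
  if (any(is.na(pred)) || any(is.na(ref)))
    stop_field("cohort", "stenosis/pav/label must be complete")
  confusion_matrix(tp = sum(pred & ref), fp = sum(pred & !ref),
                   fn = sum(!pred & ref), tn = sum(!pred & !ref))
}
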