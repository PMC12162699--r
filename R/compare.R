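# Paired between-model comparison tests. The published analysis names none
# of its tests; these are documented conventional choices for paired binary
# classifiers sharing one reference standard, validated by type-I-error
# simulation rather than by reproducing printed p-values.

paired_inputs <- function(pred_a, pred_b, labels) {
  pred_a <- as.logical(pred_a); pred_b <- as.logical(pred_b)
  labels <- as.logical(labels)
  n <- length(labels)
  if (length(pred_a) != n || length(pred_b) != n)
    stop_field("paired classifications", "all vectors must share one length")
  if (n == 0L || any(is.na(pred_a)) || any(is.na(pred_b)) || any(is.na(labels)))
    stop_field("paired classifications", "must be non-empty and complete")
  list(a = pred_a, b = pred_b, y = labels)
}

#' Exact McNemar comparison of paired sensitivities
#'
#' Restricted to reference-positive patients, counts the discordant pairs
#' (positive under one rule only) and applies the exact two-sided binomial
#' test of symmetry. With zero discordant pairs the rules are
#' indistinguishable and `p = 1` is returned with `warning = TRUE`.
#'
#' @param pred_a,pred_b logical classifications of the same patients under
#'   rules A and B.
#' @param labels logical reference labels.
#' @return list with `p_value`, discordant counts `b` (A+ B-) and `c`
#'   (A- B+), `n_discordant` and `warning`.
#' @seealso [compare_specificity()] for the same machinery on
#'   reference-negatives.
#' @export
compare_sensitivity <- function(pred_a, pred_b, labels) {
  z <- paired_inputs(pred_a, pred_b, labels)
  mcnemar_exact(z$a[z$y], z$b[z$y])
}

#' Exact McNemar comparison of paired specificities
#'
#' As [compare_sensitivity()], restricted to reference-negative patients
#' (discordance in the *negative* classification).
#'
#' @inheritParams compare_sensitivity
#' @return as [compare_sensitivity()].
#' @export
compare_specificity <- function(pred_a, pred_b, labels) {
  z <- paired_inputs(pred_a, pred_b, labels)
  mcnemar_exact(!z$a[!z$y], !z$b[!z$y])
}

mcnemar_exact <- function(correct_a, correct_b) {
  b <- sum(correct_a & !correct_b)   # A right, B wrong
  cc <- sum(!correct_a & correct_b)  # B right, A wrong
  m <- b + cc
  if (m == 0L)
    return(list(p_value = 1.0, b = b, c = cc, n_discordant = 0L,
                warning = TRUE))
  p <- stats::binom.test(min(b, cc), m, p = 0.5)$p.value
  list(p_value = min(1, p), b = b, c = cc, n_discordant = m,
       warning = FALSE)
}

#' Generalized score comparison of paired predictive values
#'
#' Weighted generalized score statistic for comparing positive and negative
#' predictive values of two binary tests applied to the same patients
#' (Leisenring-style relative-predictive-value test). For PPV the analysis
#' set is one record per (patient, test) pair with a positive test result;
#' the score statistic for the test-indicator coefficient, with an empirical
#' (sandwich) variance that respects within-patient pairing, is referred to
#' chi-squared with 1 df. NPV uses the mirrored construction on negative
#' results.
#'
#' @inheritParams compare_sensitivity
#' @return list with elements `ppv` and `npv`, each holding `statistic`,
#'   `p_value` and `undefined` (`TRUE` when no patient enters the
#'   comparison, e.g. no positives under either rule for PPV).
#' @export
compare_predictive_values <- function(pred_a, pred_b, labels) {
  z <- paired_inputs(pred_a, pred_b, labels)
  list(ppv = leisenring_score(z$a, z$b, z$y),
       npv = leisenring_score(!z$a, !z$b, !z$y))
}

# Generalized score statistic for H0: P(y | a = 1) = P(y | b = 1).
# x1/x2: record-inclusion indicators (test positive), y: outcome.
leisenring_score <- function(x1, x2, y) {
  denom <- sum(x1) + sum(x2)
  if (denom == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, undefined = TRUE))
  phat <- sum(y * (x1 + x2)) / denom          # pooled predictive value
  u_i <- x2 * (y - phat)                       # per-patient score (test B)
  s_i <- (x1 + x2) * (y - phat)                # per-patient intercept score
  w <- sum(x2) / denom
  U <- sum(u_i)
  V <- sum((u_i - w * s_i)^2)
  if (V <= 0) {
    p <- if (abs(U) < .Machine$double.eps^0.5) 1.0 else 0.0
    return(list(statistic = if (U == 0) 0 else Inf, p_value = p,
                undefined = FALSE))
  }
  stat <- U^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       undefined = FALSE)
}

#' Paired comparison of binary-classifier AUCs
#'
#' For a binary rule the ROC area is exactly `(Se + Sp) / 2`, so the paired
#' AUC difference is `(dSe + dSp) / 2`, with `dSe` estimated on
#' reference-positives and `dSp` on reference-negatives. The variance of
#' each paired difference of proportions comes from the discordant-pair
#' structure (the DeLong paired variance specialized to binary scores); the
#' two strata are independent, and the statistic is referred to the standard
#' normal, two-sided.
#'
#' @inheritParams compare_sensitivity
#' @return list with `auc_a`, `auc_b`, `difference`, `statistic`, `p_value`.
#' @export
compare_auc_binary <- function(pred_a, pred_b, labels) {
  z <- paired_inputs(pred_a, pred_b, labels)
  n1 <- sum(z$y); n0 <- sum(!z$y)
  if (n1 == 0L || n0 == 0L)
    stop_field("labels", "both reference classes must be present")

  paired_diff <- function(a, b, n) {
    d <- (sum(a) - sum(b)) / n
    b10 <- sum(a & !b); b01 <- sum(!a & b)
    v <- (b10 + b01 - (b10 - b01)^2 / n) / n^2
    c(d = d, v = v)
  }
  se_d <- paired_diff(z$a[z$y], z$b[z$y], n1)
  sp_d <- paired_diff(!z$a[!z$y], !z$b[!z$y], n0)

  diff <- (se_d[["d"]] + sp_d[["d"]]) / 2
  v <- (se_d[["v"]] + sp_d[["v"]]) / 4
  auc_a <- (sum(z$a & z$y) / n1 + sum(!z$a & !z$y) / n0) / 2
  auc_b <- (sum(z$b & z$y) / n1 + sum(!z$b & !z$y) / n0) / 2
  if (v <= 0) {
    p <- if (abs(diff) < .Machine$double.eps^0.5) 1.0 else 0.0
    return(list(auc_a = auc_a, auc_b = auc_b, difference = diff,
                statistic = if (diff == 0) 0 else Inf, p_value = p))
  }
  stat <- diff / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, difference = diff, statistic = stat,
       p_value = 2 * stats::pnorm(-abs(stat)))
}
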