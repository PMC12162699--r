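#' Grid specification for the staged-rule search
#'
#' The default grid is the published search space: stenosis band bounds from
#' 1 to 99% in 1% steps (with `upper >= lower` enforced during the search)
#' and PAV thresholds from 0.1 to 49.0% in 0.1% steps (490 candidate
#' thresholds), i.e. 99 * 100 / 2 * 490 = 2,425,500 candidate rules.
#'
#' @param lower_values,upper_values candidate stenosis bounds, percent.
#' @param pav_values candidate PAV thresholds, percent.
#' @return object of class `grid_spec` with sorted, de-duplicated axes.
#' @export
grid_spec <- function(lower_values = 1:99,
                      upper_values = 1:99,
                      pav_values = default_pav_grid()) {
  chk <- function(x, field, lo, hi) {
    if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
      stop_field(field, "must be non-empty finite numerics")
    if (any(x < lo) || any(x > hi))
      stop_field(field, sprintf("values must lie in [%g, %g]", lo, hi))
    sort(unique(as.numeric(x)))
  }
  structure(list(lower_values = chk(lower_values, "lower_values", 0, 100),
                 upper_values = chk(upper_values, "upper_values", 0, 100),
                 pav_values = chk(pav_values, "pav_values", 0, 100)),
            class = "grid_spec")
}

#' Default PAV threshold grid: 0.1 to 49.0 percent in 0.1 steps
#' @return numeric vector of length 490 (exact multiples of 0.1).
#' @export
default_pav_grid <- function() seq_len(490L) / 10

search_labels <- function(cohort, label) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_field("cohort", "must be a non-empty data frame")
  y <- as.logical(cohort[[label]])
  if (any(is.na(y))) stop_field("cohort", "labels must be complete")
  if (!any(y)) stop("cohort contains no reference-positive patients",
                    call. = FALSE)
  if (all(y)) stop("cohort contains no reference-negative patients",
                   call. = FALSE)
  y
}

#' Exhaustive grid search for the optimal staged rule
#'
#' Scores every rule `(lower, upper, pav_threshold)` of the grid (with
#' `upper >= lower`) by whole-cohort Youden's J of the staged classification
#' against the reference label, and returns the maximizer together with the
#' complete tie set.
#'
#' The implementation bins patients on the grid's own breakpoints and scores
#' all rules from two cumulative count matrices (cases and controls) in
#' O(bins + rules); all threshold comparisons go through [findInterval()] on
#' the exact grid values, so results are identical to naive per-rule
#' enumeration of [classify_staged()] for any input. J comparisons use the
#' integer-valued scaled objective `tp * n_controls - fp * n_cases`, so ties
#' are exact, not floating-point-fuzzy.
#'
#' Tie-breaking among maximum-J rules: higher specificity (fewer false
#' positives), then narrower band (`upper - lower`), then lower PAV
#' threshold.
#'
#' @param cohort data frame with `stenosis`, `pav` and the label column.
#' @param spec a [grid_spec()].
#' @param label reference label column (default `"ischemia"`).
#' @return object of class `search_result`: list with `best_rule`
#'   ([staged_rule()]), `best_j`, `best_cm` ([confusion_matrix()]), `ties`
#'   (data frame `lower`, `upper`, `pav_threshold`, `tp`, `fp`) and
#'   `grid_evaluated` (number of rules scored).
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 300, seed = 11))
#' grid_search_staged(cohort, grid_spec(seq(10, 90, 10), seq(10, 90, 10),
#'                                      c(5, 10, 15)))
#' @export
grid_search_staged <- function(cohort, spec = grid_spec(),
                               label = "ischemia") {
  if (!inherits(spec, "grid_spec")) stop_field("spec", "must be a grid_spec")
  y <- search_labels(cohort, label)
  s <- as.numeric(cohort$stenosis)
  p <- as.numeric(cohort$pav)
  if (any(is.na(s)) || any(is.na(p)))
    stop_field("cohort", "stenosis and pav must be complete")

  L <- spec$lower_values; H <- spec$upper_values; TT <- spec$pav_values
  nL <- length(L); nH <- length(H); K <- length(TT)
  ncase <- sum(y); nctrl <- sum(!y)

  # monotone combined stenosis index: (# L <= s) + (# H < s); the two
  # inequality senses encode the closed lower / open upper band edges.
  iL <- findInterval(s, L)
  iH <- findInterval(s, H, left.open = TRUE)
  cidx <- iL + iH                      # 0 .. nL + nH
  iT <- findInterval(p, TT)            # 0 .. K ; pav >= TT[k]  <=>  iT >= k
  C <- nL + nH

  # padded 2-D prefix counts: P[r, j] = #{cidx <= r - 2, iT <= j - 2}
  prefix2 <- function(keep) {
    M <- matrix(0, C + 1L, K + 1L)
    if (any(keep)) {
      tab <- table(factor(cidx[keep], levels = 0:C),
                   factor(iT[keep], levels = 0:K))
      M <- matrix(as.numeric(tab), C + 1L, K + 1L)
    }
    M <- apply(M, 2L, cumsum)
    M <- t(apply(M, 1L, cumsum))
    rbind(0, cbind(0, M))
  }
  Pc <- prefix2(y)          # cases
  Pt <- prefix2(!y)         # controls
  D <- nctrl * Pc - ncase * Pt

  # row indices: "cidx <= m" lives at row m + 2
  cLa <- seq_len(nL) + findInterval(L, H, left.open = TRUE)  # cidx at s = L[a]
  cHb <- seq_len(nH) + findInterval(H, L)                    # cidx just above H[b]
  cols <- 1L + seq_len(K)                                    # iT <= k - 1
  col_all <- K + 2L

  bmin <- findInterval(L, H, left.open = TRUE) + 1L  # first b with H[b] >= L[a]
  grid_evaluated <- sum(pmax(0L, nH - bmin + 1L)) * K
  if (grid_evaluated == 0L)
    stop_field("spec", "grid contains no rule with upper >= lower")

  best <- -Inf
  pair_max <- vector("list", nL)
  for (a in seq_len(nL)) {
    if (bmin[a] > nH) { pair_max[[a]] <- numeric(0); next }
    rL <- cLa[a] + 1L
    base_a <- ncase * Pt[rL, col_all] - nctrl * Pc[rL, col_all] + D[rL, cols]
    bs <- bmin[a]:nH
    pm <- numeric(length(bs))
    for (j in seq_along(bs)) {
      m <- max(base_a - D[cHb[bs[j]] + 1L, cols])
      pm[j] <- m
      if (m > best) best <- m
    }
    pair_max[[a]] <- pm
  }

  ties <- list()
  for (a in seq_len(nL)) {
    pm <- pair_max[[a]]
    if (!length(pm) || max(pm) < best) next
    rL <- cLa[a] + 1L
    base_a <- ncase * Pt[rL, col_all] - nctrl * Pc[rL, col_all] + D[rL, cols]
    bs <- bmin[a]:nH
    for (j in seq_along(bs)) {
      if (pm[j] < best) next
      rU <- cHb[bs[j]] + 1L
      Jv <- base_a - D[rU, cols]
      ks <- which(Jv == best)
      if (!length(ks)) next
      tp <- ncase - Pc[rL, col_all] - (Pc[rU, 1L + ks] - Pc[rL, 1L + ks])
      fp <- nctrl - Pt[rL, col_all] - (Pt[rU, 1L + ks] - Pt[rL, 1L + ks])
      ties[[length(ties) + 1L]] <-
        data.frame(lower = L[a], upper = H[bs[j]], pav_threshold = TT[ks],
                   tp = tp, fp = fp)
    }
  }
  ties <- do.call(rbind, ties)
  ord <- order(ties$fp, ties$upper - ties$lower, ties$pav_threshold)
  ties <- ties[ord, , drop = FALSE]
  rownames(ties) <- NULL
  top <- ties[1L, ]
  best_cm <- confusion_matrix(tp = top$tp, fp = top$fp,
                              fn = ncase - top$tp, tn = nctrl - top$fp)
  structure(list(best_rule = staged_rule(top$lower, top$upper,
                                         top$pav_threshold),
                 best_j = youden_j(best_cm),
                 best_cm = best_cm,
                 ties = ties,
                 grid_evaluated = grid_evaluated),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>\n  best rule: ", format(x$best_rule),
      sprintf("\n  Youden J : %.4f (%d tie%s, %s rules scored)\n",
              x$best_j, nrow(x$ties), if (nrow(x$ties) == 1L) "" else "s",
              format(x$grid_evaluated, big.mark = ",")), sep = "")
  invisible(x)
}

#' Youden-optimal PAV threshold within a stenosis subgroup
#'
#' Restricts the cohort to patients whose stenosis lies in
#' `[subgroup_lower, subgroup_upper]` (inclusive; `Inf` for an open upper
#' end) and finds the candidate PAV threshold maximizing Youden's J of the
#' classification `pav >= threshold`. With `objective = "subgroup"`
#' (default) J is computed within the subgroup — the convention for the
#' published 16.8% and 12.2% thresholds. With `objective = "cohort"` the
#' candidate thresholds are scored as full staged rules
#' `(subgroup_lower, subgroup_upper, t)` on the whole cohort.
#'
#' Tie-breaking among maximum-J candidates: higher sensitivity first, then
#' the largest threshold.
#'
#' @param cohort data frame with `stenosis`, `pav` and the label column.
#' @param subgroup_lower,subgroup_upper stenosis band, percent
#'   (`subgroup_upper` may be `Inf`).
#' @param candidate_thresholds candidate PAV thresholds (default the 0.1%
#'   grid of [default_pav_grid()]).
#' @param label reference label column.
#' @param objective `"subgroup"` or `"cohort"` (see Details).
#' @return list with `threshold`, `j`, `cm` ([confusion_matrix()]), `ties`
#'   (all thresholds attaining the maximum J) and `n_subgroup`.
#' @export
youden_threshold_subgroup <- function(cohort, subgroup_lower,
                                      subgroup_upper = Inf,
                                      candidate_thresholds = default_pav_grid(),
                                      label = "ischemia",
                                      objective = c("subgroup", "cohort")) {
  objective <- match.arg(objective)
  if (!is.numeric(candidate_thresholds) || length(candidate_thresholds) == 0L)
    stop_field("candidate_thresholds", "must be non-empty numerics")
  tt <- sort(unique(as.numeric(candidate_thresholds)))
  y_all <- as.logical(cohort[[label]])
  in_band <- cohort$stenosis >= subgroup_lower & cohort$stenosis <= subgroup_upper
  if (!any(in_band))
    stop("stenosis subgroup is empty", call. = FALSE)
  y_sub <- y_all[in_band]
  if (!any(y_sub))
    stop("subgroup lacks reference-positive patients", call. = FALSE)
  if (all(y_sub))
    stop("subgroup lacks reference-negative patients", call. = FALSE)

  if (objective == "subgroup") {
    pav <- cohort$pav[in_band]
    y <- y_sub
    tp <- vapply(tt, function(t) sum(pav >= t & y), numeric(1L))
    fp <- vapply(tt, function(t) sum(pav >= t & !y), numeric(1L))
    ncase <- sum(y); nctrl <- sum(!y)
  } else {
    y <- search_labels(cohort, label)
    ncase <- sum(y); nctrl <- sum(!y)
    above <- cohort$stenosis > subgroup_upper
    tp0 <- sum(above & y); fp0 <- sum(above & !y)
    pav <- cohort$pav[in_band]
    tp <- tp0 + vapply(tt, function(t) sum(pav >= t & y_sub), numeric(1L))
    fp <- fp0 + vapply(tt, function(t) sum(pav >= t & !y_sub), numeric(1L))
  }
  jscaled <- tp * nctrl - fp * ncase
  best <- max(jscaled)
  tie_idx <- which(jscaled == best)
  # prefer higher sensitivity, then the largest threshold
  pick <- tie_idx[order(-tp[tie_idx], -tt[tie_idx])][1L]
  cm <- confusion_matrix(tp = tp[pick], fp = fp[pick],
                         fn = ncase - tp[pick], tn = nctrl - fp[pick])
  list(threshold = tt[pick], j = youden_j(cm), cm = cm,
       ties = tt[tie_idx], n_subgroup = sum(in_band))
}

#' Refit the PAV threshold for a fixed (e.g. clinically rounded) band
#'
#' The two-step procedure behind the staged model: take a stenosis band
#' (typically the grid-search optimum simplified for clinical use), rerun
#' the one-dimensional Youden threshold search for PAV inside that band, and
#' return the completed staged rule.
#'
#' @inheritParams youden_threshold_subgroup
#' @param band_lower,band_upper the fixed stenosis band, percent.
#' @return a [staged_rule()] with the refitted threshold.
#' @export
refit_threshold_for_band <- function(cohort, band_lower, band_upper,
                                     candidate_thresholds = default_pav_grid(),
                                     label = "ischemia",
                                     objective = c("subgroup", "cohort")) {
  fit <- youden_threshold_subgroup(cohort, band_lower, band_upper,
                                   candidate_thresholds, label,
                                   match.arg(objective))
  staged_rule(band_lower, band_upper, fit$threshold)
}
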