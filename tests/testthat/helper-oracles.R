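# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (brute-force enumeration, closed forms)
# kept separate from the implementation paths they check.

# brute-force staged-rule grid search: triple loop, per-rule classification
naive_grid_search <- function(cohort, spec, label = "ischemia") {
  y <- as.logical(cohort[[label]])
  ncase <- sum(y); nctrl <- sum(!y)
  best <- -Inf; ties <- NULL
  for (lo in spec$lower_values) for (hi in spec$upper_values) {
    if (hi < lo) next
    for (t in spec$pav_values) {
      pred <- ifelse(cohort$stenosis < lo, FALSE,
                     ifelse(cohort$stenosis > hi, TRUE, cohort$pav >= t))
      tp <- sum(pred & y); fp <- sum(pred & !y)
      js <- tp * nctrl - fp * ncase   # scaled Youden objective (exact)
      if (js > best) { best <- js; ties <- NULL }
      if (js == best)
        ties <- rbind(ties, c(lower = lo, upper = hi, pav_threshold = t))
    }
  }
  list(best_j = best / (ncase * nctrl),
       ties = as.data.frame(ties))
}

sort_rules <- function(df) {
  df <- df[order(df$lower, df$upper, df$pav_threshold),
           c("lower", "upper", "pav_threshold")]
  rownames(df) <- NULL
  df
}

# Wilson interval via the quadratic-root form (independent arrangement)
wilson_by_roots <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  # roots of (p_hat - theta)^2 * n = z^2 * theta * (1 - theta)
  a <- n + z^2
  b <- -(2 * n * p + z^2)
  cc <- n * p^2
  disc <- sqrt(b^2 - 4 * a * cc)
  sort(c((-b - disc) / (2 * a), (-b + disc) / (2 * a)))
}

toy_cohort4 <- function() {
  data.frame(stenosis = c(20, 40, 40, 80),
             pav = c(5, 15, 5, 2),
             ischemia = c(FALSE, TRUE, FALSE, TRUE))
}

random_toy_cohort <- function(n) {
  data.frame(stenosis = runif(n, 0, 100),
             pav = runif(n, 0, 45),
             ischemia = runif(n) < 0.4)
}

# perfusion rule as plain edge logic over a below-threshold bit pattern
perfusion_oracle_all_masks <- function(excluded = c(2L, 3L)) {
  edges <- which(stagedcad::aha17_adjacency(), arr.ind = TRUE)
  edges <- edges[edges[, 1L] < edges[, 2L], , drop = FALSE]
  keep <- !(edges[, 1L] %in% excluded) & !(edges[, 2L] %in% excluded)
  edges <- edges[keep, , drop = FALSE]
  masks <- 0:(2^17 - 1)
  res <- rep(FALSE, length(masks))
  for (e in seq_len(nrow(edges))) {
    bi <- bitwShiftL(1L, edges[e, 1L] - 1L)
    bj <- bitwShiftL(1L, edges[e, 2L] - 1L)
    res <- res | (bitwAnd(masks, bi) > 0L & bitwAnd(masks, bj) > 0L)
  }
  res
}

mask_to_mbf <- function(mask, low = 2.0, high = 3.0) {
  ifelse(bitwAnd(mask, bitwShiftL(1L, 0:16)) > 0L, low, high)
}
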