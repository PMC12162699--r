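test_that("subgroup Youden search matches hand-enumerable 6-patient case", {
  # subgroup {pav, label}: controls 3, 8, 14; cases 10, 18, 25.
  co <- data.frame(stenosis = rep(50, 6),
                   pav = c(3, 8, 10, 14, 18, 25),
                   ischemia = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  # independent brute force over the full 0.1-step candidate grid, in exact
  # integer arithmetic (scaled objective tp * n_ctrl - fp * n_case)
  grid <- default_pav_grid()
  js <- vapply(grid, function(t) {
    pred <- co$pav >= t
    sum(pred & co$ischemia) * 3 - sum(pred & !co$ischemia) * 3
  }, numeric(1))
  expect_equal(max(js) / 9, 2 / 3)
  res <- youden_threshold_subgroup(co, 0, 100)
  expect_equal(res$j, 2 / 3)
  # both the 10.0 plateau and the (14.1 .. 18.0] plateau attain J = 2/3;
  # the sensitivity-first tie-break selects 10.0, not 18.0
  expect_equal(res$threshold, 10.0)
  expect_true(18.0 %in% res$ties)
  expect_setequal(res$ties, grid[js == max(js)])
})

test_that("perfect separation: tie-break returns the largest separating cut", {
  co <- data.frame(stenosis = rep(60, 8),
                   pav = c(rep(5, 4), rep(20, 4)),
                   ischemia = c(rep(FALSE, 4), rep(TRUE, 4)))
  res <- youden_threshold_subgroup(co, 0, 100)
  expect_equal(res$j, 1)
  expect_equal(res$threshold, 20.0)   # largest candidate in (5, 20]
})

test_that("single candidate threshold is returned regardless of J", {
  co <- random_toy_cohort(30)
  res <- youden_threshold_subgroup(co, 0, 100, candidate_thresholds = 7.5)
  expect_equal(res$threshold, 7.5)
})

test_that("subgroup errors name the missing label class", {
  co <- data.frame(stenosis = c(10, 20, 60, 70),
                   pav = c(1, 2, 10, 20),
                   ischemia = c(FALSE, FALSE, TRUE, TRUE))
  expect_error(youden_threshold_subgroup(co, 0, 30), "reference-positive")
  expect_error(youden_threshold_subgroup(co, 55, 100), "reference-negative")
  expect_error(youden_threshold_subgroup(co, 90, 100), "empty")
})

test_that("grid search equals brute-force enumeration on toy cohorts", {
  set.seed(606)
  for (rep in 1:20) {
    co <- random_toy_cohort(sample(12:50, 1))
    if (!any(co$ischemia) || all(co$ischemia)) next
    spec <- grid_spec(sort(sample(1:99, 4)), sort(sample(1:99, 4)),
                      sort(sample(default_pav_grid(), 4)))
    fast <- grid_search_staged(co, spec)
    slow <- naive_grid_search(co, spec)
    expect_equal(fast$best_j, slow$best_j)
    expect_equal(sort_rules(fast$ties), sort_rules(slow$ties))
  }
})

test_that("grid search counts the advertised number of rules", {
  res_default_count <- local({
    spec <- grid_spec()
    # 99 * 100 / 2 band pairs times 490 thresholds
    co <- data.frame(stenosis = c(10, 60, 80, 20), pav = c(1, 20, 9, 3),
                     ischemia = c(FALSE, TRUE, TRUE, FALSE))
    grid_search_staged(co, spec)$grid_evaluated
  })
  expect_equal(res_default_count, 99 * 100 / 2 * 490)
})

test_that("binned evaluation is lossless for on-grid inputs", {
  set.seed(31)
  co <- data.frame(stenosis = sample(0:100, 40, replace = TRUE),
                   pav = sample(0:490, 40, replace = TRUE) / 10,
                   ischemia = runif(40) < 0.4)
  spec <- grid_spec(c(20, 45, 70), c(30, 60, 90), c(2.0, 7.7, 12.2, 16.8))
  fast <- grid_search_staged(co, spec)
  slow <- naive_grid_search(co, spec)
  expect_equal(fast$best_j, slow$best_j)
  expect_equal(sort_rules(fast$ties), sort_rules(slow$ties))
  # and the best rule's J re-derives from its confusion matrix
  expect_equal(fast$best_j, youden_j(fast$best_cm))
  cm <- evaluate_rule(co, fast$best_rule)
  expect_identical(unlist(cm), unlist(fast$best_cm))
})

test_that("search is deterministic and its objective dominates Model 1", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 17))
  spec <- grid_spec(seq(5, 95, 5), seq(5, 95, 5), seq(0.5, 30, 0.5))
  r1 <- grid_search_staged(co, spec)
  r2 <- grid_search_staged(co, spec)
  expect_identical(r1$ties, r2$ties)
  expect_identical(unlist(r1$best_cm), unlist(r2$best_cm))
  expect_true(r1$best_j >= -1 && r1$best_j <= 1)
  # the space contains a near-equivalent of the binary 50% rule
  j50 <- youden_j(evaluate_rule(co, staged_rule(50, 50, 0.5)))
  expect_gte(r1$best_j, j50)
})

test_that("refit on a fixed band is idempotent and recovers planted truth", {
  planted <- staged_rule(30, 70, 12.0)
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 23,
                                         label_mode = "planted",
                                         planted_rule = planted,
                                         planted_flip_prob = 0))
  rule <- refit_threshold_for_band(co, 30, 70, label = "latent_ischemia")
  expect_equal(rule$lower, 30); expect_equal(rule$upper, 70)
  expect_lte(abs(rule$pav_threshold - 12.0), 0.1)  # within one grid step
  # idempotence: refitting the band of a subgroup optimum returns it
  fit <- youden_threshold_subgroup(co, 30, 70, label = "latent_ischemia")
  rule2 <- refit_threshold_for_band(co, 30, 70, label = "latent_ischemia")
  expect_equal(rule2$pav_threshold, fit$threshold)
  # band (0, 100) is the global 1-D search
  g1 <- youden_threshold_subgroup(co, 0, 100, label = "latent_ischemia")
  g2 <- local({
    y <- co$latent_ischemia
    grid <- default_pav_grid()
    js <- vapply(grid, function(t)
      sum(co$pav >= t & y) * sum(!y) - sum(co$pav >= t & !y) * sum(y),
      numeric(1))
    max(js) / (sum(y) * sum(!y))
  })
  expect_equal(g1$j, g2)
})

test_that("grid_spec validation", {
  expect_error(grid_spec(lower_values = numeric(0)), "lower_values")
  expect_error(grid_spec(pav_values = c(1, NA)), "pav_values")
  expect_error(grid_spec(upper_values = 150), "upper_values")
  expect_identical(length(grid_spec()$pav_values), 490L)
  expect_identical(length(grid_spec()$lower_values), 99L)
})
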