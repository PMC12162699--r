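test_that("Wilson interval matches the quadratic-root closed form", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    got <- wilson_interval(x, n)
    want <- wilson_by_roots(x, n)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
  # symmetric case, checked to tight tolerance against the closed form
  expect_equal(unname(wilson_interval(5, 10)), wilson_by_roots(5, 10),
               tolerance = 1e-12)
})

test_that("Wilson boundary behaviour and validation", {
  ci <- wilson_interval(0, 10)
  expect_identical(ci[["lower"]], 0)
  expect_gt(ci[["upper"]], 0)
  ci <- wilson_interval(10, 10)
  expect_identical(ci[["upper"]], 1)
  expect_error(wilson_interval(3, 0), "trials")
  expect_error(wilson_interval(11, 10), "successes")
})

test_that("Wilson CI width shrinks as n doubles at fixed proportion", {
  widths <- vapply(c(20, 40, 80, 160, 320), function(n) {
    ci <- wilson_interval(round(0.3 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("diagnostic report satisfies the exact identities", {
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(0:200, 4, replace = TRUE) + c(1, 0, 1, 0)
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    r <- metrics_from_cm(cm)
    expect_equal(r$youden_j,
                 r$sensitivity[["estimate"]] + r$specificity[["estimate"]] - 1)
    expect_equal(r$auc[["estimate"]],
                 (r$sensitivity[["estimate"]] + r$specificity[["estimate"]]) / 2)
    # accuracy = prevalence * Se + (1 - prevalence) * Sp
    expect_equal(r$accuracy[["estimate"]],
                 r$prevalence * r$sensitivity[["estimate"]] +
                   (1 - r$prevalence) * r$specificity[["estimate"]])
    # two-point ROC trapezoid oracle: (0,0), (1-Sp, Se), (1,1)
    fpr <- 1 - r$specificity[["estimate"]]; tpr <- r$sensitivity[["estimate"]]
    trap <- fpr * tpr / 2 + (1 - fpr) * (tpr + 1) / 2
    expect_equal(r$auc[["estimate"]], trap)
    # each CI contains its point estimate
    for (m in list(r$sensitivity, r$specificity, r$ppv, r$npv, r$accuracy, r$auc))
      if (!is.na(m[["estimate"]])) {
        expect_lte(m[["lower"]], m[["estimate"]])
        expect_gte(m[["estimate"]], m[["lower"]])
        expect_lte(m[["estimate"]], m[["upper"]])
      }
  }
})

test_that("perfect and degenerate classifiers", {
  r <- metrics_from_cm(confusion_matrix(10, 0, 0, 10))
  expect_equal(r$sensitivity[["estimate"]], 1)
  expect_equal(r$specificity[["estimate"]], 1)
  expect_equal(r$ppv[["estimate"]], 1)
  expect_equal(r$npv[["estimate"]], 1)
  expect_equal(r$accuracy[["estimate"]], 1)
  expect_equal(r$auc[["estimate"]], 1)
  expect_equal(r$youden_j, 1)
  # nobody classified positive: PPV undefined, everything else returned
  r2 <- metrics_from_cm(confusion_matrix(0, 0, 5, 15))
  expect_true(is.na(r2$ppv[["estimate"]]))
  expect_identical(r2$undefined, "ppv")
  expect_equal(r2$specificity[["estimate"]], 1)
  expect_error(metrics_from_cm(confusion_matrix(0, 5, 0, 15)), "classes")
})

test_that("fixture matrices reproduce the published rounded metrics", {
  fx <- load_fixture_matrices()
  r1 <- metrics_from_cm(fx$model1)
  pct <- function(m) floor(m * 100 + 0.5)
  expect_equal(pct(r1$sensitivity[["estimate"]]), 75)
  expect_equal(pct(r1$specificity[["estimate"]]), 88)
  expect_equal(pct(r1$ppv[["estimate"]]), 57)
  expect_equal(pct(r1$npv[["estimate"]]), 94)
  expect_equal(pct(r1$accuracy[["estimate"]]), 86)
  expect_equal(floor(abs(r1$auc[["estimate"]]) * 100 + 0.5) / 100, 0.81)
  # sensitivity CI prints as 70-79
  expect_equal(pct(r1$sensitivity[["lower"]]), 70)
  expect_equal(pct(r1$sensitivity[["upper"]]), 79)
  r2 <- metrics_from_cm(fx$model2)
  expect_equal(pct(r2$sensitivity[["estimate"]]), 41)
  expect_equal(pct(r2$specificity[["estimate"]]), 97)
})
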