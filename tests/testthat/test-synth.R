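test_that("generator config validation names the offending field", {
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(visual_referral_cutoff = 0),
               "visual_referral_cutoff")
  expect_error(generator_config(visual_referral_cutoff = 100),
               "visual_referral_cutoff")
  expect_error(generator_config(
    stenosis_dist = list(minimal_fraction = 1.2, minimal_max = 10,
                         location = 42, scale = 25)),
    "minimal_fraction")
  expect_error(generator_config(
    pav_link = list(intercept = 0, slope = 0.04, noise_sd = -1)),
    "noise_sd")
  expect_error(generator_config(label_mode = "planted"), "planted_rule")
})

test_that("cohorts are reproducible and order-independent by record", {
  cfg <- generator_config(n_patients = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # the first i records do not depend on n
  cfg2 <- generator_config(n_patients = 120, seed = 42)
  expect_identical(generate_cohort(cfg2), a[1:120, ])
})

test_that("composite label structure holds in every generated cohort", {
  for (seed in c(1, 7, 99)) {
    co <- generate_cohort(generator_config(n_patients = 400, seed = seed))
    expect_true(all(!co$ischemia | co$pet_performed))       # isch => PET
    expect_identical(co$ischemia, co$latent_ischemia & co$pet_performed)
    expect_true(all(co$stenosis >= 0 & co$stenosis <= 100))
    expect_true(all(co$pav >= 0 & co$pav <= 100))
    expect_equal(co$ncpv + co$cpv, co$pav, tolerance = 1e-12)
    expect_true(all(co$ncpv >= 0 & co$cpv >= 0))
  }
})

test_that("degenerate ischemia coefficients give an all-negative cohort", {
  cfg <- generator_config(n_patients = 200, seed = 5,
                          ischemia_coef = c(-Inf, 0, 0))
  co <- generate_cohort(cfg)
  expect_false(any(co$latent_ischemia))
  expect_false(any(co$ischemia))
})

test_that("without visual noise or bias, referral equals stenosis >= cutoff", {
  cfg <- generator_config(n_patients = 500, seed = 8,
                          visual_noise_sd = 0, visual_bias = 0,
                          visual_referral_cutoff = 50)
  co <- generate_cohort(cfg)
  expect_identical(co$pet_performed, co$stenosis >= 50)
})

test_that("referral fraction is monotone non-increasing in the cutoff", {
  cuts <- c(30, 40, 50, 60, 70)
  fr <- vapply(cuts, function(ct) {
    co <- generate_cohort(generator_config(n_patients = 1000, seed = 21,
                                           visual_referral_cutoff = ct))
    mean(co$pet_performed)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("stenosis and PAV are strongly positively correlated (default link)", {
  co <- generate_cohort(generator_config(n_patients = 20000, seed = 123))
  expect_gt(cor(co$stenosis, co$pav, method = "spearman"), 0.5)
})

test_that("default world matches the stated registry rates", {
  co <- generate_cohort(generator_config(n_patients = 50000, seed = 2))
  expect_equal(mean(co$ischemia), 0.17, tolerance = 0.15)        # ~17%
  expect_equal(mean(co$pet_performed), 0.36, tolerance = 0.15)   # ~36%
  expect_equal(mean(co$stenosis >= 50), 0.23, tolerance = 0.15)  # ~23%
})

test_that("compute_pav normalizes plaque to vessel volume", {
  expect_identical(compute_pav(0, 1000), 0)
  expect_identical(compute_pav(1000, 1000), 100)
  expect_equal(compute_pav(157, 1000), 15.7)
  expect_error(compute_pav(10, 0), "vessel_volume")
  expect_error(compute_pav(10, -5), "vessel_volume")
  expect_error(compute_pav(1001, 1000), "total_plaque_volume")
})

test_that("packaged fixture matrices carry the published margins", {
  fx <- load_fixture_matrices()
  expect_named(fx, c("model1", "model2", "model3"))
  for (m in fx) {
    expect_s3_class(m, "confusion_matrix")
    expect_equal(m$tp + m$fp + m$fn + m$tn, 2145)
    expect_equal(m$tp + m$fn, 373)    # reference-positive column
    expect_equal(m$fp + m$tn, 1772)   # reference-negative column
  }
  expect_equal(fx$model2$tp + fx$model2$fp, 205)   # test-positive row
  expect_equal(fx$model3$fn + fx$model3$tn, 1696)  # test-negative row
})

test_that("cohort CSV round-trips through the interchange schema", {
  co <- generate_cohort(generator_config(n_patients = 50, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  header <- readLines(path, n = 1L)
  expect_identical(header,
    "\"patient_id\",\"stenosis_pct\",\"pav_pct\",\"ncpv_pct\",\"cpv_pct\",\"pet_performed\",\"ischemia\"")
  back <- read_cohort_csv(path)
  expect_equal(back$stenosis, co$stenosis, tolerance = 1e-9)
  expect_equal(back$pav, co$pav, tolerance = 1e-9)
  expect_identical(back$pet_performed, co$pet_performed)
  expect_identical(back$ischemia, co$ischemia)
  expect_false("latent_ischemia" %in% names(back))
})
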