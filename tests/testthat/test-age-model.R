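test_that("a single noise-free age-equal feature yields perfect predictions", {
  set.seed(1)
  tab <- tibble::tibble(id = as.character(1:40), group = "CUA-V-",
                        age = runif(40, 40, 80))
  tab$proxy <- tab$age
  model <- fit_age_model(tab, "proxy", folds = 5, seed = 2)
  expect_equal(model$cv$fold_mse, rep(0, 5), tolerance = 1e-16)
  cad <- predict_cad(model, tab)
  expect_equal(cad$y_hat_raw, tab$age, tolerance = 1e-8)
  expect_equal(cad$cad, rep(0, 40), tolerance = 1e-8)
})

test_that("full-sample coefficients equal the explicit normal-equation solution", {
  cohort <- generate_cohort(cohort_spec(seed = 6))
  cohort <- classify_cohort(cohort)
  feats <- default_feature_set()
  model <- fit_age_model(cohort, feats, folds = 5, seed = 1)
  ref <- cohort[cohort$group == "CUA-V-", ]
  Xs <- scale(as.matrix(ref[, feats]))
  hand <- normal_eq(Xs, ref$age)
  expect_equal(model$intercept, hand[1], tolerance = 1e-8)
  expect_equal(unname(model$coefficients), unname(hand[-1]), tolerance = 1e-8)
})

test_that("final coefficients are invariant to row order and fold seed", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 9)))
  feats <- default_feature_set()
  m1 <- fit_age_model(cohort, feats, seed = 1)
  shuffled <- cohort[sample.int(nrow(cohort)), ]
  m2 <- fit_age_model(shuffled, feats, seed = 1)
  m3 <- fit_age_model(cohort, feats, seed = 99)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  expect_equal(m1$coefficients, m3$coefficients, tolerance = 1e-12)
  # the bias line is fold-dependent, but only mildly
  expect_false(identical(m1$bias_line, m3$bias_line))
})

test_that("degenerate designs are refused with informative errors", {
  tab <- tiny_table(n = 30, noise_sd = 2, seed = 3)
  tab$f1_copy <- tab$f1
  expect_error(fit_age_model(tab, c("f1", "f2", "f1_copy")), "dependent column")
  expect_error(fit_age_model(tab[1:4, ], c("f1", "f2"), folds = 5), "folds")
  tab$flat <- 1
  expect_error(fit_age_model(tab, c("f1", "flat")), "constant feature")
})

test_that("bias-correction line recovers planted and null age trends", {
  set.seed(11)
  y <- runif(100, 40, 80)
  # null: deltas orthogonal to age by construction
  resid <- stats::residuals(stats::lm(rnorm(100) ~ y))
  line0 <- fit_bias_correction(y + resid, y)
  expect_equal(line0[["slope"]], 0, tolerance = 1e-10)
  # planted regression-to-the-mean slope of -0.5
  delta <- -0.5 * (y - mean(y))
  line <- fit_bias_correction(y + delta, y)
  expect_equal(line[["slope"]], -0.5, tolerance = 1e-10)
  expect_equal(line[["intercept"]], 0.5 * mean(y), tolerance = 1e-8)
  # after subtracting the fitted line, the corrected delta has no age slope
  corrected <- (y + delta) - (line[["slope"]] * y + line[["intercept"]]) - y
  expect_equal(unname(stats::coef(stats::lm(corrected ~ y))[2]), 0,
               tolerance = 1e-8)
  expect_error(fit_bias_correction(c(50, 51), c(50, 51)), "at least 3")
  expect_error(fit_bias_correction(rep(1, 5), rep(60, 5)), "zero variance")
})

test_that("out-of-fold deltas are exactly de-biased on the training sample", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 4)))
  model <- fit_age_model(cohort, default_feature_set(), seed = 3)
  oo <- oof_cad(model)
  expect_equal(nrow(oo), 140L)
  expect_lt(abs(mean(oo$cad)), 1e-8)
  expect_lt(abs(stats::coef(stats::lm(oo$cad ~ oo$y))[2]), 1e-8)
})

test_that("CAD is the corrected prediction minus chronological age", {
  model <- structure(
    list(feature_order = "f1",
         scaler = tibble::tibble(feature = "f1", mean = 0, sd = 1),
         coefficients = c(f1 = 0), intercept = 62,
         bias_method = "subtract", bias_line = c(slope = 0, intercept = 0),
         cv = list(folds = 5, seed = 1, fold_mse = rep(NA_real_, 5)),
         oof = NULL, fit_group = "CUA-V-", n_fit = 0L),
    class = "cognitive_age_model")
  tab <- tibble::tibble(id = c("a", "b"), age = c(60, 70), f1 = c(1, 2))
  cad <- predict_cad(model, tab)
  expect_equal(cad$y_hat_corrected, c(62, 62))
  expect_equal(cad$cad, c(2, -8))
})

test_that("rows missing a model feature are skipped and reported", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 2)))
  cohort <- inject_missingness(cohort, default_feature_set(), 2, seed = 5)
  model <- fit_age_model(cohort, default_feature_set())
  expect_message(cad <- predict_cad(model, cohort), "skipping 2")
  expect_equal(nrow(cad), 175L)
  expect_length(attr(cad, "skipped"), 2L)
})

test_that("prediction error vanishes as generator noise goes to zero", {
  # noise must stay positive: at exactly zero every education-corrected
  # feature is the same affine function of age and the design is singular
  fd <- default_feature_defs()
  fd$noise_sd <- 1e-4
  cohort <- classify_cohort(generate_cohort(
    cohort_spec(feature_defs = fd, covariate_defs = NULL, seed = 8)))
  # fit on raw scores: age lies in the feature span, so the regression
  # recovers it exactly as noise vanishes (education-corrected scores would
  # instead recover age minus its sample projection on education)
  model <- fit_age_model(cohort, fd$name)
  cad <- predict_cad(model, cohort)
  expect_lt(mean(abs(cad$y_hat_raw - cad$y)), 1e-2)
})

test_that("the inversion-style bias correction is available and consistent", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 10)))
  model <- fit_age_model(cohort, default_feature_set(), bias_method = "invert")
  oo <- oof_cad(model)
  # inverting the prediction-on-age line also removes the age trend
  expect_lt(abs(stats::coef(stats::lm(oo$cad ~ oo$y))[2]), 1e-8)
})

test_that("a model round-trips through JSON with identical predictions", {
  cohort <- classify_cohort(generate_cohort(cohort_spec(seed = 12)))
  model <- fit_age_model(cohort, default_feature_set())
  path <- withr::local_tempfile(fileext = ".json")
  write_age_model(model, path)
  back <- read_age_model(path)
  expect_equal(predict_cad(back, cohort)$cad, predict_cad(model, cohort)$cad,
               tolerance = 1e-12)
})
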