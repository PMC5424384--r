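test_that("ilr model recovers generating coefficients on synthetic data", {
  cfg <- synthetic_config(n = c(all = 500), group_means = cohort_reference$means["all", , drop = FALSE],
                          seed = 101)
  rec <- generate_records(cfg)
  fit <- fit_outcome_model(rec, "zbmi")
  est <- coef(fit)[fit$ilr_terms]
  se <- sqrt(diag(vcov(fit)))[fit$ilr_terms]
  truth <- cfg$outcomes$zbmi$beta
  expect_true(all(abs(est - truth) < 3 * se))
  # covariate effects too
  expect_lt(abs(coef(fit)[["sexgirl"]] - cfg$outcomes$zbmi$gamma[["sex_girl"]]),
            3 * sqrt(diag(vcov(fit)))[["sexgirl"]])
})

test_that("a constant outcome yields zero slopes", {
  rec <- quick_records(7)
  rec$zbmi <- 1.5
  fit <- fit_outcome_model(rec, "zbmi")
  expect_equal(max(abs(coef(fit)[-1])), 0, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), 1.5, tolerance = 1e-10)
})

test_that("fitted values, predictions and ANOVA are basis-invariant", {
  rec <- quick_records(19)
  f1 <- fit_outcome_model(rec, "zbmi", basis = default_basis())
  f2 <- fit_outcome_model(rec, "zbmi", basis = ilr_basis(alt_sbp_4()))
  expect_equal(fitted(f1$fit), fitted(f2$fit), tolerance = 1e-8)
  expect_equal(residuals(f1$fit), residuals(f2$fit), tolerance = 1e-8)
  a1 <- anova_marginality(f1); a2 <- anova_marginality(f2)
  expect_equal(a1$sum_sq, a2$sum_sq, tolerance = 1e-8)
  expect_equal(a1$f_value, a2$f_value, tolerance = 1e-8)
  comp <- c(sleep = 520, st = 530, lpa = 360, mvpa = 30)
  expect_equal(predict_outcome(f1, comp), predict_outcome(f2, comp),
               tolerance = 1e-8)
})

test_that("default-profile prediction at the training mean is the mean fitted value", {
  rec <- quick_records(23)
  fit <- fit_outcome_model(rec, "whtr_pct")
  cm <- comp_mean(fit$compositions, fit$kappa)
  expect_equal(predict_outcome(fit, cm), mean(fitted(fit$fit)), tolerance = 1e-8)
})

test_that("prediction differences do not depend on the covariate profile", {
  rec <- quick_records(29)
  fit <- fit_outcome_model(rec, "zbmi")
  c1 <- c(sleep = 540, st = 520, lpa = 350, mvpa = 30)
  c2 <- c(sleep = 560, st = 520, lpa = 340, mvpa = 20)
  p_default <- predict_outcome(fit, c1) - predict_outcome(fit, c2)
  pr1 <- list(sex = "girl", age = 9.5, imd_decile = "2")
  pr2 <- list(sex = "boy", age = 11, imd_decile = "1")
  d1 <- predict_outcome(fit, c1, pr1) - predict_outcome(fit, c2, pr1)
  d2 <- predict_outcome(fit, c1, pr2) - predict_outcome(fit, c2, pr2)
  expect_equal(d1, d2, tolerance = 1e-10)
  expect_equal(d1, p_default, tolerance = 1e-10)
  expect_error(predict_outcome(fit, c1, list(sex = "dog")), "unknown level")
})

test_that("degenerate designs and missing data are handled explicitly", {
  rec <- quick_records(31)
  rec$age_copy <- rec$age
  expect_error(fit_outcome_model(rec, "zbmi", c("sex", "age", "age_copy")),
               "collinear")
  rec2 <- quick_records(37)
  rec2$zbmi[1:6] <- NA
  expect_message(fit <- fit_outcome_model(rec2, "zbmi"), "dropped 6")
  expect_equal(fit$n, nrow(rec2) - 6L)
  expect_error(fit_outcome_model(rec2, "nope"), "outcome column")
  rec3 <- quick_records(41)
  rec3$imd_decile[2] <- 12
  expect_error(fit_outcome_model(rec3, "zbmi"), "1..10")
})

test_that("the fitness model accepts zBMI as an extra covariate", {
  rec <- quick_records(43)
  fit <- fit_outcome_model(rec, "vo2peak", c("sex", "age", "imd_decile", "zbmi"))
  expect_true("zbmi" %in% names(coef(fit)))
  # generated vo2peak really depends on zbmi, so the term should be strong
  an <- anova_marginality(fit)
  expect_lt(an$p_value[an$term == "zbmi"], 0.001)
})
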