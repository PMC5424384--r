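test_that("generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  expect_identical(generate_records(cfg), generate_records(cfg))
  x1 <- generate_compositions(cfg, "normal_weight")
  x2 <- generate_compositions(cfg, "normal_weight")
  expect_identical(x1, x2)
  cfg2 <- synthetic_config(seed = 8)
  expect_false(identical(generate_records(cfg), generate_records(cfg2)))
})

test_that("zero covariance collapses every sample onto the group mean", {
  cfg <- synthetic_config(seed = 7)
  cfg$ilr_cov <- matrix(0, 3, 3)
  x <- generate_compositions(cfg, "overweight_obese", n = 25)
  target <- close_comp(cfg$group_means["overweight_obese", ], 1440)
  expect_equal(x, matrix(target, 25, 4, byrow = TRUE,
                         dimnames = list(NULL, behaviour_parts)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("large samples reproduce the configured mean and dispersion", {
  cfg <- synthetic_config(seed = 977)
  x <- generate_compositions(cfg, "normal_weight", n = 10000)
  target <- close_comp(cfg$group_means["normal_weight", ], 1440)
  cm <- comp_mean(x, 1440)
  expect_true(all(abs(cm - target) / target < 0.01))

  vm <- variation_matrix(x)
  ref <- ilr_cov_to_variation(cfg$ilr_cov, cfg$basis)
  off <- upper.tri(ref)
  expect_true(all(abs(vm[off] - ref[off]) / ref[off] < 0.10))
  # and the configured dispersion is itself the published variation matrix
  expect_equal(ref, cohort_reference$variation, tolerance = 1e-9)
})

test_that("noiseless records identify the generating coefficients exactly", {
  cfg <- noiseless(synthetic_config(seed = 139))
  rec <- generate_records(cfg)
  for (oc in c("zbmi", "whtr_pct")) {
    fit <- fit_outcome_model(rec, oc)
    expect_equal(unname(coef(fit)[fit$ilr_terms]),
                 unname(cfg$outcomes[[oc]]$beta), tolerance = 1e-8)
    expect_equal(coef(fit)[["age"]], cfg$outcomes[[oc]]$gamma[["age"]],
                 tolerance = 1e-8)
  }
  # for the zbmi-adjusted fitness model, zbmi must keep its own noise:
  # a fully deterministic zbmi is collinear with the other regressors
  cfgv <- noiseless(synthetic_config(seed = 139))
  cfgv$outcomes$zbmi$sigma <- synthetic_config(seed = 139)$outcomes$zbmi$sigma
  recv <- generate_records(cfgv)
  fitv <- fit_outcome_model(recv, "vo2peak", c("sex", "age", "imd_decile", "zbmi"))
  expect_equal(unname(coef(fitv)[fitv$ilr_terms]),
               unname(cfg$outcomes$vo2peak$beta), tolerance = 1e-8)
  expect_equal(coef(fitv)[["zbmi"]], cfg$outcomes$vo2peak$gamma[["zbmi"]],
               tolerance = 1e-8)
})

test_that("end-to-end noiseless substitution equals beta' delta-ilr", {
  cfg <- noiseless(synthetic_config(seed = 149))
  rec <- generate_records(cfg)
  fit <- fit_outcome_model(rec, "zbmi")
  base <- ref_mean_all()
  for (t in c(5, 15, 25)) {
    d <- predicted_difference(fit, base, "mvpa", "st", t)$difference
    dz <- as.numeric(ilr_coords(reallocate(base, "mvpa", "st", t), cfg$basis)) -
      as.numeric(ilr_coords(base, cfg$basis))
    expect_equal(d, sum(cfg$outcomes$zbmi$beta * dz), tolerance = 1e-8)
  }
})

test_that("synthetic cohorts reproduce the published substitution pattern", {
  cfg <- synthetic_config(seed = 151)
  rec <- generate_records(cfg)
  fit <- fit_outcome_model(rec, "zbmi")
  m <- substitution_matrix(fit, ref_mean_all(), minutes = 15)
  # moving time out of MVPA raises predicted zBMI; into MVPA lowers it
  expect_true(all(m[c("sleep", "st", "lpa"), "mvpa"] > 0))
  expect_true(all(m["mvpa", c("sleep", "st", "lpa")] < 0))
  # asymmetry: losses exceed the mirror-image gains
  expect_true(all(m[c("sleep", "st", "lpa"), "mvpa"] >
                    abs(m["mvpa", c("sleep", "st", "lpa")])))
})

test_that("fixtures are byte-stable, readable, and sized as configured", {
  cfg <- synthetic_config(seed = 20170510)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  expect_identical(readLines(p1[["data"]]), readLines(p2[["data"]]))
  expect_identical(readLines(p1[["truth"]]), readLines(p2[["truth"]]))

  rec <- read_records(p1[["data"]])
  orig <- generate_records(cfg)
  expect_equal(nrow(rec), sum(cfg$n))
  expect_equal(rec$sleep_min, orig$sleep_min, tolerance = 1e-12)
  expect_equal(table(rec$weight_status),
               table(orig$weight_status))
  expect_equal(unname(table(orig$weight_status)[c("underweight", "normal_weight", "overweight_obese")]),
               c(15L, 115L, 39L), ignore_attr = TRUE)

  truth <- jsonlite::read_json(p1[["truth"]])
  expect_equal(truth$seed, 20170510)
  expect_length(truth$outcomes$zbmi$beta, 3)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(ilr_cov = matrix(c(1, 2, 2, 1, 1, 1, 2, 1, -3), 3, 3)),
               "positive semidefinite")
  cv <- list(prop_girls = .5, age_mean = 10.3, age_sd = .3,
             imd_probs = rep(0.2, 10), height_mean = 141, height_sd = 6)
  expect_error(synthetic_config(covariates = cv), "sum to 1")
})
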