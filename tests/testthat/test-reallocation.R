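test_that("reallocation moves exactly the requested minutes", {
  base <- c(sleep = 548.6, st = 510.3, lpa = 354.8, mvpa = 26.4)
  r <- reallocate(base, from = "sleep", to = "mvpa", minutes = 10)
  expect_equal(unname(r), c(538.6, 510.3, 354.8, 36.4))
  expect_identical(r[["st"]], base[["st"]])   # untouched parts bit-identical
  expect_identical(r[["lpa"]], base[["lpa"]])
  expect_equal(sum(r), sum(base), tolerance = 1e-9)

  expect_equal(reallocate(base, "st", "lpa", 0), base)
  expect_error(reallocate(base, "mvpa", "st", 26.4), "26.4")
  expect_error(reallocate(base, "mvpa", "st", 30), "mvpa")
  expect_error(reallocate(base, "st", "st", 5), "differ")
  expect_error(reallocate(base, "nap", "st", 5), "unknown part")
  expect_error(reallocate(base, "st", "lpa", -1), "nonnegative")
})

test_that("predicted differences are zero at zero minutes and asymmetric otherwise", {
  rec <- quick_records(103)
  fit <- fit_outcome_model(rec, "zbmi")
  base <- comp_mean(fit$compositions)
  expect_identical(predicted_difference(fit, base, "st", "mvpa", 0)$difference, 0)

  fwd <- predicted_difference(fit, base, "mvpa", "st", 15)$difference
  bwd <- predicted_difference(fit, base, "st", "mvpa", 15)$difference
  expect_gt(abs(fwd) - abs(bwd), 0.05)   # taking MVPA away hurts more
  expect_true(fwd > 0 && bwd < 0)
})

test_that("small-duration differences match a finite-difference derivative", {
  rec <- quick_records(107)
  fit <- fit_outcome_model(rec, "vo2peak")
  base <- comp_mean(fit$compositions)
  beta <- coef(fit)[fit$ilr_terms]
  h <- 1e-5
  for (pair in list(c("mvpa", "st"), c("sleep", "lpa"), c("st", "mvpa"))) {
    # directional derivative of the linear predictor along the reallocation
    z0 <- as.numeric(ilr_coords(base, fit$basis))
    zh <- as.numeric(ilr_coords(reallocate(base, pair[1], pair[2], h), fit$basis))
    deriv <- sum(beta * (zh - z0)) / h
    t_small <- 0.01
    d <- predicted_difference(fit, base, pair[1], pair[2], t_small)$difference
    expect_equal(d / t_small, deriv, tolerance = 1e-3)
  }
})

test_that("difference grids: zero column, feasibility marking, basis invariance", {
  rec <- quick_records(109)
  fit <- fit_outcome_model(rec, "zbmi")

  g0 <- difference_grid(fit, durations = 0)
  expect_true(all(g0$difference == 0))
  expect_true(all(g0$feasible))

  # baseline with tiny MVPA: donations beyond it are flagged, not errors
  tiny <- c(sleep = 600, st = 500, lpa = 330, mvpa = 10)
  g <- difference_grid(fit, tiny, durations = c(0, 5, 15))
  bad <- g[g$from == "mvpa" & g$minutes == 15, ]
  expect_true(all(!bad$feasible))
  expect_true(all(is.na(bad$difference)))
  expect_true(all(g$feasible[g$from != "mvpa"]))
  expect_equal(nrow(g), 12 * 3)   # full grid always produced

  f2 <- fit_outcome_model(rec, "zbmi", basis = ilr_basis(alt_sbp_4()))
  g1 <- difference_grid(fit, durations = seq(0, 25, 5))
  g2 <- difference_grid(f2, durations = seq(0, 25, 5))
  expect_equal(g1$difference, g2$difference, tolerance = 1e-8)
  expect_equal(g1$se, g2$se, tolerance = 1e-8)
})

test_that("substitution matrix is oriented rows-receive, columns-donate", {
  rec <- quick_records(113)
  fit <- fit_outcome_model(rec, "zbmi")
  base <- comp_mean(fit$compositions)
  m <- substitution_matrix(fit, base, minutes = 15)
  expect_equal(m["st", "mvpa"],
               predicted_difference(fit, base, "mvpa", "st", 15)$difference)
  expect_true(all(is.na(diag(m))))
  expect_equal(dim(m), c(4, 4))
})

test_that("delta-method intervals are coherent and profile-free", {
  rec <- quick_records(127)
  fit <- fit_outcome_model(rec, "whtr_pct")
  base <- comp_mean(fit$compositions)
  d <- predicted_difference(fit, base, "mvpa", "st", 15, conf_level = 0.95)
  expect_lt(d$lower, d$difference)
  expect_gt(d$upper, d$difference)
  expect_gt(d$se, 0)
  d99 <- predicted_difference(fit, base, "mvpa", "st", 15, conf_level = 0.99)
  expect_lt(d99$lower, d$lower)
})

test_that("group grids share the model but differ through their baselines", {
  cfg <- synthetic_config(seed = 131)
  rec <- generate_records(cfg)
  fit <- fit_outcome_model(rec, "zbmi")
  gg <- group_baseline_grids(fit, rec, durations = c(0, 15))
  expect_named(gg, c("normal_weight", "overweight_obese", "underweight"))
  b_norm <- attr(gg$normal_weight, "baseline")
  b_over <- attr(gg$overweight_obese, "baseline")
  expect_gt(max(abs(b_norm - b_over)), 1)   # baselines genuinely differ
  d_norm <- gg$normal_weight
  d_over <- gg$overweight_obese
  i <- which(d_norm$from == "mvpa" & d_norm$to == "st" & d_norm$minutes == 15)
  expect_false(isTRUE(all.equal(d_norm$difference[i], d_over$difference[i])))

  # a grouping with a single group reproduces the full-sample grid
  rec1 <- rec; rec1$weight_status <- "all"
  g1 <- group_baseline_grids(fit, rec1, durations = c(0, 15))$all
  gfull <- difference_grid(fit, durations = c(0, 15))
  expect_equal(g1$difference, gfull$difference, tolerance = 1e-10)

  expect_error(group_baseline_grids(fit, rec, group_col = "postcode"), "not found")
})
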