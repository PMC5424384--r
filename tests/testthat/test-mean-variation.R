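test_that("compositional mean equals closed per-part geometric means", {
  # hand-computed: gmean(1,4)=2, gmean(2,2)=2, gmean(4,1)=2, gmean(8,8)=8,
  # which sum to 14 and are then closed to kappa = 15
  m <- rbind(c(1, 2, 4, 8), c(4, 2, 1, 8))
  expect_equal(unname(comp_mean(m, kappa = 15)), c(2, 2, 2, 8) * 15 / 14,
               tolerance = 1e-12, ignore_attr = TRUE)

  # all samples identical -> that composition
  one <- close_comp(c(a = 500, b = 600, c = 300, d = 40), 1440)
  expect_equal(comp_mean(rbind(one, one, one), 1440), one, tolerance = 1e-12,
               ignore_attr = TRUE)

  # ilr-mean route agrees with the geometric-mean route for any basis
  set.seed(21)
  x <- random_comps(50, parts = behaviour_parts)
  for (b in list(default_basis(), ilr_basis(alt_sbp_4()))) {
    via_ilr <- ilr_inverse(colMeans(ilr_coords(x, b)), b, kappa = 1440)
    expect_equal(as.numeric(via_ilr), unname(comp_mean(x, 1440)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(comp_mean(matrix(numeric(0), 0, 4)), "at least one")
})

test_that("variation matrix matches the brute-force pairwise oracle", {
  hand <- rbind(c(540, 520, 350, 30),
                c(600, 480, 330, 30),
                c(500, 560, 360, 20))
  colnames(hand) <- behaviour_parts
  vm <- variation_matrix(hand)
  expect_equal(vm, variation_oracle(hand), tolerance = 1e-12)

  # spot-check one entry fully by hand
  lr <- log(hand[, "st"] / hand[, "mvpa"])
  expect_equal(vm["st", "mvpa"], sum((lr - mean(lr))^2) / 2, tolerance = 1e-12)

  set.seed(31)
  x <- random_comps(40, parts = behaviour_parts)
  expect_equal(variation_matrix(x), variation_oracle(x), tolerance = 1e-10)
})

test_that("variation matrix invariances: closure, perturbation, permutation", {
  set.seed(33)
  x <- random_comps(30, parts = behaviour_parts)
  vm <- variation_matrix(x)
  expect_equal(vm, t(vm))
  expect_equal(unname(diag(vm)), rep(0, 4))
  expect_true(all(vm >= 0))

  # identical samples -> all-zero matrix
  expect_equal(max(abs(variation_matrix(x[c(1, 1, 1), ]))), 0)

  # closure invariance
  expect_equal(variation_matrix(close_comp(x, 1440)), vm, tolerance = 1e-10)

  # perturbation invariance: multiply all samples by a fixed composition
  pert <- c(sleep = 2, st = 0.5, lpa = 3, mvpa = 0.1)
  xp <- sweep(x, 2, pert, `*`)
  expect_equal(variation_matrix(xp), vm, tolerance = 1e-10)

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(variation_matrix(x[, perm]), vm[perm, perm], tolerance = 1e-12)

  expect_error(variation_matrix(x[1, , drop = FALSE]), "at least 2")
})

test_that("variation <-> log-ratio covariance conversions round-trip", {
  # zero matrix -> zero covariance
  z4 <- matrix(0, 4, 4, dimnames = list(behaviour_parts, behaviour_parts))
  expect_equal(max(abs(variation_to_clr_cov(z4))), 0)
  expect_equal(max(abs(variation_to_ilr_cov(z4))), 0)

  # the published dispersion summary round-trips exactly
  vm_ref <- cohort_reference$variation
  for (b in list(default_basis(), ilr_basis(alt_sbp_4()))) {
    S <- variation_to_ilr_cov(vm_ref, b)
    expect_equal(ilr_cov_to_variation(S, b), vm_ref, tolerance = 1e-9)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-12)
  }

  # a variation matrix estimated from simulated data round-trips too
  set.seed(41)
  x <- random_comps(200, parts = behaviour_parts)
  vm <- variation_matrix(x)
  S <- variation_to_ilr_cov(vm)
  expect_equal(ilr_cov_to_variation(S, default_basis()), vm, tolerance = 1e-9)

  bad <- vm_ref; bad[1, 2] <- bad[1, 2] + 1
  expect_error(variation_to_clr_cov(bad), "symmetric")
  bad2 <- vm_ref; diag(bad2) <- 1
  expect_error(variation_to_clr_cov(bad2), "diagonal")
  bad3 <- vm_ref; bad3[1, 2] <- bad3[2, 1] <- -0.1
  expect_error(variation_to_clr_cov(bad3), "nonnegative")
})
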