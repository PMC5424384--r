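# Shared fixtures and independent oracles for the test suite.

# clr-projection oracle for ilr coordinates: centre the log vector, then
# project onto the contrast matrix. Independent of ilr_coords(), which
# multiplies the raw log vector by t(V).
clr_oracle <- function(x) log(x) - mean(log(x))
ilr_oracle <- function(x, basis) as.numeric(crossprod(basis$V, clr_oracle(x)))

# Brute-force variation matrix: loop over all ordered pairs, var() each
# log-ratio directly.
variation_oracle <- function(m) {
  D <- ncol(m)
  out <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(D)) for (j in seq_len(D)) if (i != j)
    out[i, j] <- var(log(m[, i] / m[, j]))
  out
}

# Random strictly positive compositions (rows), log-normal parts.
random_comps <- function(n, D = 4, parts = NULL) {
  m <- matrix(exp(rnorm(n * D, sd = 0.7)), n, D)
  colnames(m) <- if (is.null(parts)) paste0("p", seq_len(D)) else parts
  m
}

# A second, structurally different SBP for the four behaviours:
# step 1 separates (sleep, st) from (lpa, mvpa), then splits each pair.
alt_sbp_4 <- function(parts = behaviour_parts) {
  S <- matrix(c(
     1,  1,  0,
     1, -1,  0,
    -1,  0,  1,
    -1,  0, -1
  ), nrow = 4, byrow = TRUE, dimnames = list(parts, paste0("b", 1:3)))
  S
}

# Small calibrated synthetic cohort for model tests; seed controlled by the
# caller so different tests get independent draws.
quick_records <- function(seed, n = NULL) {
  cfg <- if (is.null(n)) synthetic_config(seed = seed) else
    synthetic_config(n = n, seed = seed)
  generate_records(cfg)
}

# Noiseless copy of a config: outcomes become deterministic functions of the
# composition and covariates.
noiseless <- function(cfg) {
  for (o in names(cfg$outcomes)) cfg$outcomes[[o]]$sigma <- 0
  cfg
}

ref_mean_all <- function() close_comp(cohort_reference$means["all", ], 1440)
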