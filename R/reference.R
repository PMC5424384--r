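#' Behaviour part labels
#'
#' Canonical order of the four daily movement behaviours: sleep, sedentary
#' time (st), light physical activity (lpa) and moderate-to-vigorous physical
#' activity (mvpa). All defaults in the package use this order.
#' @export
behaviour_parts <- c("sleep", "st", "lpa", "mvpa")

#' Published cohort reference values
#'
#' Summary statistics reported for a cross-sectional cohort of 169 English
#' children aged 9-10 years (215 consented; 169 with valid 24-h accelerometer
#' data) whose daily movement behaviours were analysed compositionally. These
#' values calibrate the synthetic data generator ([synthetic_config()]) and
#' serve as fixed points for internal-consistency checks; they are inputs to
#' this package, not estimates it produces.
#'
#' A list with elements:
#' \describe{
#'   \item{parts}{behaviour labels, in order.}
#'   \item{kappa}{closure constant, 1440 min.}
#'   \item{n_consented, n_analysed}{cohort accounting (215 and 169).}
#'   \item{group_sizes}{named sizes of the weight-status groups.}
#'   \item{means}{compositional means (min/day, closed to 1440) for the full
#'     sample and each weight-status group; a 4 x 4 matrix, rows = samples.}
#'   \item{variation}{full-sample pairwise log-ratio variation matrix.}
#'   \item{covariates}{age mean/sd (years), proportion girls, IMD decile
#'     mean/sd, height and waist means/sds (cm).}
#'   \item{outcomes}{mean and sd of zBMI, \%WHtR and VO2 peak
#'     (ml.kg.min^-1).}
#'   \item{substitution_15min}{published predicted outcome differences for
#'     15-min pairwise reallocations (rows receive time, columns donate it),
#'     per outcome and per baseline composition. zBMI to 2 dp, \%WHtR and VO2
#'     peak to 1 dp. The VO2 peak model is additionally adjusted for zBMI.}
#' }
#' @export
cohort_reference <- local({
  parts <- c("sleep", "st", "lpa", "mvpa")
  groups <- c("all", "underweight", "normal_weight", "overweight_obese")

  means <- matrix(c(
    548.6, 510.3, 354.8, 26.4,
    546.0, 488.1, 370.9, 35.0,
    545.6, 509.3, 356.2, 28.9,
    557.1, 520.9, 343.9, 18.1
  ), nrow = 4, byrow = TRUE, dimnames = list(groups, parts))

  variation <- matrix(c(
    0,     0.030, 0.036, 0.281,
    0.030, 0,     0.079, 0.442,
    0.036, 0.079, 0,     0.235,
    0.281, 0.442, 0.235, 0
  ), nrow = 4, byrow = TRUE, dimnames = list(parts, parts))

  # rows receive, columns donate; diagonal NA
  sub_mat <- function(v) {
    m <- matrix(NA_real_, 4, 4, dimnames = list(parts, parts))
    m[upper.tri(m) | lower.tri(m)] <- 0  # placeholder
    k <- 1L
    for (i in 1:4) for (j in 1:4) if (i != j) { m[i, j] <- v[k]; k <- k + 1L }
    m
  }
  # per row (receiver): donors in part order, skipping the diagonal
  substitution_15min <- list(
    all = list(
      zbmi     = sub_mat(c( 0.05, -0.01,  0.88,  -0.05, -0.06,  0.83,
                            0.01,  0.06,  0.89,  -0.48, -0.43, -0.49)),
      whtr_pct = sub_mat(c( 0.1,  -0.4,   5.1,   -0.1,  -0.5,   5.0,
                            0.3,   0.4,   5.5,   -2.8,  -2.7,  -3.1)),
      vo2peak  = sub_mat(c( 0.0,   0.0,  -2.4,    0.0,   0.0,  -2.4,
                            0.0,   0.0,  -2.4,    1.3,   1.3,   1.3))
    ),
    underweight = list(
      zbmi     = sub_mat(c( 0.05, -0.01,  0.59,  -0.05, -0.06,  0.54,
                            0.01,  0.06,  0.60,  -0.39, -0.33, -0.40)),
      whtr_pct = sub_mat(c( 0.1,  -0.3,   3.4,   -0.1,  -0.4,   3.3,
                            0.3,   0.4,   3.7,   -2.2,  -2.1,  -2.5)),
      vo2peak  = sub_mat(c( 0.0,   0.0,  -1.6,    0.0,   0.0,  -1.6,
                            0.0,   0.0,  -1.6,    1.1,   1.1,   1.0))
    ),
    normal_weight = list(
      zbmi     = sub_mat(c( 0.05, -0.01,  0.77,  -0.05, -0.06,  0.72,
                            0.01,  0.06,  0.78,  -0.45, -0.40, -0.46)),
      whtr_pct = sub_mat(c( 0.1,  -0.4,   4.5,   -0.1,  -0.5,   4.4,
                            0.3,   0.4,   4.8,   -2.6,  -2.5,  -2.9)),
      vo2peak  = sub_mat(c( 0.0,   0.0,  -2.1,    0.0,   0.0,  -2.1,
                            0.0,   0.0,  -2.1,    1.2,   1.2,   1.2))
    ),
    overweight_obese = list(
      zbmi     = sub_mat(c( 0.05, -0.01,  1.82,  -0.05, -0.06,  1.77,
                            0.01,  0.06,  1.83,  -0.64, -0.59, -0.65)),
      whtr_pct = sub_mat(c( 0.1,  -0.4,  10.8,   -0.1,  -0.5,  10.7,
                            0.4,   0.5,  11.1,   -3.7,  -3.6,  -4.1)),
      vo2peak  = sub_mat(c( 0.0,   0.0,  -5.1,    0.0,   0.0,  -5.1,
                            0.0,   0.0,  -5.0,    1.8,   1.8,   1.7))
    )
  )

  list(
    parts = parts,
    kappa = 1440,
    n_consented = 215L,
    n_analysed = 169L,
    group_sizes = c(underweight = 15L, normal_weight = 115L,
                    overweight_obese = 39L),
    means = means,
    variation = variation,
    covariates = list(
      age_mean = 10.3, age_sd = 0.3,
      prop_girls = 0.503,
      imd_mean = 2.5, imd_sd = 2.0,
      height_mean = 141.2, height_sd = 6.2,
      waist_mean = 64.3, waist_sd = 10.3
    ),
    outcomes = list(
      zbmi = c(mean = 0.43, sd = 1.31),
      whtr_pct = c(mean = 46, sd = 6),
      vo2peak = c(mean = 47.0, sd = 4.0)
    ),
    substitution_15min = substitution_15min
  )
})
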