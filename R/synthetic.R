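#' Calibrate ilr effect vectors from target substitution differences
#'
#' Given target predicted differences for the D-1 reallocations that donate
#' `minutes` from one part to each other part at a baseline composition,
#' solves the linear system target = beta' (ilr(new) - ilr(base)) for the
#' ilr coefficient vector beta. Used to build generator defaults whose
#' implied substitution tables match published values.
#'
#' @param targets Named numeric vector of length D-1: predicted outcome
#'   differences when `minutes` are moved from `donor` to each named part.
#' @param baseline Baseline composition (named, positive).
#' @param donor Part the time is taken from (default `"mvpa"`).
#' @param minutes Reallocated duration the targets refer to (default 15).
#' @param basis ilr basis; `NULL` for the pivot default.
#' @return Numeric vector of length D-1: ilr coefficients under `basis`.
#' @export
calibrate_ilr_effects <- function(targets, baseline, donor = "mvpa",
                                  minutes = 15, basis = NULL) {
  parts <- names(baseline)
  if (is.null(parts)) stop("`baseline` must be named")
  receivers <- names(targets)
  if (is.null(receivers) || !all(receivers %in% setdiff(parts, donor)) ||
      length(receivers) != length(parts) - 1L)
    stop("`targets` must be named with every part except the donor")
  b <- resolve_basis(basis, parts)
  base <- close_comp(baseline, sum(baseline))
  z0 <- as.numeric(ilr_coords(base, b))
  A <- t(vapply(receivers, function(rcv) {
    as.numeric(ilr_coords(reallocate(base, donor, rcv, minutes), b)) - z0
  }, numeric(length(parts) - 1L)))
  beta <- solve(A, as.numeric(targets))
  stats::setNames(beta, colnames(b$V))
}

#' Configuration of the synthetic cohort generator
#'
#' Assembles every parameter of the logistic-normal data generator. The
#' defaults emulate the reference cohort ([cohort_reference]): three
#' weight-status groups of 15 / 115 / 39 children with the published group
#' compositional means, a shared ilr covariance derived from the published
#' variation matrix via [variation_to_ilr_cov()], covariates matching the
#' cohort's age, sex and deprivation profile, and outcome models whose ilr
#' coefficients are calibrated (via [calibrate_ilr_effects()]) so that 15-min
#' substitution differences at the full-sample mean reproduce the published
#' tables. The calibrated coefficients are fixture defaults for testing, not
#' estimates of the cohort's true coefficients.
#'
#' @param n Named integer vector of group sizes.
#' @param group_means Matrix of group compositional means (rows = groups in
#'   `names(n)`, columns = parts), closed to `kappa`.
#' @param ilr_cov Shared (D-1) x (D-1) ilr covariance of the within-group
#'   composition distribution, under `basis`.
#' @param basis ilr basis used throughout generation.
#' @param outcomes List per outcome of `beta0` (intercept), `beta` (ilr
#'   coefficients), `gamma` (named covariate effects: `sex_girl`, `age`, and
#'   optionally `zbmi`), and `sigma` (residual sd).
#' @param covariates List: `prop_girls`, `age_mean`, `age_sd`, `imd_probs`
#'   (length-10 probabilities of deciles 1..10), `height_mean`, `height_sd`.
#' @param kappa Closure constant (minutes).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n = cohort_reference$group_sizes,
                             group_means = NULL,
                             ilr_cov = NULL,
                             basis = default_basis(),
                             outcomes = NULL,
                             covariates = NULL,
                             kappa = 1440,
                             seed = 20170510) {
  basis <- ilr_basis(basis)
  parts <- basis$parts
  ref <- cohort_reference
  if (is.null(group_means)) {
    group_means <- ref$means[names(n), parts, drop = FALSE]
  }
  group_means <- close_comp(as.matrix(group_means), kappa)
  if (is.null(rownames(group_means))) rownames(group_means) <- names(n)
  if (is.null(ilr_cov)) ilr_cov <- variation_to_ilr_cov(ref$variation[parts, parts], basis)
  ilr_cov <- (as.matrix(ilr_cov) + t(as.matrix(ilr_cov))) / 2
  ev <- eigen(ilr_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("`ilr_cov` must be positive semidefinite")

  if (is.null(covariates)) {
    covariates <- list(
      prop_girls = ref$covariates$prop_girls,
      age_mean = ref$covariates$age_mean, age_sd = ref$covariates$age_sd,
      # concentrated in the most deprived deciles (cohort mean ~2.5, sd ~2)
      imd_probs = c(0.38, 0.27, 0.20, 0.04, 0.03, 0.02, 0.02, 0.02, 0.01, 0.01),
      height_mean = ref$covariates$height_mean,
      height_sd = ref$covariates$height_sd
    )
  }
  if (abs(sum(covariates$imd_probs) - 1) > 1e-8)
    stop("`imd_probs` must sum to 1")

  if (is.null(outcomes)) {
    base_all <- close_comp(ref$means["all", parts], kappa)
    sub <- ref$substitution_15min$all
    mvpa_col <- function(m) {
      rcv <- setdiff(parts, "mvpa")
      stats::setNames(m[rcv, "mvpa"], rcv)
    }
    beta <- lapply(list(zbmi = sub$zbmi, whtr_pct = sub$whtr_pct,
                        vo2peak = sub$vo2peak),
                   function(m) calibrate_ilr_effects(mvpa_col(m), base_all,
                                                     donor = "mvpa",
                                                     minutes = 15, basis = basis))
    z_all <- as.numeric(ilr_coords(base_all, basis))
    ecov <- c(sex_girl = covariates$prop_girls, age = covariates$age_mean)
    lin0 <- function(beta, gamma) sum(beta * z_all) + sum(gamma * ecov[names(gamma)])
    gamma_zbmi <- c(sex_girl = -0.2, age = 0.9)
    gamma_whtr <- c(sex_girl = -1.9, age = 2.0)
    gamma_vo2 <- c(sex_girl = -0.4, age = 0)
    outcomes <- list(
      zbmi = list(
        beta0 = ref$outcomes$zbmi[["mean"]] - lin0(beta$zbmi, gamma_zbmi),
        beta = beta$zbmi, gamma = gamma_zbmi, sigma = 0.9),
      whtr_pct = list(
        beta0 = ref$outcomes$whtr_pct[["mean"]] - lin0(beta$whtr_pct, gamma_whtr),
        beta = beta$whtr_pct, gamma = gamma_whtr, sigma = 4.5),
      vo2peak = list(
        beta0 = ref$outcomes$vo2peak[["mean"]] - lin0(beta$vo2peak, gamma_vo2) -
          (-1.5) * ref$outcomes$zbmi[["mean"]],
        beta = beta$vo2peak,
        gamma = c(gamma_vo2, zbmi = -1.5), sigma = 2.8)
    )
  }
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (length(o$beta) != length(parts) - 1L)
      stop(sprintf("outcome '%s': beta must have length D-1", nm))
    if (!is.numeric(o$sigma) || o$sigma < 0)
      stop(sprintf("outcome '%s': sigma must be nonnegative", nm))
  }
  structure(list(
    parts = parts, kappa = kappa, basis = basis,
    n = n, group_means = group_means, ilr_cov = ilr_cov,
    outcomes = outcomes, covariates = covariates, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic cohort config: %d participants in %d group(s), seed %d\n",
              sum(x$n), length(x$n), x$seed))
  cat("group sizes:\n"); print(x$n)
  cat("group compositional means (min/day):\n"); print(round(x$group_means, 1))
  cat("outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  invisible(x)
}

# Draw n compositions for one group: multivariate normal in ilr space around
# the group mean's coordinates, back-transformed and closed. No seeding here.
draw_compositions <- function(cfg, group, n) {
  mu <- as.numeric(ilr_coords(cfg$group_means[group, ], cfg$basis))
  z <- MASS::mvrnorm(n, mu = mu, Sigma = cfg$ilr_cov)
  if (n == 1L) z <- rbind(z)
  ilr_inverse(z, cfg$basis, cfg$kappa)
}

#' Generate synthetic behaviour compositions for one group
#'
#' Logistic-normal sampling: multivariate normal ilr coordinates centred on
#' the group's mean composition with the configured covariance, inverted to
#' the simplex and closed to `kappa`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param group Group name (a row of `cfg$group_means`).
#' @param n Number of samples; defaults to the configured group size.
#' @return An n x D matrix of closed compositions.
#' @export
generate_compositions <- function(cfg, group, n = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!group %in% rownames(cfg$group_means)) stop("unknown group: ", group)
  if (is.null(n)) n <- cfg$n[[group]]
  set.seed(cfg$seed)
  draw_compositions(cfg, group, n)
}

#' Generate a full synthetic participant table
#'
#' Draws compositions per weight-status group, covariates (sex, age, IMD
#' decile, height), and outcomes from the configured linear models
#' y = beta0 + beta' ilr(x) + gamma' covariates + N(0, sigma^2). VO2 peak may
#' depend on the generated zBMI through a `zbmi` entry in its `gamma`, so the
#' fitness-adjusted-for-fatness analysis is meaningful on synthetic data.
#' Waist circumference is emitted consistently with \%WHtR and height. The
#' weight-status label records the generating group.
#'
#' @param cfg A [synthetic_config()].
#' @return A data frame with columns `id`, `sleep_min`, `st_min`, `lpa_min`,
#'   `mvpa_min`, `sex`, `age`, `imd_decile`, `height_cm`, `waist_cm`,
#'   `weight_status`, `zbmi`, `whtr_pct`, `vo2peak`.
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  groups <- names(cfg$n)
  comp <- do.call(rbind, lapply(groups, function(g) draw_compositions(cfg, g, cfg$n[[g]])))
  n <- nrow(comp)
  rec <- data.frame(id = sprintf("P%04d", seq_len(n)))
  for (p in cfg$parts) rec[[paste0(p, "_min")]] <- unname(comp[, p])
  cv <- cfg$covariates
  rec$sex <- ifelse(stats::runif(n) < cv$prop_girls, "girl", "boy")
  rec$age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  rec$imd_decile <- sample(1:10, n, replace = TRUE, prob = cv$imd_probs)
  rec$height_cm <- stats::rnorm(n, cv$height_mean, cv$height_sd)
  rec$weight_status <- rep(groups, times = as.integer(cfg$n[groups]))

  z <- ilr_coords(comp, cfg$basis)
  xg <- cbind(sex_girl = as.numeric(rec$sex == "girl"), age = rec$age)
  linpred <- function(o, extra = NULL) {
    lp <- o$beta0 + as.numeric(z %*% o$beta)
    for (nm in names(o$gamma)) {
      val <- if (nm %in% colnames(xg)) xg[, nm] else extra[[nm]]
      if (is.null(val)) stop("no generator column for gamma term: ", nm)
      lp <- lp + o$gamma[[nm]] * val
    }
    lp
  }
  rec$zbmi <- linpred(cfg$outcomes$zbmi) + stats::rnorm(n, 0, cfg$outcomes$zbmi$sigma)
  rec$whtr_pct <- linpred(cfg$outcomes$whtr_pct) + stats::rnorm(n, 0, cfg$outcomes$whtr_pct$sigma)
  rec$vo2peak <- linpred(cfg$outcomes$vo2peak, extra = list(zbmi = rec$zbmi)) +
    stats::rnorm(n, 0, cfg$outcomes$vo2peak$sigma)
  rec$waist_cm <- rec$whtr_pct / 100 * rec$height_cm
  rec
}

#' Write a seeded synthetic fixture to disk
#'
#' Writes the generated participant table as CSV together with a JSON truth
#' file recording the generating parameters (group means, ilr covariance,
#' outcome coefficients, seed), so tests can compare estimates against the
#' ground truth. Output is byte-stable for a fixed config.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
make_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- generate_records(cfg)
  data_path <- file.path(dir, "synthetic_records.csv")
  utils::write.csv(rec, data_path, row.names = FALSE)
  truth <- list(
    parts = cfg$parts, kappa = cfg$kappa, seed = cfg$seed,
    n = as.list(cfg$n),
    group_means = apply(cfg$group_means, 1, function(r) as.list(r), simplify = FALSE),
    ilr_cov = unclass(cfg$ilr_cov),
    sbp = unclass(cfg$basis$sbp),
    outcomes = lapply(cfg$outcomes, function(o)
      list(beta0 = o$beta0, beta = as.list(o$beta),
           gamma = as.list(o$gamma), sigma = o$sigma)),
    covariates = cfg$covariates
  )
  truth_path <- file.path(dir, "synthetic_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(data = data_path, truth = truth_path))
}
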