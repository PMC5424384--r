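#' Extract and close the behaviour composition columns of a records table
#'
#' @param records Data frame with one row per participant.
#' @param part_cols Named character vector mapping part labels to column
#'   names; default `sleep_min`, `st_min`, `lpa_min`, `mvpa_min`.
#' @param kappa Closure constant (minutes).
#' @return An n x D matrix of closed compositions, columns named by part.
#' @export
record_compositions <- function(records,
                                part_cols = default_part_cols(),
                                kappa = 1440) {
  missing_cols <- setdiff(unname(part_cols), names(records))
  if (length(missing_cols) > 0L)
    stop("missing behaviour columns: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(records[, unname(part_cols), drop = FALSE])
  colnames(m) <- names(part_cols)
  close_comp(m, kappa)
}

#' @rdname record_compositions
#' @export
default_part_cols <- function() {
  stats::setNames(paste0(behaviour_parts, "_min"), behaviour_parts)
}

#' Fit a linear model of an outcome on ilr coordinates and covariates
#'
#' Ordinary least squares of a health outcome on the D-1 ilr coordinates of
#' the daily behaviour composition plus sociodemographic covariates. Sex and
#' IMD decile are entered as unordered factors (reference = first level
#' alphabetically / lowest observed decile); age is numeric. Rows with
#' missing values in any used column are dropped (complete-case) and the
#' count is reported. Fitted values, predictions and all downstream
#' substitution differences are invariant to the choice of ilr basis.
#'
#' @param records Data frame with behaviour columns (see
#'   [record_compositions()]), the outcome, and the covariates.
#' @param outcome Name of the outcome column, e.g. `"zbmi"`, `"whtr_pct"`,
#'   `"vo2peak"`.
#' @param covariates Character vector of covariate column names. Default
#'   `c("sex", "age", "imd_decile")`; add `"zbmi"` to adjust the fitness
#'   model for adiposity.
#' @param basis ilr basis (see [ilr_basis()]); `NULL` for the pivot default.
#' @param part_cols,kappa Passed to [record_compositions()].
#' @return An object of class `"ilr_lm"`: a list carrying the underlying
#'   [stats::lm] fit, the basis, the part/column mapping, and bookkeeping
#'   (n used, rows dropped).
#' @export
fit_outcome_model <- function(records, outcome,
                              covariates = c("sex", "age", "imd_decile"),
                              basis = NULL,
                              part_cols = default_part_cols(),
                              kappa = 1440) {
  if (!outcome %in% names(records)) stop("outcome column not found: ", outcome)
  miss <- setdiff(covariates, names(records))
  if (length(miss) > 0L) stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  if (outcome %in% covariates) stop("outcome cannot also be a covariate")

  used <- c(unname(part_cols), outcome, covariates)
  cc <- stats::complete.cases(records[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0L)
    message(sprintf("fit_outcome_model: dropped %d incomplete row(s) for outcome '%s'",
                    n_dropped, outcome))
  rec <- records[cc, , drop = FALSE]

  comp <- record_compositions(rec, part_cols, kappa)
  b <- resolve_basis(basis, colnames(comp))
  z <- ilr_coords(comp, b)
  ilr_terms <- paste0(".ilr", seq_len(ncol(z)))
  colnames(z) <- ilr_terms

  df <- data.frame(.outcome = rec[[outcome]], z, check.names = FALSE)
  for (cv in covariates) {
    v <- rec[[cv]]
    if (cv == "imd_decile") {
      if (!all(v %in% 1:10)) stop("imd_decile values must be integers 1..10")
      v <- factor(v, levels = sort(unique(v)))
    } else if (is.character(v) || is.logical(v)) {
      v <- factor(v)
    }
    df[[cv]] <- v
  }

  p <- length(ilr_terms) + 1L +
    sum(vapply(covariates, function(cv) {
      if (is.factor(df[[cv]])) nlevels(df[[cv]]) - 1L else 1L
    }, integer(1)))
  if (nrow(df) <= p) stop(sprintf("too few complete records (%d) for %d parameters", nrow(df), p))

  fml <- stats::as.formula(paste(".outcome ~", paste(c(ilr_terms, covariates), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ", paste(aliased, collapse = ", "))
  }

  structure(list(
    fit = fit, outcome = outcome, covariates = covariates,
    ilr_terms = ilr_terms, basis = b, part_cols = part_cols, kappa = kappa,
    data = df, compositions = comp,
    n = nrow(df), n_dropped = n_dropped
  ), class = "ilr_lm")
}

#' @export
print.ilr_lm <- function(x, ...) {
  cat(sprintf("ilr linear model: %s ~ ilr(%s) + %s\n", x$outcome,
              paste(x$basis$parts, collapse = ", "),
              paste(x$covariates, collapse = " + ")))
  cat(sprintf("n = %d (%d incomplete row(s) dropped), residual df = %d\n",
              x$n, x$n_dropped, x$fit$df.residual))
  print(round(stats::coef(x$fit), 4))
  invisible(x)
}

#' @export
coef.ilr_lm <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.ilr_lm <- function(object, ...) stats::vcov(object$fit)

# Mean row of the design matrix: intercept 1, covariate columns at their
# sample means (factors averaged over observed proportions). The ilr columns
# are returned too but are overwritten by callers.
design_profile <- function(object) {
  colMeans(stats::model.matrix(object$fit))
}

# Design row for an explicit covariate profile (named list). Factor values
# must be existing levels; numeric covariates scalars.
profile_design_row <- function(object, profile) {
  xbar <- design_profile(object)
  if (is.null(profile)) return(xbar)
  nd <- data.frame(.outcome = 0)
  for (tm in object$ilr_terms) nd[[tm]] <- 0
  for (cv in object$covariates) {
    v <- object$data[[cv]]
    if (cv %in% names(profile)) {
      val <- profile[[cv]]
      if (is.factor(v)) {
        if (!val %in% levels(v))
          stop(sprintf("unknown level '%s' for covariate '%s'", val, cv))
        nd[[cv]] <- factor(val, levels = levels(v))
      } else nd[[cv]] <- as.numeric(val)
    } else {
      nd[[cv]] <- if (is.factor(v)) factor(levels(v)[1L], levels = levels(v)) else mean(v)
    }
  }
  extra <- setdiff(names(profile), object$covariates)
  if (length(extra) > 0L)
    stop("profile names not among model covariates: ", paste(extra, collapse = ", "))
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$fit)), nd,
                           xlev = object$fit$xlevels)
  row <- xbar
  row[colnames(X)] <- X[1L, ]
  row
}

#' Predict an outcome for a composition at a covariate profile
#'
#' Evaluates the fitted linear predictor at the ilr coordinates of `comp`.
#' By default the covariates are held at their sample means, with factors
#' averaged over their observed proportions, so the prediction at the
#' training compositional mean equals the mean fitted value. Differences in
#' predictions between two compositions do not depend on the profile (no
#' interactions are modelled).
#'
#' @param object An `"ilr_lm"` fit.
#' @param comp A composition: named vector of the model's parts (any positive
#'   total; it is closed internally).
#' @param profile Optional named list of covariate values, e.g.
#'   `list(sex = "girl", age = 10)`. Omitted covariates fall back to the
#'   default profile.
#' @param se Also return the standard error of the prediction.
#' @return The predicted outcome (a single number), or a named vector with
#'   `fit` and `se` when `se = TRUE`.
#' @export
predict_outcome <- function(object, comp, profile = NULL, se = FALSE) {
  stopifnot(inherits(object, "ilr_lm"))
  comp <- align_comp(object, comp)
  z <- ilr_coords(close_comp(comp, object$kappa), object$basis)
  row <- profile_design_row(object, profile)
  row[object$ilr_terms] <- as.numeric(z)
  est <- drop(row %*% stats::coef(object$fit))
  if (!se) return(est)
  v <- drop(t(row) %*% stats::vcov(object$fit) %*% row)
  c(fit = est, se = sqrt(v))
}

# Reorders a named composition vector to the model's part order; unnamed
# vectors of the right length are accepted as already ordered.
align_comp <- function(object, comp) {
  parts <- object$basis$parts
  if (length(comp) != length(parts))
    stop(sprintf("composition has %d parts; model expects %d", length(comp), length(parts)))
  if (!is.null(names(comp))) {
    if (!setequal(names(comp), parts))
      stop("composition parts do not match the model: expected ",
           paste(parts, collapse = ", "))
    comp <- comp[parts]
  } else names(comp) <- parts
  comp
}
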