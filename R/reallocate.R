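#' Reallocate time between two behaviours
#'
#' Builds a new composition in which `minutes` are moved from one part to
#' another while every other part is left untouched, so the 1440-min total is
#' preserved exactly. The donor part must retain strictly positive time.
#'
#' @param baseline A closed composition (named numeric vector).
#' @param from,to Part labels: time is taken from `from` and given to `to`.
#' @param minutes Nonnegative duration to move.
#' @return The reallocated composition, same names and total as `baseline`.
#' @examples
#' base <- close_comp(c(sleep = 548.6, st = 510.3, lpa = 354.8, mvpa = 26.4))
#' reallocate(base, from = "sleep", to = "mvpa", minutes = 10)
#' @export
reallocate <- function(baseline, from, to, minutes) {
  if (is.null(names(baseline))) stop("`baseline` must be a named composition")
  if (!from %in% names(baseline)) stop("unknown part: ", from)
  if (!to %in% names(baseline)) stop("unknown part: ", to)
  if (from == to) stop("`from` and `to` must differ")
  if (!is.numeric(minutes) || length(minutes) != 1L || minutes < 0)
    stop("`minutes` must be a single nonnegative number")
  if (minutes >= baseline[[from]])
    stop(sprintf("cannot move %g min out of '%s': only %g min available (strict positivity required)",
                 minutes, from, baseline[[from]]))
  out <- baseline
  out[[from]] <- out[[from]] - minutes
  out[[to]] <- out[[to]] + minutes
  out
}

#' Predicted outcome difference for one time reallocation
#'
#' Compositional isotemporal substitution around a baseline: the fitted
#' model's prediction for the reallocated composition minus its prediction
#' for the baseline, covariates held fixed. The covariate profile cancels in
#' the subtraction, so the difference depends only on the ilr coefficients
#' and the two compositions. A delta-method standard error and confidence
#' interval are derived from the coefficient covariance of the ilr block.
#'
#' Because predictions are linear in ilr coordinates -- not in minutes -- the
#' difference for A to B does not mirror B to A, and the same reallocation
#' yields different differences at different baselines.
#'
#' @param object An `"ilr_lm"` fit.
#' @param baseline Baseline composition (named vector; closed internally).
#' @param from,to,minutes The reallocation, as in [reallocate()].
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row data frame: `outcome`, `from`, `to`, `minutes`,
#'   `difference`, `se`, `lower`, `upper`.
#' @export
predicted_difference <- function(object, baseline, from, to, minutes,
                                 conf_level = 0.95) {
  stopifnot(inherits(object, "ilr_lm"))
  baseline <- close_comp(align_comp(object, baseline), object$kappa)
  new <- reallocate(baseline, from, to, minutes)
  z0 <- as.numeric(ilr_coords(baseline, object$basis))
  z1 <- as.numeric(ilr_coords(new, object$basis))
  dz <- z1 - z0
  beta_z <- stats::coef(object$fit)[object$ilr_terms]
  diff <- drop(crossprod(beta_z, dz))
  Vz <- stats::vcov(object$fit)[object$ilr_terms, object$ilr_terms]
  se <- sqrt(drop(t(dz) %*% Vz %*% dz))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, object$fit$df.residual)
  data.frame(outcome = object$outcome, from = from, to = to, minutes = minutes,
             difference = diff, se = se,
             lower = diff - tcrit * se, upper = diff + tcrit * se)
}

#' Substitution grid over durations and behaviour pairs
#'
#' Evaluates [predicted_difference()] for every ordered pair of parts and
#' every requested duration. Reallocations that would exhaust the donor part
#' are not errors: the row is kept with `feasible = FALSE` and missing
#' difference, so a complete grid is always produced.
#'
#' @param object An `"ilr_lm"` fit.
#' @param baseline Baseline composition; default the compositional mean of
#'   the model's training data.
#' @param durations Minutes to reallocate; default `seq(0, 25, by = 5)`. Use
#'   `seq(0, 25, by = 2.5)` for a fine grid.
#' @param conf_level Confidence level for the delta-method intervals.
#' @return A data frame with one row per (from, to, duration):
#'   `outcome, from, to, minutes, difference, se, lower, upper, feasible`.
#' @export
difference_grid <- function(object, baseline = NULL,
                            durations = seq(0, 25, by = 5),
                            conf_level = 0.95) {
  stopifnot(inherits(object, "ilr_lm"))
  if (any(durations < 0)) stop("durations must be nonnegative")
  if (is.null(baseline)) baseline <- comp_mean(object$compositions, object$kappa)
  baseline <- close_comp(align_comp(object, baseline), object$kappa)
  parts <- object$basis$parts
  rows <- list()
  for (from in parts) for (to in parts) {
    if (from == to) next
    for (t in durations) {
      if (t < baseline[[from]]) {
        r <- predicted_difference(object, baseline, from, to, t, conf_level)
        r$feasible <- TRUE
      } else {
        r <- data.frame(outcome = object$outcome, from = from, to = to,
                        minutes = t, difference = NA_real_, se = NA_real_,
                        lower = NA_real_, upper = NA_real_, feasible = FALSE)
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  out
}

#' One-duration substitution matrix (rows receive, columns donate)
#'
#' Reshapes a substitution at a single duration into the conventional square
#' display: the entry in row i, column j is the predicted outcome difference
#' when part i receives `minutes` taken from part j. The diagonal is `NA`;
#' infeasible moves are `NA` too.
#'
#' @inheritParams difference_grid
#' @param minutes Single duration (default 15).
#' @return A D x D numeric matrix with a `"baseline"` attribute.
#' @export
substitution_matrix <- function(object, baseline = NULL, minutes = 15) {
  g <- difference_grid(object, baseline, durations = minutes)
  parts <- object$basis$parts
  m <- matrix(NA_real_, length(parts), length(parts), dimnames = list(parts, parts))
  for (k in seq_len(nrow(g))) m[g$to[k], g$from[k]] <- g$difference[k]
  attr(m, "baseline") <- attr(g, "baseline")
  attr(m, "minutes") <- minutes
  m
}

#' Substitution grids around group-specific baseline compositions
#'
#' Fits nothing new: the shared model (fitted on all records) is evaluated at
#' the compositional mean of each group, so differences between the group
#' grids reflect baseline dependence only. Empty groups are skipped with a
#' warning.
#'
#' @param object An `"ilr_lm"` fit (on the full sample).
#' @param records The records table containing the grouping column and the
#'   behaviour columns the model was configured with.
#' @param group_col Name of the grouping column (default `"weight_status"`).
#' @param durations As in [difference_grid()].
#' @param conf_level Confidence level for intervals.
#' @return A named list, one [difference_grid()] data frame per group; each
#'   carries its group baseline as an attribute.
#' @export
group_baseline_grids <- function(object, records, group_col = "weight_status",
                                 durations = seq(0, 25, by = 5),
                                 conf_level = 0.95) {
  stopifnot(inherits(object, "ilr_lm"))
  if (!group_col %in% names(records)) stop("grouping column not found: ", group_col)
  groups <- records[[group_col]]
  lv <- if (is.factor(groups)) levels(groups) else sort(unique(as.character(groups)))
  out <- list()
  for (g in lv) {
    idx <- which(as.character(groups) == g & !is.na(groups))
    if (length(idx) == 0L) {
      warning("group '", g, "' is empty; skipped")
      next
    }
    comp <- record_compositions(records[idx, , drop = FALSE],
                                object$part_cols, object$kappa)
    base <- comp_mean(comp, object$kappa)
    out[[g]] <- difference_grid(object, base, durations, conf_level)
  }
  out
}
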