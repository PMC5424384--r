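#' Type II (marginality) tests for an ilr linear model
#'
#' Tests each explanatory term after all others: the ilr coordinates are
#' treated as a single block with D-1 degrees of freedom, and each covariate
#' as its own term. For every term the Type II sum of squares is the increase
#' in residual sum of squares when that term alone is removed from the full
#' model; F = (SS / df_term) / (RSS_full / df_residual). Because no
#' interactions are modelled, this coincides with the classical Type II
#' decomposition. Wald chi-squared statistics for the same hypotheses
#' (b' V^-1 b on the term's coefficient block) are reported alongside; with
#' OLS they equal df_term * F and give asymptotically equivalent p-values.
#'
#' @param object An `"ilr_lm"` fit from [fit_outcome_model()].
#' @param terms Terms to test; default the ilr block plus every covariate.
#' @return A data frame of class `"ilr_anova"` with one row per term:
#'   `term`, `sum_sq`, `df`, `f_value`, `p_value`, `wald_chisq`,
#'   `p_wald`. The full-model residual SS and df are attached as attributes
#'   `"rss"` and `"df_residual"`.
#' @export
anova_marginality <- function(object, terms = NULL) {
  stopifnot(inherits(object, "ilr_lm"))
  all_terms <- c("ilr", object$covariates)
  if (is.null(terms)) terms <- all_terms
  unknown <- setdiff(terms, all_terms)
  if (length(unknown) > 0L)
    stop("term(s) not in the model: ", paste(unknown, collapse = ", "))

  fit <- object$fit
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- fit$df.residual
  s2 <- rss_full / df_res
  Vb <- stats::vcov(fit)
  beta <- stats::coef(fit)

  rows <- lapply(terms, function(tm) {
    drop_vars <- if (tm == "ilr") object$ilr_terms else tm
    keep <- setdiff(c(object$ilr_terms, object$covariates), drop_vars)
    rhs <- if (length(keep) > 0L) paste(keep, collapse = " + ") else "1"
    red <- stats::lm(stats::as.formula(paste(".outcome ~", rhs)), data = object$data)
    ss <- sum(stats::residuals(red)^2) - rss_full
    df_term <- red$df.residual - df_res
    fval <- (ss / df_term) / s2
    # Wald block test on the same coefficients
    idx <- if (tm == "ilr") object$ilr_terms else
      colnames(stats::model.matrix(fit))[attr(stats::model.matrix(fit), "assign") ==
                                           which(attr(stats::terms(fit), "term.labels") == tm)]
    bsub <- beta[idx]
    W <- drop(t(bsub) %*% solve(Vb[idx, idx, drop = FALSE]) %*% bsub)
    data.frame(term = tm, sum_sq = ss, df = df_term,
               f_value = fval,
               p_value = stats::pf(fval, df_term, df_res, lower.tail = FALSE),
               wald_chisq = W,
               p_wald = stats::pchisq(W, df_term, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rss") <- rss_full
  attr(out, "df_residual") <- df_res
  attr(out, "outcome") <- object$outcome
  class(out) <- c("ilr_anova", "data.frame")
  out
}

#' @export
print.ilr_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Type II tests for outcome '%s' (residual df = %d)\n",
              attr(x, "outcome"), attr(x, "df_residual")))
  df <- as.data.frame(x)
  df$sum_sq <- round(df$sum_sq, 1)
  df$f_value <- round(df$f_value, 1)
  df$p_value <- signif(df$p_value, digits)
  df$wald_chisq <- round(df$wald_chisq, 1)
  df$p_wald <- signif(df$p_wald, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Regression diagnostics for an ilr linear model
#'
#' Assumption checks for the OLS fit: residual normality (Shapiro-Wilk),
#' homoscedasticity (studentised Breusch-Pagan test on the model's
#' regressors), linearity (Ramsey RESET with squared and cubed fitted
#' values), and flagging of outlying / influential observations.
#'
#' Flag thresholds (documented, overridable): |externally studentised
#' residual| > `rstudent_cut` (default 3), leverage > `leverage_mult` * p / n
#' (default 2 p/n), Cook's distance > `cooks_cut` (default 4 / n).
#'
#' @param object An `"ilr_lm"` fit.
#' @param alpha Significance level for the three assumption tests.
#' @param rstudent_cut,leverage_mult,cooks_cut Flag thresholds, see above.
#' @return A list of class `"ilr_lm_diagnostics"`: test statistics and
#'   p-values, logical `pass` entries at `alpha`, and integer index vectors
#'   of flagged observations.
#' @export
model_diagnostics <- function(object, alpha = 0.05, rstudent_cut = 3,
                              leverage_mult = 2, cooks_cut = NULL) {
  stopifnot(inherits(object, "ilr_lm"))
  fit <- object$fit
  n <- object$n
  p <- fit$rank
  if (is.null(cooks_cut)) cooks_cut <- 4 / n

  res <- stats::residuals(fit)
  sw <- stats::shapiro.test(res)
  bp <- lmtest::bptest(fit, studentize = TRUE)
  reset <- lmtest::resettest(fit, power = 2:3, type = "fitted")

  rstud <- stats::rstudent(fit)
  lev <- stats::hatvalues(fit)
  cook <- stats::cooks.distance(fit)
  lev_cut <- leverage_mult * p / n

  structure(list(
    n = n, p = p, alpha = alpha,
    normality = list(statistic = unname(sw$statistic), p_value = sw$p.value,
                     pass = sw$p.value > alpha),
    homoscedasticity = list(statistic = unname(bp$statistic), df = unname(bp$parameter),
                            p_value = bp$p.value, pass = bp$p.value > alpha),
    linearity = list(statistic = unname(reset$statistic), p_value = reset$p.value,
                     pass = reset$p.value > alpha),
    outliers = list(rstudent_cut = rstudent_cut,
                    flagged = which(abs(rstud) > rstudent_cut),
                    max_abs_rstudent = max(abs(rstud))),
    leverage = list(cut = lev_cut, flagged = which(lev > lev_cut)),
    influence = list(cooks_cut = cooks_cut, flagged = which(cook > cooks_cut),
                     max_cooks = max(cook)),
    residual_sd = sqrt(sum(res^2) / fit$df.residual)
  ), class = "ilr_lm_diagnostics")
}

#' @export
print.ilr_lm_diagnostics <- function(x, ...) {
  ok <- function(p) if (p) "ok" else "FLAG"
  cat(sprintf("Diagnostics (n = %d, p = %d, alpha = %g)\n", x$n, x$p, x$alpha))
  cat(sprintf("  normality (Shapiro-Wilk):   W = %.3f, p = %.3g  [%s]\n",
              x$normality$statistic, x$normality$p_value, ok(x$normality$pass)))
  cat(sprintf("  homoscedasticity (BP):      LM = %.2f, p = %.3g  [%s]\n",
              x$homoscedasticity$statistic, x$homoscedasticity$p_value,
              ok(x$homoscedasticity$pass)))
  cat(sprintf("  linearity (RESET):          F = %.2f, p = %.3g  [%s]\n",
              x$linearity$statistic, x$linearity$p_value, ok(x$linearity$pass)))
  cat(sprintf("  |rstudent| > %g:            %d flagged\n",
              x$outliers$rstudent_cut, length(x$outliers$flagged)))
  cat(sprintf("  leverage > %.3f:            %d flagged\n",
              x$leverage$cut, length(x$leverage$flagged)))
  cat(sprintf("  Cook's D > %.3f:            %d flagged\n",
              x$influence$cooks_cut, length(x$influence$flagged)))
  invisible(x)
}
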