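#' Close a positive vector onto the simplex
#'
#' Rescales strictly positive durations so that the parts of each composition
#' sum to the closure constant `kappa`, preserving all ratios between parts.
#' For daily movement behaviours `kappa` is 1440 minutes (24 h).
#'
#' @param x A numeric vector of strictly positive part values, or a matrix /
#'   data frame with one composition per row. Part names are taken from
#'   `names(x)` or `colnames(x)` and preserved.
#' @param kappa Closure constant (total sum after closure), in the same units
#'   as `x`. Default 1440 minutes.
#' @return A numeric vector or matrix of the same shape as `x`, each
#'   composition summing to `kappa`, with a `"kappa"` attribute recording the
#'   constant.
#' @examples
#' close_comp(c(sleep = 548.6, st = 510.3, lpa = 354.8, mvpa = 26.4))
#' @export
close_comp <- function(x, kappa = 1440) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single positive number")
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    check_positive_parts(x)
    out <- x * (kappa / rowSums(x))
  } else {
    check_positive_parts(rbind(x))
    out <- x * (kappa / sum(x))
    names(out) <- names(x)
  }
  attr(out, "kappa") <- kappa
  out
}

# Validates an n x D matrix of part values: finite and strictly positive.
# Names the offending part in the error so bad input rows are traceable.
check_positive_parts <- function(m) {
  if (!is.numeric(m)) stop("composition values must be numeric")
  if (ncol(m) < 2L) stop("a composition needs at least 2 parts")
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    j <- bad[1L, 2L]
    part <- if (!is.null(colnames(m))) colnames(m)[j] else paste0("part ", j)
    stop(sprintf("non-positive or non-finite value in %s (row %d): %g",
                 part, bad[1L, 1L], m[bad[1L, 1L], j]))
  }
  cn <- colnames(m)
  if (!is.null(cn) && anyDuplicated(cn))
    stop("part labels must be unique")
  invisible(m)
}

#' Replace zero durations before log-ratio analysis
#'
#' Log-ratio methods are undefined at zero. This helper applies simple
#' multiplicative replacement: each zero is set to `delta` and the non-zero
#' parts of that composition are shrunk proportionally so the row total is
#' unchanged. Replacement is deliberately explicit and loud: by default every
#' affected row is reported via [message()].
#'
#' @param x Matrix or data frame of nonnegative part durations (rows =
#'   compositions).
#' @param delta Replacement value in minutes for each zero part. Default 0.5.
#' @param quiet Suppress the per-call message. Default `FALSE`.
#' @return Matrix with strictly positive entries and unchanged row sums.
#' @export
replace_zeros <- function(x, delta = 0.5, quiet = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- rbind(x)
  if (any(!is.finite(x) | x < 0)) stop("negative or non-finite durations cannot be zero-replaced")
  if (delta <= 0) stop("`delta` must be positive")
  nz <- rowSums(x == 0)
  if (all(nz == 0L)) return(x)
  tot <- rowSums(x)
  if (any(delta * nz >= tot)) stop("`delta` too large for the row totals")
  out <- x
  for (i in which(nz > 0L)) {
    z <- x[i, ] == 0
    out[i, z] <- delta
    out[i, !z] <- x[i, !z] * (tot[i] - delta * sum(z)) / tot[i]
  }
  if (!quiet)
    message(sprintf("replace_zeros: imputed %d zero value(s) in %d row(s) with delta = %g min",
                    sum(nz), sum(nz > 0L), delta))
  out
}
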