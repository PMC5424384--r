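#' Pairwise log-ratio variation matrix
#'
#' Entry (i, j) is the sample variance (denominator n-1) of ln(x_i / x_j)
#' across observations. Small entries indicate that the two behaviours are
#' nearly proportional across people (high co-dependence); large entries mark
#' behaviours whose share varies freely relative to the other. The matrix is
#' symmetric with a zero diagonal and is unchanged by closure of the input or
#' by perturbation (multiplying every row by a fixed positive composition).
#'
#' @param x Matrix or data frame of compositions, one row per observation.
#' @return A D x D symmetric nonnegative matrix with zero diagonal, labelled
#'   by the part names.
#' @export
variation_matrix <- function(x) {
  m <- if (is.data.frame(x)) as.matrix(x) else x
  if (!is.matrix(m)) stop("`x` must be a matrix of compositions (rows = samples)")
  if (nrow(m) < 2L) stop("need at least 2 compositions to estimate variation")
  check_positive_parts(m)
  lx <- log(m)
  D <- ncol(m)
  vm <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(D - 1L)) {
    for (j in (i + 1L):D) {
      v <- stats::var(lx[, i] - lx[, j])
      vm[i, j] <- vm[j, i] <- v
    }
  }
  vm
}

#' Convert between a variation matrix and log-ratio covariances
#'
#' The variation matrix T and the centred log-ratio (clr) covariance S are
#' equivalent descriptions of compositional dispersion, linked by
#' S = -1/2 * G T G with G = I - J/D the double-centring projector, and
#' T\[i, j\] = S\[i, i\] + S\[j, j\] - 2 S\[i, j\]. The ilr covariance under a
#' basis V is t(V) %*% S %*% V. These conversions let a dispersion summary
#' published as a variation matrix parameterise a logistic-normal simulator.
#'
#' @param vm A symmetric nonnegative variation matrix with zero diagonal.
#' @param basis An `"ilr_basis"` (or sign matrix) whose dimension matches
#'   `vm`; `NULL` gives the pivot default for the row labels of `vm`.
#' @return `variation_to_clr_cov()`: the D x D clr covariance matrix.
#'   `variation_to_ilr_cov()`: the (D-1) x (D-1) ilr covariance.
#'   `ilr_cov_to_variation()`: the D x D variation matrix implied by an ilr
#'   covariance.
#' @name variation_cov
#' @export
variation_to_clr_cov <- function(vm) {
  vm <- as.matrix(vm)
  D <- nrow(vm)
  if (ncol(vm) != D) stop("variation matrix must be square")
  if (max(abs(vm - t(vm))) > 1e-8) stop("variation matrix must be symmetric")
  if (any(vm < -1e-12)) stop("variation matrix entries must be nonnegative")
  if (max(abs(diag(vm))) > 1e-8) stop("variation matrix must have a zero diagonal")
  G <- diag(D) - matrix(1 / D, D, D)
  S <- -0.5 * G %*% vm %*% G
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(vm)
  S
}

#' @rdname variation_cov
#' @export
variation_to_ilr_cov <- function(vm, basis = NULL) {
  vm <- as.matrix(vm)
  b <- resolve_basis(basis, rownames(vm))
  if (length(b$parts) != nrow(vm)) stop("basis dimension does not match the variation matrix")
  S <- variation_to_clr_cov(vm)
  out <- t(b$V) %*% S %*% b$V
  out <- (out + t(out)) / 2
  dimnames(out) <- list(colnames(b$V), colnames(b$V))
  out
}

#' @rdname variation_cov
#' @param sigma A (D-1) x (D-1) ilr covariance matrix under `basis`.
#' @export
ilr_cov_to_variation <- function(sigma, basis) {
  b <- ilr_basis(basis)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != length(b$parts) - 1L) stop("ilr covariance dimension does not match basis")
  S <- b$V %*% sigma %*% t(b$V)      # clr covariance
  d <- diag(S)
  vm <- outer(d, d, "+") - 2 * S
  vm[abs(vm) < 1e-15] <- 0
  dimnames(vm) <- list(b$parts, b$parts)
  vm
}
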