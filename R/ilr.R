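#' Isometric log-ratio coordinates
#'
#' Maps compositions from the simplex to unconstrained real coordinates,
#' z = t(V) %*% log(x), where V is the orthonormal contrast matrix of a
#' sequential binary partition. Coordinates are invariant to closure: scaling
#' a composition by any positive constant leaves them unchanged, so the
#' 1440-min sum constraint carries no information in ilr space.
#'
#' @param x A composition (named numeric vector) or a matrix / data frame of
#'   compositions (one per row, columns = parts).
#' @param basis An `"ilr_basis"`, a sign matrix, or `NULL` for the pivot
#'   default in the order of the columns of `x`.
#' @return A numeric vector of length D-1 (or an n x (D-1) matrix), with the
#'   basis attached as attribute `"basis"`.
#' @examples
#' ilr_coords(c(sleep = 548.6, st = 510.3, lpa = 354.8, mvpa = 26.4))
#' @export
ilr_coords <- function(x, basis = NULL) {
  vec <- !is.matrix(x) && !is.data.frame(x)
  m <- if (is.data.frame(x)) as.matrix(x) else if (is.matrix(x)) x else rbind(x)
  check_positive_parts(m)
  b <- resolve_basis(basis, colnames(m))
  if (ncol(m) != length(b$parts))
    stop(sprintf("composition has %d parts but basis expects %d", ncol(m), length(b$parts)))
  if (!is.null(colnames(m)) && !identical(colnames(m), b$parts) &&
      setequal(colnames(m), b$parts))
    m <- m[, b$parts, drop = FALSE]  # align column order to the basis
  z <- log(m) %*% b$V
  if (vec) z <- z[1L, ]
  attr(z, "basis") <- b
  z
}

#' Inverse ilr: back to the simplex
#'
#' Reconstructs compositions from ilr coordinates under the same basis that
#' produced them and closes them to `kappa`. `ilr_inverse(ilr_coords(x))`
#' recovers `close_comp(x, kappa)` exactly (up to floating point); using a
#' different basis than the one used forward does not.
#'
#' @param z A coordinate vector of length D-1 or an n x (D-1) matrix. If `z`
#'   carries a `"basis"` attribute it is used unless `basis` is supplied.
#' @param basis The `"ilr_basis"` (or sign matrix) to invert under.
#' @param kappa Closure constant for the reconstructed compositions.
#' @return A composition vector or matrix closed to `kappa`, parts named from
#'   the basis.
#' @export
ilr_inverse <- function(z, basis = NULL, kappa = 1440) {
  if (is.null(basis)) basis <- attr(z, "basis")
  if (is.null(basis))
    stop("no basis: supply `basis` or use coordinates produced by ilr_coords()")
  b <- ilr_basis(basis)
  vec <- !is.matrix(z)
  zm <- if (vec) rbind(as.numeric(z)) else as.matrix(z)
  if (ncol(zm) != length(b$parts) - 1L)
    stop(sprintf("coordinates have length %d but basis expects %d",
                 ncol(zm), length(b$parts) - 1L))
  x <- exp(zm %*% t(b$V))
  colnames(x) <- b$parts
  out <- close_comp(x, kappa)
  if (vec) {
    out <- structure(out[1L, ], kappa = kappa)
  }
  out
}

#' Compositional mean
#'
#' The centre of a compositional sample: the arithmetic mean taken in ilr
#' coordinates, back-transformed to the simplex and closed to `kappa`. This
#' equals the closure of the per-part geometric means, and does not depend on
#' which ilr basis is used.
#'
#' @param x Matrix or data frame of compositions (rows = observations).
#' @param kappa Closure constant for the returned mean (default 1440 min).
#' @return A named composition vector summing to `kappa`.
#' @examples
#' m <- rbind(c(480, 520, 400, 40), c(560, 500, 350, 30))
#' colnames(m) <- c("sleep", "st", "lpa", "mvpa")
#' comp_mean(m)
#' @export
comp_mean <- function(x, kappa = 1440) {
  m <- if (is.data.frame(x)) as.matrix(x) else if (is.matrix(x)) x else rbind(x)
  if (nrow(m) < 1L) stop("need at least one composition")
  check_positive_parts(m)
  g <- exp(colMeans(log(m)))   # per-part geometric means
  close_comp(g, kappa)
}
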