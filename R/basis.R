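#' Sequential binary partitions and ilr contrast matrices
#'
#' An isometric log-ratio (ilr) coordinate system for D-part compositions is
#' defined by a sequential binary partition (SBP): at each of D-1 steps one
#' group of parts is split into a numerator group (+1) and a denominator group
#' (-1). The SBP is encoded as a D x (D-1) sign matrix; the corresponding
#' orthonormal contrast (balance) matrix V satisfies t(V) %*% V = I and
#' colSums(V) = 0, and defines coordinates z = t(V) %*% log(x).
#'
#' `pivot_sbp()` builds the package default: pivot balances in the given part
#' order, where coordinate k contrasts part k against the geometric mean of
#' the remaining parts k+1, ..., D. Any other valid SBP can be supplied as a
#' sign matrix; all downstream results that live on the simplex (compositional
#' means, fitted values, predicted substitution differences) are invariant to
#' this choice.
#'
#' @param parts Character vector of part labels in order, e.g.
#'   `c("sleep", "st", "lpa", "mvpa")`.
#' @name sbp
NULL

#' @rdname sbp
#' @return `pivot_sbp()`: a D x (D-1) sign matrix with entries in \{-1, 0, +1\},
#'   rows named by `parts`.
#' @examples
#' pivot_sbp(c("sleep", "st", "lpa", "mvpa"))
#' @export
pivot_sbp <- function(parts) {
  D <- length(parts)
  if (D < 2L) stop("need at least 2 parts")
  if (anyDuplicated(parts)) stop("part labels must be unique")
  S <- matrix(0L, D, D - 1L, dimnames = list(parts, paste0("ilr", seq_len(D - 1L))))
  for (k in seq_len(D - 1L)) {
    S[k, k] <- 1L
    S[(k + 1L):D, k] <- -1L
  }
  S
}

#' Build an orthonormal ilr basis from a sign matrix
#'
#' @param sbp A D x (D-1) sign matrix describing a sequential binary
#'   partition (rows = parts, columns = partition steps); entries +1
#'   (numerator), -1 (denominator) or 0 (not involved). Row names are the part
#'   labels.
#' @return An object of class `"ilr_basis"`: a list with elements `parts`
#'   (labels), `sbp` (the sign matrix) and `V` (the D x (D-1) orthonormal
#'   contrast matrix).
#' @examples
#' b <- ilr_basis(pivot_sbp(c("sleep", "st", "lpa", "mvpa")))
#' crossprod(b$V)       # identity
#' colSums(b$V)         # zeros
#' @export
ilr_basis <- function(sbp) {
  if (inherits(sbp, "ilr_basis")) return(sbp)
  sbp <- as.matrix(sbp)
  D <- nrow(sbp)
  if (ncol(sbp) != D - 1L) stop("sign matrix must be D x (D-1)")
  if (is.null(rownames(sbp))) rownames(sbp) <- paste0("part", seq_len(D))
  if (is.null(colnames(sbp))) colnames(sbp) <- paste0("ilr", seq_len(D - 1L))
  if (!all(sbp %in% c(-1, 0, 1))) stop("sign matrix entries must be -1, 0 or +1")
  V <- matrix(0, D, D - 1L, dimnames = dimnames(sbp))
  for (k in seq_len(D - 1L)) {
    r <- sum(sbp[, k] == 1)
    s <- sum(sbp[, k] == -1)
    if (r < 1L || s < 1L)
      stop(sprintf("partition step %d needs at least one +1 and one -1", k))
    V[sbp[, k] == 1, k] <- sqrt(s / (r * (r + s)))
    V[sbp[, k] == -1, k] <- -sqrt(r / (s * (r + s)))
  }
  G <- crossprod(V)
  if (max(abs(G - diag(D - 1L))) > 1e-10)
    stop("sign matrix is not a valid sequential binary partition (non-orthonormal balances)")
  structure(list(parts = rownames(sbp), sbp = sbp, V = V), class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat(sprintf("ilr basis for %d parts: %s\n", length(x$parts),
              paste(x$parts, collapse = ", ")))
  print(round(x$V, 4))
  invisible(x)
}

#' Default ilr basis for a part set
#'
#' Pivot-balance basis in the stated part order; see [pivot_sbp()].
#'
#' @inheritParams pivot_sbp
#' @return An `"ilr_basis"` object.
#' @export
default_basis <- function(parts = behaviour_parts) ilr_basis(pivot_sbp(parts))

# Coerce a basis argument: ilr_basis, sign matrix, or NULL (-> pivot default
# for the supplied part labels). Checks part labels when both are available.
resolve_basis <- function(basis, parts) {
  if (is.null(basis)) return(default_basis(parts))
  b <- ilr_basis(basis)
  if (!is.null(parts) && !identical(b$parts, as.character(parts))) {
    if (length(b$parts) != length(parts))
      stop("basis dimension does not match the number of parts")
    if (!setequal(b$parts, parts) && !all(grepl("^part[0-9]+$", b$parts)))
      stop("basis part labels do not match the composition's parts")
  }
  b
}
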