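#' Multi-regional input-output table
#'
#' Container for a balanced multi-region, multi-sector economy: the
#' intermediate-flow matrix \code{Z} (one row/column per region-sector pair,
#' region-major order), the final-demand matrix \code{Fd} (one column per
#' destination region), the primary-input vector \code{v} and the total-output
#' vector \code{x}. Two balance identities must hold: each row of \code{Z}
#' plus the row's final demand equals total output (row balance), and each
#' column of \code{Z} plus primary input equals total output (column balance).
#'
#' @param Z numeric matrix, RS x RS, intermediate monetary flows
#'   \eqn{z_{ij}^{mn}} from sector i in region m (row) to sector j in region n
#'   (column).
#' @param Fd numeric matrix, RS x R, final demand of destination region n
#'   (column) for products of sector i in region m (row).
#' @param v numeric vector, length RS, primary input per region-sector.
#' @param x numeric vector, length RS, total output per region-sector.
#' @param regions character vector of region labels.
#' @param sectors character vector of sector labels.
#' @param deflators optional numeric vector of per-region price indices
#'   (default 1).
#' @param tol relative tolerance for the balance checks.
#' @return An object of class \code{mrio_table}.
#' @seealso [input_coefficients()], [deflate()], [consumption_based()]
#' @export
mrio_table <- function(Z, Fd, v, x, regions, sectors,
                       deflators = rep(1, length(regions)), tol = 1e-8) {
  Z  <- as.matrix(Z)
  Fd <- as.matrix(Fd)
  R <- length(regions)
  S <- length(sectors)
  RS <- R * S
  stopifnot(nrow(Z) == RS, ncol(Z) == RS,
            nrow(Fd) == RS, ncol(Fd) == R,
            length(v) == RS, length(x) == RS,
            length(deflators) == R)
  if (any(Z < 0) || any(Fd < 0) || any(v < -tol * max(x, 1)) || any(x < 0))
    stop("mrio_table entries must be nonnegative")
  lab <- rs_labels(regions, sectors)
  dimnames(Z) <- list(lab, lab)
  dimnames(Fd) <- list(lab, regions)
  names(v) <- lab
  names(x) <- lab
  obj <- structure(
    list(Z = Z, Fd = Fd, v = pmax(v, 0), x = x,
         regions = regions, sectors = sectors, deflators = deflators),
    class = "mrio_table")
  check_mrio_balance(obj, tol = tol)
  obj
}

rs_labels <- function(regions, sectors) {
  as.vector(t(outer(regions, sectors, paste, sep = ".")))
}

#' Verify the two MRIO balance identities
#'
#' @param t an \code{mrio_table}.
#' @param tol relative tolerance.
#' @return invisibly \code{TRUE}; errors if either identity fails.
#' @export
check_mrio_balance <- function(t, tol = 1e-8) {
  scale <- max(abs(t$x), 1)
  row_gap <- max(abs(t$x - (rowSums(t$Z) + rowSums(t$Fd))))
  col_gap <- max(abs(t$x - (colSums(t$Z) + t$v)))
  if (row_gap > tol * scale)
    stop(sprintf("MRIO row balance violated (max gap %.3g)", row_gap))
  if (col_gap > tol * scale)
    stop(sprintf("MRIO column balance violated (max gap %.3g)", col_gap))
  invisible(TRUE)
}

#' @export
print.mrio_table <- function(x, ...) {
  cat(sprintf("MRIO table: %d regions x %d sectors (%d flows)\n",
              length(x$regions), length(x$sectors), length(x$x)^2))
  cat(sprintf("  total output %.4g, final demand %.4g, primary input %.4g\n",
              sum(x$x), sum(x$Fd), sum(x$v)))
  invisible(x)
}

#' Direct input (technical) coefficient matrix A
#'
#' \eqn{a_{ij}^{mn} = z_{ij}^{mn} / x_j^n}: intermediate use per monetary unit
#' of the purchasing sector's output. Columns with zero total output are set
#' to zero rather than raising an error, so empty sectors are tolerated.
#'
#' @param t an \code{mrio_table}.
#' @return RS x RS matrix A.
#' @export
input_coefficients <- function(t) {
  inv_x <- ifelse(t$x > 0, 1 / t$x, 0)
  sweep(t$Z, 2, inv_x, `*`)
}

#' Direct output (allocation) coefficient matrix B
#'
#' \eqn{b_{ij}^{mn} = z_{ij}^{mn} / x_i^m}: row-wise division by the selling
#' sector's output (Ghosh convention). Zero-output rows give zero rows.
#'
#' @param t an \code{mrio_table}.
#' @return RS x RS matrix B.
#' @export
output_coefficients <- function(t) {
  inv_x <- ifelse(t$x > 0, 1 / t$x, 0)
  sweep(t$Z, 1, inv_x, `*`)
}

#' Leontief inverse (I - A)^-1
#'
#' Computed by direct solve; requires a productive economy (spectral radius of
#' A strictly below 1), otherwise the Neumann series diverges and the
#' economy-wide multipliers are meaningless.
#'
#' @param A direct input coefficient matrix.
#' @return matrix L with L = I + A L.
#' @export
leontief_inverse <- function(A) {
  productive_inverse(A, "Leontief")
}

#' Ghosh inverse (I - B)^-1
#'
#' @param B direct output coefficient matrix.
#' @return matrix G with G = I + B G.
#' @export
ghosh_inverse <- function(B) {
  productive_inverse(B, "Ghosh")
}

productive_inverse <- function(M, label) {
  M <- as.matrix(M)
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12)
    stop(sprintf(
      "%s inverse undefined: spectral radius %.4f >= 1 (non-productive economy)",
      label, rho))
  solve(diag(nrow(M)) - M)
}

#' Re-express an MRIO table in base-year prices (double deflation)
#'
#' Each monetary flow is divided by the price deflator of its origin region
#' (the region of the selling sector), then total output is recomputed from
#' the row balance and primary input from the column balance, so both balance
#' identities hold exactly in the deflated table. A uniform deflator rescales
#' every entry and leaves the coefficient matrices, and hence the Leontief and
#' Ghosh inverses, unchanged.
#'
#' @param t an \code{mrio_table}.
#' @param deflators numeric vector of per-region price indices (> 0), base
#'   year = 1.
#' @return a balanced \code{mrio_table} in base-year prices.
#' @export
deflate <- function(t, deflators) {
  R <- length(t$regions)
  S <- length(t$sectors)
  stopifnot(length(deflators) == R)
  if (any(deflators <= 0)) stop("deflators must be positive")
  d_rs <- rep(deflators, each = S)
  Z  <- t$Z / d_rs           # rows scaled by origin-region deflator
  Fd <- t$Fd / d_rs
  x  <- rowSums(Z) + rowSums(Fd)
  v  <- x - colSums(Z)
  if (any(v < -1e-8 * max(x, 1)))
    stop("deflation produced negative primary input; deflators inconsistent with table")
  mrio_table(Z, Fd, pmax(v, 0), x, t$regions, t$sectors,
             deflators = rep(1, R))
}
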