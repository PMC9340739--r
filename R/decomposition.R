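#' Six-factor factorization of a perspective emission account
#'
#' Decomposes the account into ordered multiplicative factors whose product
#' is the full (sector-resolved) perspective matrix:
#' \itemize{
#'   \item consumption: \eqn{Q_C = K \cdot Teff \cdot L \cdot M \cdot R \cdot P}
#'     (emissions per energy, energy per output, Leontief inverse, final-demand
#'     share structure, per-capita demand level, population);
#'   \item sale: \eqn{Q_S = K \cdot Teff \cdot L \cdot Z_s \cdot S \cdot P}
#'     with the final-sale structure and level in place of demand;
#'   \item income: \eqn{Q_I = P \cdot W \cdot N \cdot G \cdot Teff \cdot K}
#'     (population, per-capita primary-input level, primary-input structure,
#'     Ghosh inverse, then the intensity split).
#' }
#' Factor slots are named after the driver they represent
#' (\code{emission_factors}, \code{energy_efficiency},
#' \code{production_structure}, \code{demand_structure}, \code{demand_level},
#' \code{population}) so single-driver perturbations map one-to-one onto SDA
#' factors. Energy efficiency is recovered from the fuel table (total energy
#' per unit output) and the emission-factor driver as emissions per unit
#' energy, so \code{K * Teff} reconstructs the intensity u exactly.
#'
#' @param slice one year slice of a \code{world_bundle} (list with
#'   \code{mrio}, \code{fa}, \code{inventory}, \code{mortality}).
#' @param perspective one of "income", "sale", "consumption".
#' @return object of class \code{factor_set}: ordered named list of factor
#'   matrices, the product \code{Q} and bookkeeping labels.
#' @export
build_factors <- function(slice, perspective = c("consumption", "sale",
                                                 "income")) {
  perspective <- match.arg(perspective)
  t <- slice$mrio
  R <- length(t$regions); S <- length(t$sectors); RS <- R * S
  inv <- split_anthropogenic(slice$inventory)$anthropogenic
  e_vec <- as.vector(t(inv$E))
  energy <- as.vector(apply(slice$fa$FC, c(1, 2), sum))  # [R,S] col-major
  energy <- as.vector(t(matrix(energy, R, S)))           # region-major RS
  teff <- ifelse(t$x > 0, energy / t$x, 0)
  kfac <- ifelse(energy > 0, e_vec / energy, 0)
  pop <- slice$mortality$P[, 1]
  if (any(pop <= 0)) stop("zero population in a region with nonzero flows")

  if (perspective == "consumption") {
    ftot <- colSums(t$Fd)
    M <- sweep(t$Fd, 2, ifelse(ftot > 0, ftot, 1), `/`)
    factors <- list(
      emission_factors     = diag(kfac, RS),
      energy_efficiency    = diag(teff, RS),
      production_structure = leontief_inverse(input_coefficients(t)),
      demand_structure     = M,
      demand_level         = diag(ftot / pop, R),
      population           = diag(pop, R))
  } else if (perspective == "sale") {
    yv <- rowSums(t$Fd)
    ytot <- as.vector(rowsum(yv, rep(seq_len(R), each = S)))
    Zs <- matrix(0, RS, R)
    for (m in seq_len(R)) {
      idx <- (m - 1) * S + seq_len(S)
      Zs[idx, m] <- if (ytot[m] > 0) yv[idx] / ytot[m] else 0
    }
    factors <- list(
      emission_factors     = diag(kfac, RS),
      energy_efficiency    = diag(teff, RS),
      production_structure = leontief_inverse(input_coefficients(t)),
      demand_structure     = Zs,
      demand_level         = diag(ytot / pop, R),
      population           = diag(pop, R))
  } else {
    vtot <- as.vector(rowsum(t$v, rep(seq_len(R), each = S)))
    N <- matrix(0, R, RS)
    for (m in seq_len(R)) {
      idx <- (m - 1) * S + seq_len(S)
      N[m, idx] <- if (vtot[m] > 0) t$v[idx] / vtot[m] else 0
    }
    factors <- list(
      population           = diag(pop, R),
      demand_level         = diag(vtot / pop, R),
      demand_structure     = N,
      production_structure = ghosh_inverse(output_coefficients(t)),
      energy_efficiency    = diag(teff, RS),
      emission_factors     = diag(kfac, RS))
  }
  Q <- Reduce(`%*%`, factors)
  structure(list(perspective = perspective, factors = factors, Q = Q,
                 regions = t$regions, sectors = t$sectors,
                 emitting_margin = if (perspective == "income") "cols" else "rows"),
            class = "factor_set")
}

new_decomposition_result <- function(target, perspective, contributions,
                                     matrices, delta, residual,
                                     endpoints = c(0, 1)) {
  structure(list(target = target, perspective = perspective,
                 contributions = contributions, matrices = matrices,
                 delta = delta, residual = residual, endpoints = endpoints),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("%s-change decomposition (%s perspective), years %s -> %s\n",
              x$target, x$perspective, x$endpoints[1], x$endpoints[2]))
  out <- c(x$contributions, delta = x$delta, residual = x$residual)
  print(round(out, 6))
  invisible(x)
}

#' Two-polar structural decomposition
#'
#' For factors \eqn{F_1 \dots F_n} changing from year 0 to year t, the
#' contribution of factor i is the average of the two polar substitution
#' forms
#' \deqn{\Delta_i = \tfrac12 [ F^{(0)}_{<i} \Delta F_i F^{(t)}_{>i}
#'                            + F^{(t)}_{<i} \Delta F_i F^{(0)}_{>i} ],}
#' i.e. prefix at one endpoint with suffix at the other, averaged. Each polar
#' branch telescopes to the total change, so the contributions sum to
#' \eqn{\Delta Q} exactly (zero residual up to floating point).
#'
#' @param f0,f1 \code{factor_set}s for the two endpoint years (same
#'   perspective and shapes).
#' @return a \code{decomposition_result} with one scalar contribution per
#'   factor (grand total over the contribution matrix), the matrices
#'   themselves, the total change and the (machine-zero) residual.
#' @export
two_polar_sda <- function(f0, f1) {
  if (f0$perspective != f1$perspective) stop("perspective mismatch")
  F0 <- f0$factors; F1 <- f1$factors
  n <- length(F0)
  if (!all(mapply(function(a, b) all(dim(a) == dim(b)), F0, F1)))
    stop("factor shape mismatch")
  mats <- vector("list", n); names(mats) <- names(F0)
  for (i in seq_len(n)) {
    dF <- F1[[i]] - F0[[i]]
    pre0 <- chain_prod(F0, seq_len(i - 1))
    pre1 <- chain_prod(F1, seq_len(i - 1))
    suf0 <- chain_prod(F0, if (i < n) (i + 1):n else integer())
    suf1 <- chain_prod(F1, if (i < n) (i + 1):n else integer())
    mats[[i]] <- 0.5 * (mat_chain(pre0, dF, suf1) + mat_chain(pre1, dF, suf0))
  }
  delta <- sum(f1$Q) - sum(f0$Q)
  contributions <- vapply(mats, sum, numeric(1))
  new_decomposition_result("emissions", f0$perspective, contributions, mats,
                           delta, delta - sum(contributions))
}

chain_prod <- function(fs, idx) if (length(idx)) Reduce(`%*%`, fs[idx]) else NULL
mat_chain <- function(pre, mid, suf) {
  out <- mid
  if (!is.null(pre)) out <- pre %*% out
  if (!is.null(suf)) out <- out %*% suf
  out
}

#' Full-average structural decomposition (all n! orderings)
#'
#' Enumeration oracle: averages the elementary first-order decomposition over
#' every substitution ordering of the factors. Complete for any n; coincides
#' with the two-polar form for n = 2 (the two polar forms are then the only
#' forms). Intended for cross-checks at n <= 6 (720 orderings).
#'
#' @inheritParams two_polar_sda
#' @param max_n refuse to enumerate beyond this many factors.
#' @return a \code{decomposition_result}.
#' @export
full_average_sda <- function(f0, f1, max_n = 7) {
  if (f0$perspective != f1$perspective) stop("perspective mismatch")
  F0 <- f0$factors; F1 <- f1$factors
  n <- length(F0)
  if (n > max_n) stop("too many factors to enumerate")
  perms <- all_permutations(n)
  mats <- rep(list(f0$Q * 0), n)
  names(mats) <- names(F0)
  for (p in seq_len(nrow(perms))) {
    at_t <- rep(FALSE, n)
    for (j in seq_len(n)) {
      i <- perms[p, j]
      term <- vector("list", n)
      for (q in seq_len(n))
        term[[q]] <- if (q == i) F1[[i]] - F0[[i]]
                     else if (at_t[q]) F1[[q]] else F0[[q]]
      mats[[i]] <- mats[[i]] + Reduce(`%*%`, term)
      at_t[i] <- TRUE
    }
  }
  nf <- nrow(perms)
  mats <- lapply(mats, function(m) m / nf)
  delta <- sum(f1$Q) - sum(f0$Q)
  contributions <- vapply(mats, sum, numeric(1))
  new_decomposition_result("emissions", f0$perspective, contributions, mats,
                           delta, delta - sum(contributions))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# Aggregate an SDA contribution matrix to per-emitting-region totals.
emitting_region_totals <- function(mat, margin, R, S) {
  grp <- rep(seq_len(R), each = S)
  if (margin == "rows") as.vector(rowsum(rowSums(mat), grp))
  else as.vector(rowsum(colSums(mat), grp))
}
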