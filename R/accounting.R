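#' Emission intensity vector
#'
#' Emissions per monetary unit of output, \eqn{u_i^m = E_i^m / x_i^m}, the
#' link between the physical inventory and the monetary table. Sectors with
#' zero output get zero intensity (they also emit nothing in a consistent
#' world).
#'
#' @param inv an \code{emission_inventory} (anthropogenic part).
#' @param t the matching \code{mrio_table}.
#' @return numeric vector u of length RS, region-major order.
#' @export
emission_intensity <- function(inv, t) {
  e <- as.vector(t(inv$E))           # [R, S] -> region-major RS
  u <- ifelse(t$x > 0, e / t$x, 0)
  names(u) <- names(t$x)
  u
}

new_perspective_emissions <- function(Qmat, perspective, regions) {
  dimnames(Qmat) <- list(emitting = regions, driving = regions)
  structure(list(Qmat = Qmat, perspective = perspective, regions = regions),
            class = "perspective_emissions")
}

#' @export
print.perspective_emissions <- function(x, ...) {
  cat(sprintf("%s-based emissions, %d regions, total %.6g\n",
              x$perspective, length(x$regions), sum(x$Qmat)))
  print(round(x$Qmat, 4))
  invisible(x)
}

# Sum a full RS x RS (or RS x R) matrix into region blocks.
region_block_sum <- function(M, R, S, cols_are_regions = FALSE) {
  grp <- rep(seq_len(R), each = S)
  rows <- rowsum(M, grp)
  if (cols_are_regions) return(as.matrix(rows))
  t(rowsum(t(rows), grp))
}

#' Production-based emission account
#'
#' The baseline: emissions attributed to the region where they are released.
#' Returned in the same region-by-region matrix form as the trade
#' perspectives (a diagonal matrix), so all four accounts share one container.
#'
#' @param inv anthropogenic \code{emission_inventory}.
#' @return a \code{perspective_emissions} with perspective "production".
#' @export
production_based <- function(inv) {
  totals <- rowSums(inv$E)
  new_perspective_emissions(diag(totals, nrow = length(totals)),
                            "production", inv$regions)
}

#' Consumption-based emission account
#'
#' \eqn{Q_C = U (I-A)^{-1} F}: emissions released anywhere along the supply
#' chain that serves region n's final consumption. Element \code{Qmat[m, n]}
#' is the mass emitted in region m attributable to final consumption in
#' region n.
#'
#' @param inv anthropogenic \code{emission_inventory}.
#' @param t an \code{mrio_table}.
#' @param L optional precomputed Leontief inverse.
#' @return a \code{perspective_emissions}.
#' @export
consumption_based <- function(inv, t, L = NULL) {
  u <- emission_intensity(inv, t)
  if (is.null(L)) L <- leontief_inverse(input_coefficients(t))
  Qfull <- u * (L %*% t$Fd)             # diag(u) %*% L %*% Fd
  R <- length(t$regions); S <- length(t$sectors)
  Qmat <- region_block_sum(Qfull, R, S, cols_are_regions = TRUE)
  new_perspective_emissions(Qmat, "consumption", t$regions)
}

#' Final-sale-based emission account
#'
#' \eqn{Q_S = U (I-A)^{-1} Y} with Y the diagonal matrix of final sales
#' \eqn{y_i^m = \sum_n f_i^{mn}}. Element \code{Qmat[m, n]} is the mass
#' emitted in region m attributable to final sales booked in region n.
#'
#' @inheritParams consumption_based
#' @return a \code{perspective_emissions}.
#' @export
sale_based <- function(inv, t, L = NULL) {
  u <- emission_intensity(inv, t)
  if (is.null(L)) L <- leontief_inverse(input_coefficients(t))
  y <- rowSums(t$Fd)
  Qfull <- u * sweep(L, 2, y, `*`)      # diag(u) %*% L %*% diag(y)
  R <- length(t$regions); S <- length(t$sectors)
  Qmat <- region_block_sum(Qfull, R, S)
  new_perspective_emissions(Qmat, "sale", t$regions)
}

#' Income-based emission account
#'
#' \eqn{Q_I = V (I-B)^{-1} U}: emissions enabled downstream by region n's
#' primary inputs (the supply-side, Ghosh view). In the full matrix the V
#' index carries the driving (income-receiving) region and the U index the
#' emitting region; the aggregated \code{Qmat[m, n]} keeps the package-wide
#' convention (row = emitting region m, column = driving region n).
#'
#' @inheritParams consumption_based
#' @param G optional precomputed Ghosh inverse.
#' @return a \code{perspective_emissions}.
#' @export
income_based <- function(inv, t, G = NULL) {
  u <- emission_intensity(inv, t)
  if (is.null(G)) G <- ghosh_inverse(output_coefficients(t))
  Qfull <- t$v * sweep(G, 2, u, `*`)    # diag(v) %*% G %*% diag(u)
  R <- length(t$regions); S <- length(t$sectors)
  Qdrv <- region_block_sum(Qfull, R, S) # row = driving, col = emitting
  new_perspective_emissions(t(Qdrv), "income", t$regions)
}

#' All four emission accounts at once
#'
#' @inheritParams consumption_based
#' @return named list of \code{perspective_emissions} (income, production,
#'   sale, consumption).
#' @export
all_perspectives <- function(inv, t) {
  A <- input_coefficients(t)
  L <- leontief_inverse(A)
  G <- ghosh_inverse(output_coefficients(t))
  list(income      = income_based(inv, t, G = G),
       production  = production_based(inv),
       sale        = sale_based(inv, t, L = L),
       consumption = consumption_based(inv, t, L = L))
}

#' Aggregate a perspective matrix to macro-regions
#'
#' Block sums under a total mapping from fine regions to macro-regions; the
#' grand total is invariant.
#'
#' @param Q a \code{perspective_emissions}.
#' @param mapping named character/integer vector: for each fine region, its
#'   macro-region label.
#' @return a \code{perspective_emissions} over the macro-regions.
#' @export
aggregate_regions <- function(Q, mapping) {
  if (is.null(names(mapping))) names(mapping) <- Q$regions
  missing_r <- setdiff(Q$regions, names(mapping))
  if (length(missing_r))
    stop("unmapped regions: ", paste(missing_r, collapse = ", "))
  grp <- as.character(mapping[Q$regions])
  macro <- unique(grp)
  M <- rowsum(Q$Qmat, grp, reorder = FALSE)
  M <- t(rowsum(t(M), grp, reorder = FALSE))
  new_perspective_emissions(as.matrix(M)[macro, macro, drop = FALSE],
                            Q$perspective, macro)
}

#' Net embodied-emission flows between regions
#'
#' \code{netflow[m, n] = Qmat[m, n] - Qmat[n, m]}: the mass region n's driver
#' causes in region m, net of the reverse. A region whose drivers cause more
#' emissions abroad than foreign drivers cause at home is a net importer of
#' embodied emissions; otherwise a net exporter. Two totals are reported per
#' region: the national net position (column sum of netflow) and the sum of
#' its positive pairwise inflows.
#'
#' @param Q a \code{perspective_emissions} (square matrix).
#' @return list with \code{netflow} (antisymmetric matrix), \code{position}
#'   (net position per region as driver), \code{net_inflow} (sum of positive
#'   pairwise flows per region), and \code{role} ("importer"/"exporter"/
#'   "balanced").
#' @export
net_flows <- function(Q) {
  M <- Q$Qmat
  if (nrow(M) != ncol(M)) stop("net_flows requires a square Qmat")
  netflow <- M - t(M)
  position <- colSums(netflow)          # region as driver
  net_inflow <- apply(pmax(netflow, 0), 2, sum)
  role <- ifelse(position > 0, "importer",
                 ifelse(position < 0, "exporter", "balanced"))
  list(netflow = netflow, position = position,
       net_inflow = net_inflow, role = role,
       perspective = Q$perspective)
}
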