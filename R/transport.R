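#' Region mask, spatial weights and population weights on a lat-lon grid
#'
#' The mask assigns every cell to a region; \code{weights} spreads each
#' region's emissions over its cells (sums to 1 within each region);
#' \code{pop_weights} does the same for population. Cell-center registered.
#'
#' @param mask integer matrix (nlat x nlon), region index per cell.
#' @param weights nonnegative matrix, per-region sums must be 1.
#' @param pop_weights nonnegative matrix, per-region sums must be 1.
#' @param regions region labels.
#' @return object of class \code{region_grid}.
#' @export
region_grid <- function(mask, weights, pop_weights, regions) {
  stopifnot(all(dim(mask) == dim(weights)), all(dim(mask) == dim(pop_weights)))
  for (m in seq_along(regions)) {
    for (W in list(weights, pop_weights)) {
      s <- sum(W[mask == m])
      if (abs(s - 1) > 1e-6)
        stop(sprintf("weights for region %d sum to %.6f, not 1", m, s))
    }
  }
  structure(list(mask = mask, weights = weights, pop_weights = pop_weights,
                 regions = regions),
            class = "region_grid")
}

#' Linear source-receptor transfer kernel
#'
#' A nonnegative linear operator mapping an annual emission grid (mass/yr per
#' cell) to an annual-mean surface concentration grid. Represented separably:
#' a circular longitude shift (advection by the prevailing wind of that
#' meteorological year), a truncated-Gaussian blur in both directions
#' (dispersion), and a scalar gain (dilution, mass-to-mixing-ratio
#' conversion). Linearity and nonnegativity hold by construction; the kernel
#' differs between years to mimic meteorological change.
#'
#' @param blur_sigma Gaussian blur scale in grid cells.
#' @param shift eastward circular shift in longitude cells (integer).
#' @param gain scalar concentration produced per unit emission.
#' @param year year tag.
#' @return object of class \code{transfer_kernel}.
#' @export
transfer_kernel <- function(blur_sigma = 1.5, shift = 1, gain = 1e-7,
                            year = NA) {
  stopifnot(blur_sigma >= 0, gain >= 0)
  structure(list(blur_sigma = blur_sigma, shift = as.integer(shift),
                 gain = gain, year = year),
            class = "transfer_kernel")
}

gauss_weights <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w / sum(w)
}

# 1-d convolution along rows (lat, zero padded) and columns (lon, circular).
blur_grid <- function(g, sigma) {
  w <- gauss_weights(sigma)
  if (length(w) == 1) return(g)
  h <- (length(w) - 1L) / 2L
  nlat <- nrow(g); nlon <- ncol(g)
  out <- matrix(0, nlat, nlon)
  for (k in seq_along(w)) {            # latitude, zero padding at the poles
    off <- k - h - 1L
    src <- seq_len(nlat) + off
    ok <- src >= 1 & src <= nlat
    out[ok, ] <- out[ok, ] + w[k] * g[src[ok], ]
  }
  g2 <- matrix(0, nlat, nlon)
  for (k in seq_along(w)) {            # longitude, circular
    off <- k - h - 1L
    src <- ((seq_len(nlon) + off - 1L) %% nlon) + 1L
    g2 <- g2 + w[k] * out[, src]
  }
  g2
}

#' Simulate annual-mean surface concentration for an emission scenario
#'
#' Applies the linear transfer kernel: shift, blur, gain. Exactly linear in
#' the emissions, so scenario concentrations superpose and ratio attribution
#' downstream is consistent.
#'
#' @param em an \code{emission_grid}.
#' @param k a \code{transfer_kernel}.
#' @return a \code{concentration_field}: matrix (ug m^-3) with scenario/year
#'   attributes.
#' @export
simulate_concentration <- function(em, k) {
  g <- unclass(em)
  attributes(g) <- list(dim = dim(em))
  nlon <- ncol(g)
  if (k$shift %% nlon != 0) {
    s <- k$shift %% nlon
    g <- g[, c((nlon - s + 1):nlon, 1:(nlon - s)), drop = FALSE]
  }
  conc <- k$gain * blur_grid(g, k$blur_sigma)
  structure(conc, scenario = attr(em, "scenario"), year = k$year,
            class = c("concentration_field", "matrix", "array"))
}

#' Fractional contribution of a scenario to the base concentration
#'
#' Per-cell ratio scenario/base, with cells where the base concentration is
#' zero set to 0 (they contribute no deaths). If a set of scenarios'
#' emissions partitions the base emissions, the fractions sum to 1 wherever
#' the base is positive, by linearity of the kernel.
#'
#' @param scenario,base \code{concentration_field}s on the same grid.
#' @return matrix of fractions.
#' @export
scenario_fraction <- function(scenario, base) {
  if (!all(dim(scenario) == dim(base))) stop("grid mismatch")
  ifelse(base > 0, as.matrix(scenario) / as.matrix(base), 0)
}
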