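#' Unit-relative-risk table
#'
#' Lifetime lung-cancer unit relative risk at a cumulative BaP exposure of
#' 100 ug m^-3 years, by macro-area. Literature values: Asia 1.3, Europe
#' 1.13, North America 1.16; everywhere else takes the world average 1.2.
#'
#' @param values named numeric vector of URR values (all >= 1); must include
#'   a "world" entry used as the default.
#' @param region_area named character vector mapping region labels to areas;
#'   regions absent from the map take "world".
#' @return object of class \code{urr_table}.
#' @export
urr_table <- function(values = c(asia = 1.3, europe = 1.13,
                                 north_america = 1.16, world = 1.2),
                      region_area = character()) {
  if (any(values < 1)) stop("URR values must be >= 1")
  if (!"world" %in% names(values)) stop("URR table needs a 'world' default")
  structure(list(values = values, region_area = region_area),
            class = "urr_table")
}

urr_for_region <- function(urr, region) {
  area <- urr$region_area[region]
  area[is.na(area)] <- "world"
  unname(urr$values[area])
}

#' Per-region lung-cancer-rate and population series
#'
#' 70-year horizon: \code{LR[m, y]} lung-cancer deaths per 100,000 people per
#' year, \code{P[m, y]} population, for region m and horizon year y.
#'
#' @param LR nonnegative matrix, regions x 70.
#' @param P nonnegative matrix, regions x 70.
#' @param regions region labels.
#' @return object of class \code{mortality_series}.
#' @export
mortality_series <- function(LR, P, regions) {
  stopifnot(ncol(LR) == 70, ncol(P) == 70,
            nrow(LR) == length(regions), nrow(P) == length(regions))
  if (any(LR < 0) || any(P < 0)) stop("rates and population must be >= 0")
  structure(list(LR = LR, P = P, regions = regions),
            class = "mortality_series")
}

#' Relative risk grid from a concentration field
#'
#' Constant lifetime exposure assumption: rr = URR^(c * 70 / 100), i.e. the
#' unit relative risk raised to the cumulative exposure (70 years at
#' concentration c) expressed in units of 100 ug m^-3 years. At
#' c = 100/70 ug m^-3 the cumulative exposure is exactly 100 ug m^-3 years
#' and rr reproduces the tabulated URR.
#'
#' @param conc a \code{concentration_field} (ug m^-3).
#' @param urr a \code{urr_table}.
#' @param grid a \code{region_grid} giving each cell's region (hence area).
#' @param lifetime exposure duration in years (default 70).
#' @return matrix of relative risks (>= 1).
#' @export
relative_risk <- function(conc, urr, grid, lifetime = 70) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  base <- matrix(urr$values["world"], nrow(conc), ncol(conc))
  for (m in seq_along(grid$regions))
    base[grid$mask == m] <- urr_for_region(urr, grid$regions[m])
  base ^ (as.matrix(conc) * lifetime / 100)
}

#' Population attributable fraction
#'
#' PAF = (rr - 1) / rr: the share of lung-cancer deaths attributable to the
#' exposure. Stored as a fraction in [0, 1); formatted as percent only at
#' reporting time.
#'
#' @param rr matrix of relative risks (>= 1).
#' @return matrix of PAF values.
#' @export
paf <- function(rr) {
  if (any(rr < 1 - 1e-12)) stop("relative risks must be >= 1")
  (rr - 1) / rr
}

#' Lifetime lung-cancer deaths per grid cell and region
#'
#' Per cell: D = PAF x (70-year sum of regional lung-cancer deaths,
#' LR/100000 x P) distributed over the region's cells with the population
#' weights. Regional burdens are the masked grid sums.
#'
#' @param paf_grid matrix of attributable fractions.
#' @param ms a \code{mortality_series}.
#' @param grid a \code{region_grid}.
#' @param scenario scenario tag carried in the result.
#' @return object of class \code{burden_field}: list with \code{D} (grid of
#'   deaths), \code{regional} (named per-region sums), \code{total}.
#' @export
lifetime_deaths <- function(paf_grid, ms, grid, scenario = "base") {
  R <- length(grid$regions)
  if (nrow(ms$LR) != R) stop("mortality table does not cover all regions")
  ld_region <- rowSums(ms$LR / 1e5 * ms$P)  # 70-yr deaths per region
  ld_cell <- matrix(0, nrow(grid$mask), ncol(grid$mask))
  for (m in seq_len(R)) {
    sel <- grid$mask == m
    ld_cell[sel] <- ld_region[m] * grid$pop_weights[sel]
  }
  D <- paf_grid * ld_cell
  regional <- vapply(seq_len(R), function(m) sum(D[grid$mask == m]),
                     numeric(1))
  names(regional) <- grid$regions
  structure(list(D = D, regional = regional, total = sum(D),
                 scenario = scenario),
            class = "burden_field")
}

#' @export
print.burden_field <- function(x, ...) {
  cat(sprintf("lifetime lung-cancer burden [%s]: %.4f deaths\n",
              x$scenario, x$total))
  print(round(x$regional, 4))
  invisible(x)
}

#' Attribute base-case deaths to an emission scenario
#'
#' Scenario deaths = base deaths x per-cell fractional contribution of the
#' scenario concentration to the base concentration. Fractions outside
#' [0, 1] (beyond rounding) indicate an upstream linearity breach and raise a
#' warning.
#'
#' @param base a base-case \code{burden_field}.
#' @param fraction matrix from [scenario_fraction()].
#' @param grid a \code{region_grid}.
#' @param scenario scenario tag.
#' @return a \code{burden_field}.
#' @export
attribute_scenario_deaths <- function(base, fraction, grid,
                                      scenario = "scenario") {
  if (!all(dim(base$D) == dim(fraction))) stop("grid mismatch")
  if (any(fraction < -1e-9) || any(fraction > 1 + 1e-9))
    warning("scenario fractions outside [0, 1]: upstream nonlinearity?")
  D <- base$D * fraction
  regional <- vapply(seq_along(grid$regions),
                     function(m) sum(D[grid$mask == m]), numeric(1))
  names(regional) <- grid$regions
  structure(list(D = D, regional = regional, total = sum(D),
                 scenario = scenario),
            class = "burden_field")
}
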