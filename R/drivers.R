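#' Copy one year slice of a world onto another year
#'
#' Sets every primitive factor of year \code{to} equal to that of year
#' \code{from} and re-derives the slice, producing a world whose two years
#' are identical. Combined with [perturb_factor()] this builds single-driver
#' worlds: clone, then scale exactly one factor in one year.
#'
#' @param bundle a \code{world_bundle}.
#' @param from,to year indices.
#' @return a \code{world_bundle}.
#' @export
clone_year <- function(bundle, from, to) {
  prim <- bundle$primitives
  for (f in c("A", "Mshare", "demand_level", "pop", "energy_int", "ef",
              "lr", "kernel"))
    prim[[f]][[to]] <- prim[[f]][[from]]
  bundle$primitives <- prim
  bundle$years[[to]] <- derive_year_slice(prim, to)
  bundle
}

# Total lifetime deaths for a set of per-region anthropogenic emission
# totals, evaluated in a given meteorological year (kernel) and mortality
# year. `dose_response = "linear"` replaces the exponential dose-response by
# its tangent at zero exposure, PAF_lin = ln(URR) * lifetime/100 * c, making
# deaths exactly linear in emissions (test/diagnostic mode).
deaths_for_emissions <- function(bundle, emis_regions, kernel_year,
                                 mortality_year, urr = urr_table(),
                                 dose_response = "nonlinear",
                                 include_natural = TRUE) {
  grid <- bundle$grid
  nat <- if (include_natural) bundle$primitives$natural else 0
  em <- grid_from_totals(pmax(emis_regions + nat, 0), grid)
  conc <- simulate_concentration(em, bundle$years[[kernel_year]]$kernel)
  pg <- paf_grid(conc, urr, grid, dose_response)
  lifetime_deaths(pg, bundle$years[[mortality_year]]$mortality, grid)$total
}

paf_grid <- function(conc, urr, grid, dose_response = "nonlinear",
                     lifetime = 70) {
  if (dose_response == "linear") {
    base <- matrix(urr$values["world"], nrow(conc), ncol(conc))
    for (m in seq_along(grid$regions))
      base[grid$mask == m] <- urr_for_region(urr, grid$regions[m])
    log(base) * (lifetime / 100) * as.matrix(conc)
  } else {
    paf(relative_risk(conc, urr, grid, lifetime))
  }
}

#' Decompose the change in lifetime lung-cancer deaths into drivers
#'
#' Splits the death change between two years into contributions of each
#' socioeconomic emission driver (via the SDA emission contributions run
#' through the transport and risk stages), meteorological change (kernel
#' year), and baseline lung-cancer mortality change, with an explicit
#' residual:
#' \itemize{
#'   \item per socioeconomic driver \eqn{\theta}: the forward/backward
#'     average \eqn{\Delta D_{Q_\theta} = \tfrac12[ (D_{0,Q_0+\Delta Q_\theta}
#'     - D_{0,Q_0}) + (D_{t,Q_t} - D_{t,Q_t-\Delta Q_\theta}) ]}, each D
#'     evaluated in its own year's full context;
#'   \item meteorology: \eqn{\Delta D_{MC} = \tfrac12[(D_{t,Q_0}-D_{0,Q_0})
#'     + (D_{t,Q_t}-D_{0,Q_t})]}, importing the same emissions into the two
#'     kernel years while mortality is held at a fixed reference year;
#'   \item mortality: \eqn{\Delta D_{LD}}, the analogous average over the two
#'     years' PAF fields with only the mortality year varying.
#' }
#' The sum of terms is not forced to close: the dose-response is nonlinear,
#' and the reported residual is the honest gap
#' \eqn{\Delta D - (\Delta D_{LD} + \Delta D_{MC} + \sum_\theta
#' \Delta D_{Q_\theta})}.
#'
#' @param bundle a \code{world_bundle}.
#' @param year0,year1 endpoint year indices.
#' @param perspective SDA perspective for the emission drivers.
#' @param urr a \code{urr_table}.
#' @param mortality_ref reference year for the mortality series when
#'   evaluating the meteorology term (default \code{year0}).
#' @param dose_response "nonlinear" (default PAF) or "linear" (tangent
#'   dose-response; with \code{fix_kernel} and \code{fix_mortality} the
#'   decomposition is then exact).
#' @param fix_kernel,fix_mortality hold the kernel / mortality at
#'   \code{year0} in every evaluation (diagnostic linear-limit mode).
#' @return a \code{decomposition_result} with target "deaths": one
#'   contribution per SDA factor plus \code{meteorology} and
#'   \code{mortality_rate}, the total change and the residual.
#' @export
health_driver_decomposition <- function(bundle, year0 = 1, year1 = 2,
                                        perspective = "consumption",
                                        urr = urr_table(),
                                        mortality_ref = year0,
                                        dose_response = "nonlinear",
                                        fix_kernel = FALSE,
                                        fix_mortality = FALSE) {
  R <- bundle$spec$n_regions; S <- bundle$spec$n_sectors
  f0 <- build_factors(bundle$years[[year0]], perspective)
  f1 <- build_factors(bundle$years[[year1]], perspective)
  sda <- two_polar_sda(f0, f1)
  dQ <- lapply(sda$matrices, emitting_region_totals,
               margin = f0$emitting_margin, R = R, S = S)

  Q0 <- rowSums(split_anthropogenic(bundle$years[[year0]]$inventory)$anthropogenic$E)
  Qt <- rowSums(split_anthropogenic(bundle$years[[year1]]$inventory)$anthropogenic$E)
  k0 <- year0; kt <- if (fix_kernel) year0 else year1
  m0 <- year0; mt <- if (fix_mortality) year0 else year1
  D <- function(q, ky, my) deaths_for_emissions(bundle, q, ky, my, urr,
                                                dose_response)

  D000 <- D(Q0, k0, m0)
  Dttt <- D(Qt, kt, mt)
  contrib <- vapply(dQ, function(dq) {
    0.5 * ((D(Q0 + dq, k0, m0) - D000) + (Dttt - D(Qt - dq, kt, mt)))
  }, numeric(1))

  mref <- if (fix_mortality) year0 else mortality_ref
  d_mc <- 0.5 * ((D(Q0, kt, mref) - D(Q0, k0, mref)) +
                 (D(Qt, kt, mref) - D(Qt, k0, mref)))

  paf_for_year <- function(y, ky) {
    grid <- bundle$grid
    em <- grid_from_totals(
      rowSums(split_anthropogenic(bundle$years[[y]]$inventory)$anthropogenic$E) +
        bundle$primitives$natural, grid)
    conc <- simulate_concentration(em, bundle$years[[ky]]$kernel)
    paf_grid(conc, urr, grid, dose_response)
  }
  dl <- function(pg, my)
    lifetime_deaths(pg, bundle$years[[my]]$mortality, bundle$grid)$total
  p0 <- paf_for_year(year0, k0)
  pt <- paf_for_year(year1, kt)
  d_ld <- 0.5 * ((dl(p0, mt) - dl(p0, m0)) + (dl(pt, mt) - dl(pt, m0)))

  delta <- Dttt - D000
  contributions <- c(contrib, meteorology = d_mc, mortality_rate = d_ld)
  new_decomposition_result("deaths", perspective, contributions,
                           matrices = NULL, delta = delta,
                           residual = delta - sum(contributions),
                           endpoints = c(year0, year1))
}
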