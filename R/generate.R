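#' Specification of a synthetic world
#'
#' Describes the dimensions and embedded structure of a generated test world:
#' a balanced multi-region multi-sector economy, gridded spatial fields,
#' year-dependent transfer kernels and mortality series. Producer regions are
#' built emission-intensive and export-oriented; consumer regions are built
#' demand-heavy, so consumers are net importers of embodied emissions by
#' construction.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_sectors number of sectors per region (>= 2).
#' @param grid_shape integer pair (nlat, nlon).
#' @param n_years number of year slices (>= 2).
#' @param seed integer RNG seed; a fixed seed gives bit-identical worlds.
#' @param producer_regions,consumer_regions disjoint region-index sets.
#' @param ef_sigma lognormal sdlog of emission-factor uncertainty.
#' @return object of class \code{world_spec}.
#' @export
world_spec <- function(n_regions = 4, n_sectors = 5, grid_shape = c(18, 36),
                       n_years = 2, seed = 1,
                       producer_regions = c(1, 2),
                       consumer_regions = setdiff(seq_len(n_regions),
                                                  producer_regions),
                       ef_sigma = 0.3) {
  stopifnot(n_regions >= 2, n_sectors >= 2, n_years >= 2,
            length(grid_shape) == 2, ef_sigma >= 0)
  producer_regions <- intersect(producer_regions, seq_len(n_regions))
  consumer_regions <- intersect(consumer_regions, seq_len(n_regions))
  if (length(intersect(producer_regions, consumer_regions)))
    stop("producer_regions and consumer_regions must be disjoint")
  structure(list(n_regions = n_regions, n_sectors = n_sectors,
                 grid_shape = as.integer(grid_shape), n_years = n_years,
                 seed = as.integer(seed),
                 producer_regions = producer_regions,
                 consumer_regions = consumer_regions,
                 ef_sigma = ef_sigma),
            class = "world_spec")
}

#' Generate a complete synthetic world
#'
#' Draws the primitive factors of the economy (input-coefficient matrix,
#' final-demand structure and levels, population, energy intensity, emission
#' factors, natural sources, transfer kernels, lung-cancer rates) once, with
#' per-year variation injected into every one of them so each structural
#' decomposition factor has a nonzero true change: emission factors decline,
#' energy efficiency improves, demand levels and population grow, the
#' production and demand structures drift, the kernel's advection shift and
#' gain differ between years, and mortality rates rise. All derived objects
#' (balanced MRIO table, fuel/activity/EF tables, inventory, mortality
#' series) are rebuilt deterministically from the primitives, so
#' [perturb_factor()] can change exactly one primitive and re-derive a
#' consistent world.
#'
#' Balance is guaranteed by construction: the coefficient matrix is rescaled
#' so its column sums stay below 0.6 (hence spectral radius < 0.6 < 0.9 and
#' nonnegative primary input), output solves the Leontief system for the
#' drawn final demand, and intermediate flows are recovered as
#' \code{Z = A diag(x)}.
#'
#' @param spec a \code{world_spec}.
#' @return object of class \code{world_bundle}: per-year slices (each with
#'   \code{mrio}, \code{fa}, \code{ef}, \code{inventory}, \code{kernel},
#'   \code{mortality}), the shared \code{grid}, and the primitive factors.
#' @export
generate_world <- function(spec) {
  prim <- withr_seed(spec$seed, draw_primitives(spec))
  # calibrate natural sources to ~2% of year-1 anthropogenic emissions
  y1 <- derive_year_slice(prim, 1)
  prim$natural <- 0.02 * rowSums(y1$inventory$E)
  years <- lapply(seq_len(spec$n_years), function(y) derive_year_slice(prim, y))
  structure(list(spec = spec, regions = prim$regions, sectors = prim$sectors,
                 grid = prim$grid, years = years, primitives = prim),
            class = "world_bundle")
}

#' @export
print.world_bundle <- function(x, ...) {
  s <- x$spec
  cat(sprintf("synthetic world: %d regions x %d sectors, %dx%d grid, %d years\n",
              s$n_regions, s$n_sectors, s$grid_shape[1], s$grid_shape[2],
              s$n_years))
  invisible(x)
}

draw_primitives <- function(spec) {
  R <- spec$n_regions; S <- spec$n_sectors; RS <- R * S
  regions <- paste0("R", seq_len(R))
  sectors <- paste0("S", seq_len(S))
  role <- rep("other", R)
  role[spec$producer_regions] <- "producer"
  role[spec$consumer_regions] <- "consumer"
  rs_region <- rep(seq_len(R), each = S)

  # grid: longitude bands per region, lognormal within-region weights
  nlat <- spec$grid_shape[1]; nlon <- spec$grid_shape[2]
  mask <- matrix(rep(pmin(ceiling(seq_len(nlon) * R / nlon), R),
                     each = nlat), nlat, nlon)
  norm_in_region <- function(W) {
    for (m in seq_len(R)) W[mask == m] <- W[mask == m] / sum(W[mask == m])
    W
  }
  weights <- norm_in_region(matrix(stats::rlnorm(nlat * nlon, 0, 1), nlat, nlon))
  pop_w <- norm_in_region(matrix(stats::rlnorm(nlat * nlon, 0, 1), nlat, nlon))
  grid <- region_grid(mask, weights, pop_w, regions)

  # base economy
  A0 <- matrix(stats::rlnorm(RS^2, 0, 0.5), RS, RS)
  intra <- outer(rs_region, rs_region, `==`)
  A0[intra] <- A0[intra] * 2                 # domestic linkages dominate
  cap_colsums <- function(A, target) A * (target / max(colSums(A)))
  M0 <- matrix(stats::rlnorm(RS * R, 0, 0.5), RS, R)
  # consumers import final goods from producers: inflate producer-origin rows
  # of consumer-region demand columns
  prod_rows <- rs_region %in% spec$producer_regions
  M0[prod_rows, spec$consumer_regions] <- M0[prod_rows, spec$consumer_regions] * 4
  norm_cols <- function(M) sweep(M, 2, colSums(M), `/`)

  lvl <- function(base_by_role, noise_sd) {
    base <- c(producer = base_by_role[1], consumer = base_by_role[2],
              other = base_by_role[3])[role]
    unname(base * stats::rlnorm(R, 0, noise_sd))
  }
  r0   <- lvl(c(1.0, 3.0, 1.5), 0.10)        # per-capita final demand level
  pop0 <- 1e6 * stats::rlnorm(R, 0, 0.2)
  lr0  <- 30 * stats::rlnorm(R, 0, 0.1)      # lung-cancer deaths /1e5 /yr
  e_base <- c(producer = 2.0, consumer = 0.8, other = 1.2)[role[rs_region]]
  e0 <- unname(e_base * stats::rlnorm(RS, 0, 0.15))   # energy per output
  k_base <- c(producer = 1.5, consumer = 0.5, other = 0.8)[role[rs_region]]
  k0 <- unname(k_base * stats::rlnorm(RS, 0, 0.15))   # emissions per energy

  jitter_mat <- function(M, sd) M * exp(matrix(stats::rnorm(length(M), 0, sd),
                                               nrow(M)))
  ny <- spec$n_years
  A <- Ms <- vector("list", ny)
  demand_level <- pop <- energy_int <- ef <- lr <- kernel <- vector("list", ny)
  for (y in seq_len(ny)) {
    g <- y - 1                                # years elapsed since base year
    A[[y]]  <- cap_colsums(if (y == 1) A0 else jitter_mat(A0, 0.05 * g),
                           0.55 * 0.97^g)
    Ms[[y]] <- norm_cols(if (y == 1) M0 else jitter_mat(M0, 0.05 * g))
    demand_level[[y]] <- r0 * 1.08^g           # demand level grows
    pop[[y]]          <- pop0 * 1.03^g         # population grows
    energy_int[[y]]   <- e0 * 0.95^g           # efficiency improves
    ef[[y]]           <- k0 * 0.92^g           # emission factors decline
    lr[[y]]           <- lr0 * 1.05^g          # baseline mortality rises
    kernel[[y]] <- transfer_kernel(blur_sigma = 1.5, shift = 2 * y - 1,
                                   gain = 1e-7 * 1.15^g, year = y)
  }
  list(regions = regions, sectors = sectors, role = role,
       rs_region = rs_region, grid = grid, spec = spec,
       A = A, Mshare = Ms, demand_level = demand_level, pop = pop,
       energy_int = energy_int, ef = ef, lr = lr, kernel = kernel,
       natural = rep(0, R))
}

# Deterministically derive one year's full data slice from the primitives.
derive_year_slice <- function(prim, y) {
  spec <- prim$spec
  R <- spec$n_regions; S <- spec$n_sectors; RS <- R * S
  A <- prim$A[[y]]
  Fd <- prim$Mshare[[y]] %*% diag(prim$demand_level[[y]] * prim$pop[[y]],
                                  nrow = R)
  yv <- rowSums(Fd)
  x <- solve(diag(RS) - A, yv)
  Z <- A %*% diag(x)
  v <- x - colSums(Z)
  mrio <- mrio_table(Z, Fd, v, x, prim$regions, prim$sectors)

  # energy and emission tables chosen so E = ef * energy_int * x exactly,
  # with K (emissions/energy) and Teff (energy/output) recoverable factors:
  # two fuels (coal 50%, biomass 30% of emissions) and one process (coke 20%)
  e <- prim$energy_int[[y]]; kap <- prim$ef[[y]]
  to_RS_mat <- function(vec) matrix(vec, R, S, byrow = TRUE)
  FC <- array(0, c(R, S, 2), dimnames = list(prim$regions, prim$sectors,
                                             c("coal", "biomass")))
  FC[, , 1] <- to_RS_mat(0.6 * e * x)
  FC[, , 2] <- to_RS_mat(0.4 * e * x)
  AR <- array(to_RS_mat(0.1 * x), c(R, S, 1),
              dimnames = list(prim$regions, prim$sectors, "coke"))
  EF_fuel <- array(0, c(R, S, 2))
  EF_fuel[, , 1] <- to_RS_mat(0.5 / 0.6 * kap)
  EF_fuel[, , 2] <- to_RS_mat(0.3 / 0.4 * kap)
  EF_proc <- array(to_RS_mat(2 * kap * e), c(R, S, 1))
  fa <- fuel_activity(FC, AR)
  ef_tab <- emission_factors(EF_fuel, EF_proc, sigma = spec$ef_sigma)
  inv <- compute_emissions(fa, ef_tab, natural = prim$natural,
                           regions = prim$regions, sectors = prim$sectors)

  ms <- mortality_series(matrix(prim$lr[[y]], R, 70),
                         matrix(prim$pop[[y]], R, 70), prim$regions)
  list(mrio = mrio, fa = fa, ef = ef_tab, inventory = inv,
       kernel = prim$kernel[[y]], mortality = ms, year = y)
}

#' Scale exactly one primitive factor and re-derive a consistent world
#'
#' Used to build single-driver test worlds: only the named factor of the
#' given year changes; everything derived from it (balanced table, inventory,
#' mortality series) is rebuilt, so all invariants hold in the returned copy.
#' A multiplier of 1 returns an identical bundle.
#'
#' @param bundle a \code{world_bundle}.
#' @param factor_name one of \code{"emission_factors"},
#'   \code{"energy_efficiency"}, \code{"production_structure"},
#'   \code{"demand_structure"}, \code{"demand_level"}, \code{"population"},
#'   \code{"kernel"}, \code{"mortality"}.
#' @param year year index to perturb.
#' @param multiplier scalar scale factor.
#' @return a perturbed \code{world_bundle}.
#' @export
perturb_factor <- function(bundle, factor_name, year, multiplier) {
  known <- c("emission_factors", "energy_efficiency", "production_structure",
             "demand_structure", "demand_level", "population", "kernel",
             "mortality")
  if (!factor_name %in% known)
    stop("unknown factor name: ", factor_name)
  if (multiplier == 1) return(bundle)
  prim <- bundle$primitives
  RS <- length(prim$energy_int[[year]])
  switch(factor_name,
    emission_factors = {
      prim$ef[[year]] <- prim$ef[[year]] * multiplier
    },
    energy_efficiency = {
      prim$energy_int[[year]] <- prim$energy_int[[year]] * multiplier
    },
    production_structure = {
      A <- prim$A[[year]] * multiplier
      if (max(colSums(A)) >= 0.95)
        stop("production_structure multiplier makes the economy non-productive")
      prim$A[[year]] <- A
    },
    demand_structure = {
      M <- prim$Mshare[[year]]
      tilt <- seq_len(nrow(M)) <= RS / 2
      M[tilt, ] <- M[tilt, ] * multiplier
      prim$Mshare[[year]] <- sweep(M, 2, colSums(M), `/`)
    },
    demand_level = {
      prim$demand_level[[year]] <- prim$demand_level[[year]] * multiplier
    },
    population = {
      prim$pop[[year]] <- prim$pop[[year]] * multiplier
    },
    kernel = {
      k <- prim$kernel[[year]]
      prim$kernel[[year]] <- transfer_kernel(k$blur_sigma, k$shift,
                                             k$gain * multiplier, k$year)
    },
    mortality = {
      prim$lr[[year]] <- prim$lr[[year]] * multiplier
    },
    stop("unknown factor name: ", factor_name)
  )
  bundle$primitives <- prim
  bundle$years[[year]] <- derive_year_slice(prim, year)
  bundle
}
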