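#' Fuel-consumption and activity-rate table
#'
#' \code{FC[m, i, k]}: fuel consumed by region m, sector i, energy type k.
#' \code{AR[m, i, p]}: activity rate (product output) by industrial process p.
#'
#' @param FC 3-d nonnegative array (region, sector, energy type).
#' @param AR 3-d nonnegative array (region, sector, process).
#' @return object of class \code{fuel_activity}.
#' @export
fuel_activity <- function(FC, AR) {
  stopifnot(length(dim(FC)) == 3, length(dim(AR)) == 3,
            all(dim(FC)[1:2] == dim(AR)[1:2]))
  if (any(FC < 0) || any(AR < 0)) stop("fuel/activity entries must be >= 0")
  structure(list(FC = FC, AR = AR), class = "fuel_activity")
}

#' Emission-factor table
#'
#' Region- and source-specific emission factors: \code{EF_fuel[m, i, k]}
#' (emissions per unit fuel) and \code{EF_proc[m, i, p]} (emissions per unit
#' product), with a lognormal uncertainty scale per region-sector-source.
#' The inventory carries a species label; benzo[a]pyrene (BaP) is the default
#' and the only species propagated to transport and health.
#'
#' @param EF_fuel 3-d nonnegative array matching \code{FC}.
#' @param EF_proc 3-d nonnegative array matching \code{AR}.
#' @param sigma lognormal sdlog of the emission factors, either a scalar or an
#'   array conformable with the EF arrays.
#' @param species species label.
#' @return object of class \code{emission_factors}.
#' @export
emission_factors <- function(EF_fuel, EF_proc, sigma = 0, species = "BaP") {
  stopifnot(length(dim(EF_fuel)) == 3, length(dim(EF_proc)) == 3)
  if (any(EF_fuel < 0) || any(EF_proc < 0) || any(sigma < 0))
    stop("emission factors and sigma must be >= 0")
  structure(list(EF_fuel = EF_fuel, EF_proc = EF_proc,
                 sigma = sigma, species = species),
            class = "emission_factors")
}

new_emission_inventory <- function(E, natural, regions, sectors,
                                   species = "BaP") {
  dimnames(E) <- list(regions, sectors)
  structure(list(E = E, natural = stats::setNames(natural, regions),
                 regions = regions, sectors = sectors, species = species),
            class = "emission_inventory")
}

#' @export
print.emission_inventory <- function(x, ...) {
  cat(sprintf("%s emission inventory: %d regions x %d sectors\n",
              x$species, nrow(x$E), ncol(x$E)))
  cat(sprintf("  anthropogenic %.6g, natural %.6g\n",
              sum(x$E), sum(x$natural)))
  invisible(x)
}

#' Production-based emission inventory
#'
#' Sum-of-products inventory equation: for each region m and sector i,
#' \deqn{E_{i,m} = \sum_k FC_{i,m}^k EF_{i,m}^k + \sum_p AR_{i,m}^p EF_{i,m}^p.}
#' Exact arithmetic; no smoothing, no allocation.
#'
#' @param fa a \code{fuel_activity} table.
#' @param ef an \code{emission_factors} table with matching index sets.
#' @param natural per-region natural-source emissions (deforestation,
#'   wildfire), not sector-resolved; excluded from the MRIO linkage
#'   downstream. Default zero.
#' @param regions,sectors labels; defaults taken from dimnames or generated.
#' @return an \code{emission_inventory}.
#' @export
compute_emissions <- function(fa, ef, natural = NULL,
                              regions = NULL, sectors = NULL) {
  if (!all(dim(fa$FC) == dim(ef$EF_fuel)) || !all(dim(fa$AR) == dim(ef$EF_proc)))
    stop("index sets of fuel/activity and emission-factor tables disagree")
  E <- apply(fa$FC * ef$EF_fuel, c(1, 2), sum) +
       apply(fa$AR * ef$EF_proc, c(1, 2), sum)
  R <- nrow(E); S <- ncol(E)
  if (is.null(regions)) regions <- dimnames(fa$FC)[[1]] %||% paste0("R", seq_len(R))
  if (is.null(sectors)) sectors <- dimnames(fa$FC)[[2]] %||% paste0("S", seq_len(S))
  if (is.null(natural)) natural <- rep(0, R)
  new_emission_inventory(E, natural, regions, sectors, species = ef$species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo confidence interval for inventory totals
#'
#' Emission factors are drawn multiplicatively from a lognormal with median at
#' the point estimate and sdlog equal to the table's \code{sigma}; the
#' inventory total is recomputed for each draw and an empirical central
#' interval returned. Reproducible for a fixed seed.
#'
#' @param fa a \code{fuel_activity} table.
#' @param ef an \code{emission_factors} table.
#' @param n_draws number of Monte-Carlo draws (>= 2).
#' @param seed integer RNG seed.
#' @param level interval coverage level (default 0.95).
#' @return list with \code{point} (total at the point EF), \code{lower},
#'   \code{upper}, \code{level}, \code{draws} (vector of sampled totals).
#' @export
monte_carlo_ci <- function(fa, ef, n_draws = 1000, seed = 1, level = 0.95) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  point <- sum(compute_emissions(fa, ef)$E)
  nf <- length(ef$EF_fuel); np <- length(ef$EF_proc)
  sig <- ef$sigma
  sig_f <- if (length(sig) == 1) rep(sig, nf) else rep(as.vector(sig), length.out = nf)
  sig_p <- if (length(sig) == 1) rep(sig, np) else rep(as.vector(sig), length.out = np)
  fc <- as.vector(fa$FC); ar <- as.vector(fa$AR)
  eff <- as.vector(ef$EF_fuel); efp <- as.vector(ef$EF_proc)
  totals <- withr_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      sum(fc * eff * stats::rlnorm(nf, 0, sig_f)) +
        sum(ar * efp * stats::rlnorm(np, 0, sig_p))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(totals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2],
       level = level, draws = totals)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split an inventory into anthropogenic and natural parts
#'
#' The MRIO linkage consumes only the anthropogenic part (natural sources are
#' not economic activity); the natural part still enters the base
#' concentration scenario through gridding.
#'
#' @param inv an \code{emission_inventory}.
#' @return list with elements \code{anthropogenic} (natural zeroed) and
#'   \code{natural} (E zeroed).
#' @export
split_anthropogenic <- function(inv) {
  anth <- inv; anth$natural <- inv$natural * 0
  nat <- inv; nat$E <- inv$E * 0
  list(anthropogenic = anth, natural = nat)
}

#' Distribute regional emissions onto a grid
#'
#' Each region's total (sectoral plus natural) is spread over the region's
#' grid cells with the region's spatial weights, which sum to 1 per region,
#' so the global grid sum equals the inventory total exactly (mass
#' conservation).
#'
#' @param inv an \code{emission_inventory}.
#' @param grid a \code{region_grid} (mask + spatial weights), see
#'   [region_grid()].
#' @param regional_totals optional explicit per-region totals overriding the
#'   inventory sums (used for scenario emissions from a perspective column).
#' @return an \code{emission_grid}: matrix (nlat x nlon) with attributes
#'   \code{species} and \code{scenario}.
#' @export
grid_emissions <- function(inv, grid, regional_totals = NULL) {
  totals <- regional_totals %||% (rowSums(inv$E) + inv$natural)
  grid_from_totals(totals, grid, species = inv$species)
}

grid_from_totals <- function(totals, grid, species = "BaP",
                             scenario = "base") {
  R <- length(grid$regions)
  stopifnot(length(totals) == R)
  g <- matrix(0, nrow(grid$mask), ncol(grid$mask))
  for (m in seq_len(R)) {
    sel <- grid$mask == m
    w <- grid$weights[sel]
    if (abs(sum(w) - 1) > 1e-6)
      stop(sprintf("spatial weights of region %d sum to %.6f, not 1", m, sum(w)))
    g[sel] <- g[sel] + totals[m] * w
  }
  structure(g, species = species, scenario = scenario,
            class = c("emission_grid", "matrix", "array"))
}
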