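# shared fixtures, generated in code

.world_cache <- new.env(parent = emptyenv())

# default synthetic world, generated once per test run
default_world <- function(seed = 7) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(world_spec(seed = seed))
  .world_cache[[key]]
}

# hand-sized two-sector closed economy used for coefficient oracles
tiny_table <- function() {
  Z <- matrix(c(2, 0, 1, 3), 2, 2)      # columns: [2,0], [1,3]
  x <- c(10, 5)
  Fd <- matrix(x - rowSums(Z), 2, 1)
  v <- x - colSums(Z)
  mrio_table(Z, Fd, v, x, regions = "R1", sectors = c("S1", "S2"))
}

# random conformable six-factor sets mimicking the consumption-perspective
# shapes (two diagonal RS factors, one RS x RS, one RS x R, two diagonal R)
random_factor_set <- function(RS, R, perspective = "consumption") {
  fs <- list(
    emission_factors     = diag(stats::runif(RS, 0.2, 2), RS),
    energy_efficiency    = diag(stats::runif(RS, 0.2, 2), RS),
    production_structure = matrix(stats::runif(RS * RS, 0, 0.4), RS, RS) +
                             diag(RS),
    demand_structure     = matrix(stats::runif(RS * R, 0, 1), RS, R),
    demand_level         = diag(stats::runif(R, 0.5, 3), R),
    population           = diag(stats::runif(R, 0.5, 3), R))
  structure(list(perspective = perspective, factors = fs,
                 Q = Reduce(`%*%`, fs), emitting_margin = "rows"),
            class = "factor_set")
}

# scalar factor set (each factor a 1x1 matrix), for hand-checkable cases
scalar_factor_set <- function(values) {
  fs <- lapply(values, function(v) matrix(v, 1, 1))
  names(fs) <- paste0("f", seq_along(values))
  structure(list(perspective = "consumption", factors = fs,
                 Q = Reduce(`%*%`, fs), emitting_margin = "rows"),
            class = "factor_set")
}

# uniform 2x2-cell world pieces for transport/health unit tests
tiny_grid <- function() {
  mask <- matrix(1L, 1, 1)
  region_grid(mask, matrix(1, 1, 1), matrix(1, 1, 1), "R1")
}
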