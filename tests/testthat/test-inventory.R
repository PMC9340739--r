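make_tables <- function(FC, EF_fuel, AR, EF_proc, sigma = 0) {
  list(fa = fuel_activity(array(FC, c(1, 1, length(FC))),
                          array(AR, c(1, 1, length(AR)))),
       ef = emission_factors(array(EF_fuel, c(1, 1, length(EF_fuel))),
                             array(EF_proc, c(1, 1, length(EF_proc))),
                             sigma = sigma))
}

test_that("inventory is the stated sum of products over fuels and processes", {
  tb <- make_tables(FC = 100, EF_fuel = 0.5, AR = 10, EF_proc = 2)
  expect_equal(sum(compute_emissions(tb$fa, tb$ef)$E), 70)

  # zero emission factors, zero inventory
  tb0 <- make_tables(FC = 100, EF_fuel = 0, AR = 10, EF_proc = 0)
  expect_equal(sum(compute_emissions(tb0$fa, tb0$ef)$E), 0)

  # linear in activity: doubling FC and AR doubles E
  tb2 <- make_tables(FC = 200, EF_fuel = 0.5, AR = 20, EF_proc = 2)
  expect_equal(sum(compute_emissions(tb2$fa, tb2$ef)$E), 140)

  # linear in EF too
  tb3 <- make_tables(FC = 100, EF_fuel = 1.5, AR = 10, EF_proc = 6)
  expect_equal(sum(compute_emissions(tb3$fa, tb3$ef)$E), 210)

  # mismatched index sets rejected
  bad_ef <- emission_factors(array(0.5, c(1, 1, 2)), array(2, c(1, 1, 1)))
  expect_error(compute_emissions(tb$fa, bad_ef), "index sets")
})

test_that("monte carlo interval collapses at zero sigma and is reproducible", {
  tb <- make_tables(FC = 100, EF_fuel = 0.5, AR = 10, EF_proc = 2, sigma = 0)
  ci <- monte_carlo_ci(tb$fa, tb$ef, n_draws = 50, seed = 1)
  expect_equal(ci$lower, 70)
  expect_equal(ci$upper, 70)
  tb2 <- make_tables(FC = 100, EF_fuel = 0.5, AR = 10, EF_proc = 2,
                     sigma = 0.3)
  a <- monte_carlo_ci(tb2$fa, tb2$ef, n_draws = 200, seed = 9)
  b <- monte_carlo_ci(tb2$fa, tb2$ef, n_draws = 200, seed = 9)
  expect_identical(a, b)
  expect_error(monte_carlo_ci(tb2$fa, tb2$ef, n_draws = 1), "n_draws")
})

test_that("monte carlo quantiles match the closed-form lognormal oracle", {
  # single source: total = FC * EF * LN(0, sigma), so the interval endpoints
  # are FC * EF * qlnorm(alpha; 0, sigma)
  tb <- make_tables(FC = 100, EF_fuel = 0.5, AR = 0, EF_proc = 0, sigma = 0.4)
  ci <- monte_carlo_ci(tb$fa, tb$ef, n_draws = 2e5, seed = 3)
  oracle <- 50 * stats::qlnorm(c(0.025, 0.975), 0, 0.4)
  expect_equal(ci$lower, oracle[1], tolerance = 0.02)
  expect_equal(ci$upper, oracle[2], tolerance = 0.02)
})

test_that("gridding conserves mass and splits respect the partition", {
  w <- default_world()
  inv <- w$years[[1]]$inventory
  g <- grid_emissions(inv, w$grid)
  expect_equal(sum(g), sum(inv$E) + sum(inv$natural), tolerance = 1e-9)
  expect_true(all(g >= 0))

  # uniform split: one region, four cells, total 8 -> each cell 2
  mask <- matrix(1L, 2, 2)
  rg <- region_grid(mask, matrix(0.25, 2, 2), matrix(0.25, 2, 2), "R1")
  gi <- grid_from_totals(8, rg)
  expect_equal(as.vector(gi), rep(2, 4))

  # zero inventory, zero grid
  inv0 <- inv; inv0$E <- inv$E * 0; inv0$natural <- inv$natural * 0
  expect_equal(sum(grid_emissions(inv0, w$grid)), 0)

  parts <- split_anthropogenic(inv)
  expect_equal(sum(parts$anthropogenic$E) + sum(parts$natural$natural),
               sum(inv$E) + sum(inv$natural))
  expect_equal(sum(parts$anthropogenic$natural), 0)
  # natural = 0 leaves the anthropogenic part equal to the full inventory
  p0 <- split_anthropogenic(inv0)
  expect_equal(p0$anthropogenic$E, inv0$E)
})
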