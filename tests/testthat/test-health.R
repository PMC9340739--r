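const_conc <- function(value, n = 1) {
  structure(matrix(value, n, n),
            class = c("concentration_field", "matrix", "array"))
}

test_that("relative risk reproduces the tabulated URR at the calibration dose", {
  urr <- urr_table()
  # 70 years at 100/70 ug m^-3 is exactly 100 ug m^-3 years of exposure
  cal <- 100 / 70
  areas <- c(asia = 1.3, europe = 1.13, north_america = 1.16, world = 1.2)
  for (a in names(areas)) {
    u <- urr_table(region_area = c(R1 = a))
    rr <- relative_risk(const_conc(cal), u, tiny_grid())
    expect_equal(rr[1, 1], areas[[a]], tolerance = 1e-12)
  }
  # zero exposure: rr = 1; and the direct-exponentiation oracle at c = 1
  expect_equal(relative_risk(const_conc(0), urr, tiny_grid())[1, 1], 1)
  expect_equal(relative_risk(const_conc(1), urr, tiny_grid())[1, 1],
               1.2^0.7, tolerance = 1e-12)
  expect_error(urr_table(values = c(asia = 0.9, world = 1.2)), ">= 1")
})

test_that("PAF follows its closed form and stays in [0, 1)", {
  expect_equal(paf(matrix(1, 1, 1))[1, 1], 0)
  expect_equal(paf(matrix(2, 1, 1))[1, 1], 0.5)
  expect_equal(paf(matrix(1.2, 1, 1))[1, 1], 1 / 6)
  expect_error(paf(matrix(0.5, 1, 1)), ">= 1")
  # strictly increasing in concentration, bounded below 1
  cs <- seq(0, 50, length.out = 40)
  ps <- vapply(cs, function(cc)
    paf(relative_risk(const_conc(cc), urr_table(), tiny_grid()))[1, 1],
    numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps >= 0 & ps < 1))
})

test_that("lifetime deaths match the hand-computed single-cell case", {
  # PAF 0.1, LR 100 per 1e5 per year, population 1e6, 70 years:
  # lifetime deaths 70 * 1000 = 70000; attributable = 7000
  ms <- mortality_series(matrix(100, 1, 70), matrix(1e6, 1, 70), "R1")
  b <- lifetime_deaths(matrix(0.1, 1, 1), ms, tiny_grid())
  expect_equal(b$total, 7000)
  expect_equal(unname(b$regional["R1"]), 7000)
  # zero PAF, zero deaths; linear in both LR and population
  expect_equal(lifetime_deaths(matrix(0, 1, 1), ms, tiny_grid())$total, 0)
  ms2 <- mortality_series(matrix(200, 1, 70), matrix(1e6, 1, 70), "R1")
  expect_equal(lifetime_deaths(matrix(0.1, 1, 1), ms2, tiny_grid())$total,
               14000)
  ms3 <- mortality_series(matrix(100, 1, 70), matrix(2e6, 1, 70), "R1")
  expect_equal(lifetime_deaths(matrix(0.1, 1, 1), ms3, tiny_grid())$total,
               14000)
})

test_that("regional burdens equal masked grid sums on a full world", {
  w <- default_world()
  sl <- w$years[[1]]
  conc <- simulate_concentration(grid_emissions(sl$inventory, w$grid),
                                 sl$kernel)
  b <- lifetime_deaths(paf(relative_risk(conc, urr_table(), w$grid)),
                       sl$mortality, w$grid)
  for (m in 1:4)
    expect_equal(unname(b$regional[m]), sum(b$D[w$grid$mask == m]),
                 tolerance = 1e-9)
  expect_equal(sum(b$regional), b$total, tolerance = 1e-9)
  expect_gt(b$total, 0)
})

test_that("scenario death attribution is multiplicative and closed", {
  w <- default_world()
  sl <- w$years[[1]]
  conc <- simulate_concentration(grid_emissions(sl$inventory, w$grid),
                                 sl$kernel)
  base <- lifetime_deaths(paf(relative_risk(conc, urr_table(), w$grid)),
                          sl$mortality, w$grid)
  ones <- matrix(1, nrow(base$D), ncol(base$D))
  expect_equal(attribute_scenario_deaths(base, ones, w$grid)$total,
               base$total)
  expect_equal(attribute_scenario_deaths(base, ones * 0, w$grid)$total, 0)
  expect_warning(attribute_scenario_deaths(base, ones * 1.5, w$grid),
                 "outside")
})
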