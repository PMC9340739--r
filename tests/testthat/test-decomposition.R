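test_that("factor sets reconstruct the directly computed footprints", {
  w <- default_world()
  for (p in c("consumption", "sale", "income")) {
    for (y in 1:2) {
      sl <- w$years[[y]]
      f <- build_factors(sl, p)
      anth <- split_anthropogenic(sl$inventory)$anthropogenic
      direct <- switch(p,
        consumption = consumption_based(anth, sl$mrio),
        sale        = sale_based(anth, sl$mrio),
        income      = income_based(anth, sl$mrio))
      expect_equal(sum(f$Q), sum(direct$Qmat), tolerance = 1e-6)
      # K * Teff reconstructs the emission intensity
      u <- emission_intensity(anth, sl$mrio)
      kt <- diag(f$factors$emission_factors %*%
                   f$factors$energy_efficiency)
      expect_equal(unname(kt), unname(u), tolerance = 1e-8)
      # structure factor columns (rows for the income side) sum to 1
      M <- f$factors$demand_structure
      sums <- if (p == "income") rowSums(M) else colSums(M)
      expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-8)
    }
  }
})

test_that("compensating population and level changes leave demand unchanged", {
  w <- default_world()
  w2 <- perturb_factor(w, "population", 1, 2)
  w2 <- perturb_factor(w2, "demand_level", 1, 0.5)
  expect_equal(w2$years[[1]]$mrio$Fd, w$years[[1]]$mrio$Fd, tolerance = 1e-12)
})

test_that("two-polar contributions reproduce the hand-evaluated scalar case", {
  # Q = k * p, k: 1 -> 2, p: 3 -> 4
  f0 <- scalar_factor_set(c(1, 3))
  f1 <- scalar_factor_set(c(2, 4))
  s <- two_polar_sda(f0, f1)
  expect_equal(unname(s$contributions), c(3.5, 1.5))
  expect_equal(s$delta, 5)
  expect_equal(s$residual, 0)
  # identical endpoints: all contributions zero
  s0 <- two_polar_sda(f0, f0)
  expect_equal(unname(s0$contributions), c(0, 0))
})

test_that("two-polar SDA is complete on random six-factor pairs", {
  set.seed(99)
  for (i in 1:40) {
    RS <- 6; R <- 2
    f0 <- random_factor_set(RS, R)
    f1 <- random_factor_set(RS, R)
    s <- two_polar_sda(f0, f1)
    expect_lt(abs(s$residual) / max(abs(s$delta), 1e-12), 1e-10)
  }
})

test_that("the all-orderings oracle is complete and matches two-polar at n=2", {
  set.seed(5)
  # n = 2: the two polar forms are all the forms, so the methods coincide
  f0 <- scalar_factor_set(stats::runif(2, 1, 3))
  f1 <- scalar_factor_set(stats::runif(2, 1, 3))
  expect_equal(full_average_sda(f0, f1)$contributions,
               two_polar_sda(f0, f1)$contributions, tolerance = 1e-12)
  # n = 3 scalars: both complete; attributions differ but stay bounded
  g0 <- scalar_factor_set(stats::runif(3, 1, 3))
  g1 <- scalar_factor_set(stats::runif(3, 1, 3))
  fa <- full_average_sda(g0, g1)
  tp <- two_polar_sda(g0, g1)
  expect_equal(sum(fa$contributions), fa$delta, tolerance = 1e-10)
  expect_equal(sum(tp$contributions), tp$delta, tolerance = 1e-10)
  expect_lt(max(abs(fa$contributions - tp$contributions)),
            abs(fa$delta) + sum(abs(fa$contributions)))
  # full six-factor matrix case agrees on completeness
  h0 <- random_factor_set(4, 2)
  h1 <- random_factor_set(4, 2)
  fh <- full_average_sda(h0, h1)
  expect_lt(abs(fh$residual) / max(abs(fh$delta), 1e-12), 1e-10)
})

test_that("reversing the years negates every contribution", {
  w <- default_world()
  f0 <- build_factors(w$years[[1]], "consumption")
  f1 <- build_factors(w$years[[2]], "consumption")
  fwd <- two_polar_sda(f0, f1)
  bwd <- two_polar_sda(f1, f0)
  expect_equal(fwd$contributions, -bwd$contributions, tolerance = 1e-10)
})

test_that("a single perturbed factor receives the whole emission change", {
  w <- default_world()
  for (fac in c("emission_factors", "energy_efficiency", "demand_structure",
                "demand_level", "population")) {
    w2 <- perturb_factor(w, fac, 2, if (fac == "demand_structure") 1.6 else 1.5)
    s <- two_polar_sda(build_factors(w$years[[2]], "consumption"),
                       build_factors(w2$years[[2]], "consumption"))
    share <- s$contributions[fac] / s$delta
    expect_gt(unname(share), 0.99)
    others <- s$contributions[setdiff(names(s$contributions), fac)]
    expect_lt(max(abs(others)) / abs(s$delta), 0.01)
  }
})

test_that("kernel-only change moves deaths through meteorology alone", {
  w <- clone_year(default_world(), 1, 2)
  w <- perturb_factor(w, "kernel", 2, 1.4)
  h <- health_driver_decomposition(w)
  expect_gt(abs(h$contributions["meteorology"]), 0)
  socio <- h$contributions[setdiff(names(h$contributions),
                                   c("meteorology", "mortality_rate"))]
  expect_lt(max(abs(socio)), 1e-9 * abs(h$delta))
  expect_equal(unname(h$contributions["meteorology"]), h$delta,
               tolerance = 1e-9)
})

test_that("identical years give an all-zero death decomposition", {
  w <- clone_year(default_world(), 1, 2)
  h <- health_driver_decomposition(w)
  expect_equal(unname(h$delta), 0)
  expect_lt(max(abs(h$contributions)), 1e-12)
})

test_that("the death decomposition is exact in the linear limit", {
  w <- default_world()
  h <- health_driver_decomposition(w, dose_response = "linear",
                                   fix_kernel = TRUE, fix_mortality = TRUE)
  socio <- h$contributions[setdiff(names(h$contributions),
                                   c("meteorology", "mortality_rate"))]
  expect_equal(unname(h$contributions["meteorology"]), 0)
  expect_equal(unname(h$contributions["mortality_rate"]), 0)
  expect_equal(sum(socio), h$delta, tolerance = 1e-8)
  expect_lt(abs(h$residual) / max(abs(h$delta), 1e-12), 1e-8)
})

test_that("the nonlinear residual is reported, small, and not re-allocated", {
  h <- health_driver_decomposition(default_world())
  expect_lt(abs(h$residual) / abs(h$delta), 0.05)
  expect_equal(sum(h$contributions) + h$residual, h$delta, tolerance = 1e-10)
})
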