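test_that("all four perspectives conserve the produced emission total", {
  for (seed in 1:6) {
    w <- generate_world(world_spec(n_regions = 2 + seed %% 3,
                                   n_sectors = 2 + seed %% 2, seed = seed))
    sl <- w$years[[1]]
    anth <- split_anthropogenic(sl$inventory)$anthropogenic
    pp <- all_perspectives(anth, sl$mrio)
    total <- sum(anth$E)
    for (q in pp)
      expect_equal(sum(q$Qmat), total, tolerance = 1e-8)
    # row sums over driver regions equal production-based emissions per
    # emitting region, in every perspective
    prod_m <- rowSums(anth$E)
    for (q in pp)
      expect_equal(unname(rowSums(q$Qmat)), unname(prod_m),
                   tolerance = 1e-8)
  }
})

test_that("a single-region world attributes everything to itself", {
  w <- generate_world(world_spec(n_regions = 2, n_sectors = 2, seed = 4))
  sl <- w$years[[1]]
  anth <- split_anthropogenic(sl$inventory)$anthropogenic
  # collapse to one macro region: 1x1 matrix equal to the grand total
  for (q in all_perspectives(anth, sl$mrio)) {
    agg <- aggregate_regions(q, c(R1 = "world", R2 = "world"))
    expect_equal(dim(agg$Qmat), c(1, 1))
    expect_equal(sum(agg$Qmat), sum(anth$E), tolerance = 1e-8)
  }
})

test_that("zero intensity or zero demand gives zero footprints", {
  sl <- default_world()$years[[1]]
  anth <- split_anthropogenic(sl$inventory)$anthropogenic
  inv0 <- anth; inv0$E <- anth$E * 0
  for (q in all_perspectives(inv0, sl$mrio))
    expect_equal(sum(abs(q$Qmat)), 0)
  # a region with zero final demand drives no consumption-based emissions
  Z <- matrix(c(0, 1, 0, 0), 2, 2)     # region 2 sells intermediates to 1
  Fd <- matrix(c(5, 0, 0, 0), 2, 2)    # all final demand in region 1
  x <- rowSums(Z) + rowSums(Fd)
  t2 <- mrio_table(Z, Fd, x - colSums(Z), x, regions = c("Ra", "Rb"),
                   sectors = "S1")
  inv2 <- compute_emissions(
    fuel_activity(array(c(2, 3), c(2, 1, 1)), array(0, c(2, 1, 1))),
    emission_factors(array(1, c(2, 1, 1)), array(0, c(2, 1, 1))))
  qc <- consumption_based(inv2, t2)
  expect_equal(sum(abs(qc$Qmat[, 2])), 0)
  expect_equal(sum(qc$Qmat), sum(inv2$E), tolerance = 1e-8)
})

test_that("regional aggregation equals brute-force block sums", {
  sl <- default_world()$years[[1]]
  anth <- split_anthropogenic(sl$inventory)$anthropogenic
  q <- consumption_based(anth, sl$mrio)
  map <- c(R1 = "A", R2 = "A", R3 = "B", R4 = "B")
  agg <- aggregate_regions(q, map)
  # identity mapping changes nothing
  idm <- stats::setNames(q$regions, q$regions)
  expect_equal(aggregate_regions(q, idm)$Qmat, q$Qmat)
  brute <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  for (m in 1:4) for (n in 1:4)
    brute[map[m], map[n]] <- brute[map[m], map[n]] + q$Qmat[m, n]
  expect_equal(unname(agg$Qmat), unname(brute), tolerance = 1e-12)
  expect_error(aggregate_regions(q, c(R1 = "A")), "unmapped")
})

test_that("net flows follow the importer/exporter definition", {
  q <- structure(list(Qmat = matrix(c(0, 1, 3, 0), 2, 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))),
                      perspective = "consumption", regions = c("a", "b")),
                 class = "perspective_emissions")
  nf <- net_flows(q)
  expect_equal(nf$netflow[1, 2], 2)           # Q[0,1]=3 minus Q[1,0]=1
  expect_equal(unname(nf$role), c("exporter", "importer"))
  expect_equal(nf$netflow, -t(nf$netflow))    # antisymmetry
  expect_equal(unname(nf$net_inflow), c(0, 2))

  # symmetric matrix: no net flows at all
  qs <- q; qs$Qmat <- matrix(c(0, 2, 2, 0), 2, 2)
  nfs <- net_flows(qs)
  expect_equal(sum(abs(nfs$netflow)), 0)
  expect_equal(unname(nfs$role), c("balanced", "balanced"))
})
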