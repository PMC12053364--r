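test_that("segment conductance matches its closed-form limits", {
  # no radial entry with a closed tip conducts nothing
  expect_equal(segmentConductance(0.1, 3e-4, 0, 1e-12, 0), 0)
  # a vanishing segment is transparent
  expect_equal(segmentConductance(1e-12, 3e-4, 1e-7, 1e-12, 5e-11), 5e-11,
               tolerance = 1e-8)
  # long-root saturation: K -> kappa regardless of the distal network
  kappa <- sqrt(2 * pi * 3e-4 * 1e-7 * 1e-12)
  expect_equal(segmentConductance(10, 3e-4, 1e-7, 1e-12, 0), kappa,
               tolerance = 1e-8)
  expect_equal(segmentConductance(10, 3e-4, 1e-7, 1e-12, 1e-9), kappa,
               tolerance = 1e-8)
  # short-segment limit: K ~ K_distal + 2 pi r l kr
  l <- 1e-4; kd <- 1e-13
  expect_equal(segmentConductance(l, 3e-4, 1e-7, 1e-12, kd),
               kd + 2 * pi * 3e-4 * l * 1e-7, tolerance = 1e-6)
  # dimensional scaling: kr, kx scaled by c scales K by c (tau invariant)
  for (cc in c(0.1, 7)) {
    expect_equal(segmentConductance(0.1, 3e-4, cc * 1e-7, cc * 1e-12, 0),
                 cc * segmentConductance(0.1, 3e-4, 1e-7, 1e-12, 0),
                 tolerance = 1e-12)
  }
  expect_error(segmentConductance(-1, 3e-4, 1e-7, 1e-12), "length")
  expect_error(segmentConductance(0.1, 3e-4, 1e-7, 0), "kx")
})

test_that("worked transmission-line value agrees with the network oracle", {
  # l=0.1, r=3e-4, kr=1e-7, kx=1e-12: tau ~ 13.73 /m, kappa ~ 1.373e-11
  K <- segmentConductance(0.1, 3e-4, 1e-7, 1e-12, 0)
  expect_equal(K, 1.21e-11, tolerance = 1e-3)
  one <- chainSystem(0.1)
  orc <- networkOracle(one, constHydraulics(kr_ax = 1e-7, kx_ax = 1e-12),
                       t = 0, nodes_per_segment = 2000)
  expect_equal(K, orc, tolerance = 1e-6)
})

test_that("tree folding obeys chain composition and parallel additivity", {
  h <- constHydraulics()
  chain <- chainSystem(c(0.05, 0.04, 0.06))
  direct <- segmentConductance(0.05, 3e-4, 1e-7, 2e-12,
            segmentConductance(0.04, 3e-4, 1e-7, 2e-12,
            segmentConductance(0.06, 3e-4, 1e-7, 2e-12, 0)))
  expect_equal(computeKrs(chain, h, t = 0)$krs, direct, tolerance = 1e-12)
  # two identical roots joined at an ideal collar: exactly twice one root
  twin <- rootSystem(data.frame(
    segment_id = 1:2, parent_id = c(0L, 0L), root_id = 1:2,
    type = "seminal", length_m = 0.07, radius_m = 3e-4, creation_day = 0,
    stringsAsFactors = FALSE), simulation_time = 0)
  single <- chainSystem(0.07)
  expect_equal(computeKrs(twin, h, t = 0)$krs,
               2 * computeKrs(single, h, t = 0)$krs, tolerance = 1e-12)
})

test_that("Krs results carry consistent normalizations and exclusions", {
  rs <- randomRootSystem(50, seed = 2, t = 25)
  h <- agedHydraulics()
  res <- computeKrs(rs, h, t = 25)
  expect_equal(res$krs_area, res$krs / surfaceArea(rs))
  expect_equal(res$krs_length, res$krs / totalLength(rs))
  # segments created after t are excluded: evaluate mid-way
  t_mid <- stats::median(rs$segments$creation_day)
  res_mid <- computeKrs(rs, h, t = t_mid)
  keep <- rs$segments$creation_day <= t_mid
  expect_equal(res_mid$total_length_m, sum(rs$segments$length_m[keep]))
  expect_lt(res_mid$krs, res$krs)
  # empty system
  empty <- simulateGrowth(wheatCultivar("Tommi"), t_end = 0, dt = 0.5, seed = 1)
  expect_equal(computeKrs(empty, h, t = 0)$krs, 0)
})

test_that("analytic Krs matches the resistor-network oracle on random trees", {
  h <- agedHydraulics()
  for (seed in 1:5) {
    rs <- randomRootSystem(40, seed = seed, t = 25)
    a <- computeKrs(rs, h, t = 25)$krs
    o <- networkOracle(rs, h, t = 25, nodes_per_segment = 400)
    expect_lt(abs(a - o) / o, 1e-5)
  }
})

test_that("oracle discretization converges to the analytic solution", {
  rs <- randomRootSystem(20, seed = 9, t = 25)
  h <- constHydraulics()
  a <- computeKrs(rs, h, t = 25)$krs
  errs <- vapply(c(10, 50, 250), function(m)
    abs(networkOracle(rs, h, t = 25, nodes_per_segment = m) - a) / a, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-5)
})

test_that("oracle limits: no radial path conducts nothing, huge kx is radial-limited", {
  one <- chainSystem(0.1)
  h0 <- constHydraulics(kr_ax = 0, kx_ax = 1e-12, kr_lat = 0)
  expect_equal(networkOracle(one, h0, t = 0, nodes_per_segment = 50), 0)
  hbig <- constHydraulics(kr_ax = 1e-7, kx_ax = 1e-3)
  expect_equal(networkOracle(one, hbig, t = 0, nodes_per_segment = 200),
               2 * pi * 3e-4 * 0.1 * 1e-7, tolerance = 1e-6)
  expect_error(networkOracle(one, h0, nodes_per_segment = 1), ">= 2")
})

test_that("Krs trajectories are monotone under age-constant properties", {
  rs <- simulateGrowth(wheatCultivar("Tommi"), t_end = 20, dt = 0.5, seed = 4)
  h <- constHydraulics()
  tr <- krsTrajectory(rs, h, times = 1:20)
  expect_equal(nrow(tr), 20L)
  expect_true(all(diff(tr$krs) >= -1e-18))
  expect_true(all(diff(tr$total_length_m) >= 0))
  empty <- krsTrajectory(rs, h, times = numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_error(krsTrajectory(rs, h, times = c(5, 3)), "increasing")
})

test_that("sensitivity sweeps are monotone and anchored at factor one", {
  rs <- simulateGrowth(wheatCultivar("Tommi"), t_end = 15, dt = 0.5, seed = 8)
  h <- wheatHydraulics("Tommi")
  base <- computeKrs(rs, h)$krs
  sw <- sensitivitySweep(rs, h, factors = c(0.5, 1, 2), target = "kr")
  expect_equal(sw$krs[2], base, tolerance = 1e-12)
  expect_true(all(diff(sw$krs) > 0))
  # radial-limited linearity: with kx effectively unlimited, kr x2 doubles Krs
  hbig <- scaleHydraulics(h, kx_factor = 1e6)
  sw2 <- sensitivitySweep(rs, hbig, factors = c(1, 2), target = "kr")
  expect_equal(sw2$krs[2] / sw2$krs[1], 2, tolerance = 1e-3)
  # against the oracle
  o <- vapply(c(0.5, 1, 2), function(f)
    networkOracle(rs, scaleHydraulics(h, kr_factor = f), nodes_per_segment = 60), 0)
  expect_true(all(diff(o) > 0))
  expect_error(sensitivitySweep(rs, h, factors = c(-1, 1)), "> 0")
})
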