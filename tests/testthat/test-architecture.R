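test_that("degenerate simulations behave as documented", {
  p <- wheatCultivar("Tommi")
  rs0 <- simulateGrowth(p, t_end = 0, dt = 0.5, seed = 1)
  expect_equal(nrow(rs0$segments), 0L)
  expect_equal(totalLength(rs0), 0)
  expect_equal(surfaceArea(rs0), 0)
  expect_error(simulateGrowth(p, t_end = 10, dt = 0), "dt")
  expect_error(simulateGrowth(p, t_end = 10, dt = 1.5), "dt")
  expect_error(simulateGrowth(p, t_end = -1), "t_end")
})

test_that("length and area equal the per-segment summation oracle", {
  rs <- randomRootSystem(100, seed = 7)
  len <- 0; area <- 0
  for (i in seq_len(nrow(rs$segments))) {   # brute-force independent sums
    len <- len + rs$segments$length_m[i]
    area <- area + 2 * pi * rs$segments$radius_m[i] * rs$segments$length_m[i]
  }
  expect_equal(totalLength(rs), len)
  expect_equal(surfaceArea(rs), area)
  one <- chainSystem(0.1, radius = 1.5e-4)
  expect_equal(totalLength(one), 0.1)
  expect_equal(surfaceArea(one), 2 * pi * 1.5e-4 * 0.1, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  p <- wheatCultivar("S. Dickkopf")
  a <- simulateGrowth(p, t_end = 25, dt = 0.5, seed = 42)
  b <- simulateGrowth(p, t_end = 25, dt = 0.5, seed = 42)
  expect_identical(a$segments, b$segments)
  c <- simulateGrowth(p, t_end = 25, dt = 0.5, seed = 43)
  expect_false(identical(a$segments, c$segments))
})

test_that("total length is non-decreasing across snapshots and axes respect Lmax", {
  p <- wheatCultivar("Tommi")
  rs <- simulateGrowth(p, t_end = 40, dt = 0.5, seed = 3)
  lens <- vapply(seq(0, 40, by = 2), function(t) totalLength(rootSnapshot(rs, t)), 0)
  expect_true(all(diff(lens) >= 0))
  expect_gt(lens[length(lens)], 0)
  per_axis <- tapply(rs$segments$length_m * 100, rs$segments$root_id, sum)
  axis_type <- tapply(rs$segments$type, rs$segments$root_id, function(x) x[1])
  lmax <- vapply(axis_type, function(ty) p$root_type_params[[ty]]$max_length, 0)
  expect_true(all(per_axis <= lmax + 1e-9))
})

test_that("segment trees are valid forests with parents older than children", {
  rs <- simulateGrowth(wheatCultivar("Okapi"), t_end = 30, dt = 0.5, seed = 11)
  seg <- rs$segments
  expect_false(anyDuplicated(seg$segment_id) > 0)
  expect_true(all(seg$parent_id < seg$segment_id))  # forest, no cycles
  par_created <- c(-Inf, seg$creation_day)[seg$parent_id + 1L]
  expect_true(all(par_created <= seg$creation_day + 1e-9))
  expect_true(all(seg$length_m > 0 & seg$radius_m > 0 & seg$creation_day >= 0))
})

test_that("mean axis counts over 20 seeds match the configured dynamics within 2 SE", {
  p <- wheatCultivar("Tommi")
  counts <- t(vapply(1:20, function(s) {
    rs <- simulateGrowth(p, t_end = 70, dt = 1, seed = s)
    seg <- rs$segments
    ax <- tapply(seg$type, seg$root_id, function(x) x[1])
    c(seminal = sum(ax == "seminal"), crown = sum(ax == "crown"))
  }, c(seminal = 0, crown = 0)))
  se <- apply(counts, 2, stats::sd) / sqrt(nrow(counts))
  expect_lt(abs(mean(counts[, "seminal"]) - p$seminal_count_mean), 2 * se["seminal"] + 1e-9)
  crown_target <- p$tiller_final_count_mean * p$crown_roots_per_tiller
  expect_lt(abs(mean(counts[, "crown"]) - crown_target), 2 * se["crown"] + 1e-9)
})

test_that("realized branching density matches 1/spacing on fully branched zones", {
  p <- wheatCultivar("S. Dickkopf")
  rs <- simulateGrowth(p, t_end = 70, dt = 0.5, seed = 5)
  seg <- rs$segments
  ax_type <- tapply(seg$type, seg$root_id, function(x) x[1])
  seminal_axes <- as.integer(names(ax_type)[ax_type == "seminal"])
  # count laterals rooted on each seminal axis
  lat_first <- seg[seg$type == "lateral" & seg$parent_id != 0L, ]
  lat_base <- lat_first[!duplicated(lat_first$root_id), ]
  parent_axis <- seg$root_id[lat_base$parent_id]
  tp <- p$root_type_params$seminal
  dens <- vapply(seminal_axes, function(a) {
    L <- sum(seg$length_m[seg$root_id == a]) * 100
    n_lat <- sum(parent_axis == a)
    branched <- L - tp$apical_unbranched_zone - tp$basal_unbranched_zone
    n_lat / branched
  }, 0)
  expect_true(all(abs(dens - 1 / tp$lateral_spacing) / (1 / tp$lateral_spacing) < 0.05))
})

test_that("cultivar parameters derive from trait tables", {
  panel <- wheatTraitPanel()
  mkRows <- function(cv, year) {
    i <- match(cv, panel$cultivar)
    vals <- c(seminal_root_number = panel$seminal_number[i],
              tiller_number = panel$tiller_number[i],
              crown_root_number = panel$crown_number[i],
              crown_root_diameter_mm = panel$crown_diameter_mm[i],
              seminal_root_diameter_mm = panel$seminal_diameter_mm[i],
              lateral_root_diameter_mm = panel$lateral_diameter_mm[i],
              branching_density_cm = panel$branching_density_cm[i])
    data.frame(plant_id = paste0(cv, "_1"), cultivar = cv, release_year = year,
               season = "s1", trait = names(vals), value = unname(vals),
               stringsAsFactors = FALSE)
  }
  traits <- rbind(mkRows("Tommi", 2002), mkRows("S. Dickkopf", 1895))
  tommi <- deriveCultivarParams(traits, "Tommi")
  expect_equal(tommi$seminal_count_mean, 5.9)
  expect_equal(tommi$tiller_final_count_mean, 4.1)
  expect_equal(tommi$root_type_params$lateral$mean_diameter, 0.17)
  dick <- deriveCultivarParams(traits, "S. Dickkopf")
  expect_equal(dick$crown_roots_per_tiller, 15.4 / 6.6, tolerance = 1e-12)
  expect_equal(dick$root_type_params$seminal$lateral_spacing, 1 / 1.1)
  expect_error(deriveCultivarParams(traits, "nope"), "unknown cultivar")
  expect_error(deriveCultivarParams(traits[0, ], "Tommi"), "unknown cultivar")
})
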