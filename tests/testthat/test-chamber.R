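makeSweep <- function(krs = 1.2e-10, intercept = 2e-12, noise = 0,
                      plant_id = "p1", cultivar = "cv", seed = NULL,
                      area = 7.8e-4, len = 0.715) {
  if (!is.null(seed)) set.seed(seed)
  p <- chamberProtocol()
  pressureSweep(plant_id, cultivar, 1900, p,
                intercept + krs * p + stats::rnorm(length(p), 0, noise),
                area, len)
}

test_that("noiseless linear sweeps are recovered exactly", {
  # a perfect fit makes summary.lm grumble; that is the point of the case
  est <- suppressWarnings(fitSweep(makeSweep(krs = 1.2e-10, intercept = 3e-12)))
  expect_equal(est$krs, 1.2e-10, tolerance = 1e-12)
  expect_equal(est$intercept, 3e-12, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
  expect_true(est$qc_pass)
  expect_equal(est$krs_area, est$krs / 7.8e-4)
  expect_equal(est$krs_length, est$krs / 0.715)
})

test_that("flat and non-linear sweeps fail quality control", {
  p <- chamberProtocol()
  flat <- pressureSweep("p1", "cv", 1900, p, rep(2e-11, 5), 7.8e-4, 0.715)
  expect_false(suppressWarnings(fitSweep(flat))$qc_pass)
  sat <- pressureSweep("p2", "cv", 1900, p, 1e-12 + 1.2e-10 * pmin(p, 0.15),
                       7.8e-4, 0.715)
  est <- fitSweep(sat)
  expect_lt(est$r_squared, 0.95)
  expect_false(est$qc_pass)
})

test_that("the slope equals the closed-form normal-equations oracle", {
  sw <- makeSweep(noise = 2e-12, seed = 99)
  est <- fitSweep(sw)
  x <- sw$pressure_MPa; y <- sw$flow_m3_s
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(est$krs, slope_oracle, tolerance = 1e-12)
  expect_equal(est$intercept, intercept_oracle, tolerance = 1e-12)
})

test_that("sweep construction is validated", {
  expect_error(pressureSweep("p", "c", 1900, c(0.1, 0.2), c(1, 2) * 1e-11,
                             1e-4, 0.5), "3 distinct")
  expect_error(pressureSweep("p", "c", 1900, c(0.1, 0.1, 0.1, 0.1),
                             rep(1e-11, 4), 1e-4, 0.5), "3 distinct")
  expect_error(pressureSweep("p", "c", 1900, c(-0.1, 0.2, 0.3),
                             rep(1e-11, 3), 1e-4, 0.5), "> 0")
  expect_error(pressureSweep("p", "c", 1900, c(0.1, 0.2, 0.3),
                             rep(1e-11, 3), 0, 0.5), "> 0")
})

test_that("Grubbs' test matches a hand computation and its critical value", {
  x <- c(1.0, 1.1, 0.9, 1.05, 5.0) * 1e-10
  g <- grubbsTest(x, alpha = 0.05)
  # hand: mean 1.81e-10, sd(x) and G = |5e-10 - mean|/sd
  expect_equal(g$index, 5L)
  expect_equal(g$G, abs(5e-10 - mean(x)) / stats::sd(x), tolerance = 1e-12)
  n <- 5; tq <- stats::qt(1 - 0.05 / (2 * n), n - 2)
  expect_equal(g$critical, (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)),
               tolerance = 1e-12)
  expect_true(g$significant)
  expect_false(grubbsTest(rep(1, 5))$significant)
  expect_error(grubbsTest(c(1, 2)), "at least 3")
})

test_that("outliers are flagged only when extreme in all three measures", {
  base <- c(1.0, 1.1, 0.9, 1.05, 1.02, 0.95, 1.08, 0.98) * 1e-10
  mk <- function(krs, area, len, id) data.frame(
    plant_id = id, cultivar = "cv", release_year = 1900, krs = krs,
    intercept = 0, r_squared = 0.99, krs_area = krs / area,
    krs_length = krs / len, qc_pass = TRUE, outlier = FALSE,
    stringsAsFactors = FALSE)
  # consistent extreme: same geometry, wild conductance
  est <- do.call(rbind, lapply(seq_along(base), function(i)
    mk(base[i], 7.8e-4, 0.715, paste0("p", i))))
  est <- rbind(est, mk(4e-10, 7.8e-4, 0.715, "bad"))
  flagged <- filterOutliers(est)
  expect_true(flagged$outlier[flagged$plant_id == "bad"])
  expect_equal(sum(flagged$outlier), 1L)
  # extreme in krs only: geometry scales area/length back into range
  est2 <- do.call(rbind, lapply(seq_along(base), function(i)
    mk(base[i], 7.8e-4, 0.715, paste0("p", i))))
  est2 <- rbind(est2, mk(4e-10, 4 * 7.8e-4, 4 * 0.715, "big_plant"))
  flagged2 <- filterOutliers(est2)
  expect_false(flagged2$outlier[flagged2$plant_id == "big_plant"])
  # identical values never flag
  est3 <- do.call(rbind, lapply(1:6, function(i) mk(1e-10, 7.8e-4, 0.715,
                                                    paste0("p", i))))
  expect_false(any(filterOutliers(est3)$outlier))
})

test_that("outlier flags are invariant under common rescaling", {
  set.seed(1)
  est <- fitSweeps(lapply(1:9, function(i)
    makeSweep(krs = 1e-10 * exp(rnorm(1, 0, 0.2)), noise = 5e-13,
              plant_id = paste0("p", i))))
  est <- rbind(est, suppressWarnings(fitSweep(makeSweep(krs = 5e-10, plant_id = "out"))))
  f1 <- filterOutliers(est)
  est_scaled <- est
  for (mm in c("krs", "krs_area", "krs_length"))
    est_scaled[[mm]] <- est_scaled[[mm]] * 1e3
  f2 <- filterOutliers(est_scaled)
  expect_identical(f1$outlier, f2$outlier)
  # inputs are annotated, never mutated or dropped
  expect_identical(f1[names(est)][, setdiff(names(est), "outlier")],
                   est[, setdiff(names(est), "outlier")])
  expect_equal(nrow(f1), nrow(est))
})

test_that("per-cultivar summaries report mean, SE and edge cases", {
  mk <- function(krs, id, cv) data.frame(
    plant_id = id, cultivar = cv, release_year = 1900, krs = krs,
    intercept = 0, r_squared = 0.99, krs_area = krs / 1e-4,
    krs_length = krs / 0.5, qc_pass = TRUE, outlier = FALSE,
    stringsAsFactors = FALSE)
  est <- rbind(mk(1e-10, "a1", "A"), mk(1.2e-10, "a2", "A"),
               mk(2e-10, "b1", "B"),
               mk(3e-10, "c1", "C"), mk(3e-10, "c2", "C"))
  s <- summarizeByCultivar(est)
  expect_equal(s$krs_mean[s$cultivar == "A"], 1.1e-10)
  expect_equal(s$krs_se[s$cultivar == "A"],
               stats::sd(c(1e-10, 1.2e-10)) / sqrt(2))
  expect_true(is.na(s$krs_se[s$cultivar == "B"]))   # single estimate
  expect_equal(s$krs_se[s$cultivar == "C"], 0)      # two equal estimates
  est$qc_pass[est$cultivar == "B"] <- FALSE
  expect_warning(s2 <- summarizeByCultivar(est), "omitted")
  expect_false("B" %in% s2$cultivar)
})

test_that("estimation is unbiased at measurement-scale noise", {
  set.seed(7)
  n <- 1000
  ests <- vapply(seq_len(n), function(i)
    fitSweep(makeSweep(krs = 1e-10, noise = 1.5e-12))$krs, 0)
  expect_lt(abs(mean(ests) - 1e-10) / 1e-10, 0.02)
})
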