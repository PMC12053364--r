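makePanel <- function(pct_per_century, ref_mean = 15, log_sd = 0.25,
                      season_sd = 0.1, n = 15, seed = 1,
                      trait = "crown_root_number") {
  set.seed(seed)
  years <- c(1895, 1920, 1940, 1961, 1978, 2002)
  means <- trendMeans(ref_mean, pct_per_century, years)
  rows <- list()
  for (s in 1:2) {
    eff <- stats::rnorm(1, 0, season_sd)
    for (i in seq_along(years)) {
      v <- exp(log(means[i]) + eff + stats::rnorm(n, 0, log_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("c%d_s%d_%02d", i, s, seq_len(n)),
        cultivar = paste0("cv", i), release_year = years[i],
        season = paste0("season", s), trait = trait, value = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("KS comparisons separate root-type diameter distributions", {
  set.seed(3)
  d <- data.frame(
    root_type = rep(c("crown", "seminal", "lateral"), each = 60),
    diameter_mm = c(rnorm(60, 0.60, 0.05), rnorm(60, 0.30, 0.05),
                    rnorm(60, 0.17, 0.05)))
  res <- compareDiameterDistributions(d)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_value < 0.001))
  # identical samples: D = 0, p = 1
  same <- data.frame(root_type = rep(c("crown", "seminal"), each = 10),
                     diameter_mm = rep(seq(0.1, 1, length.out = 10), 2))
  r2 <- compareDiameterDistributions(same)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(compareDiameterDistributions(d[d$root_type == "crown", , drop = FALSE]),
               "2 root types")
  small <- data.frame(root_type = c(rep("crown", 10), rep("lateral", 3)),
                      diameter_mm = runif(13))
  expect_error(compareDiameterDistributions(small), ">= 5")
})

test_that("percent change per century back-transforms the log-scale slope", {
  expect_equal(percentChangePerCentury(0), 0)
  expect_equal(percentChangePerCentury(log(2) / 100), 100)
  expect_equal(percentChangePerCentury(-log(2) / 100), -50)
  expect_error(percentChangePerCentury(NaN), "finite")
  # the lateral-diameter trend: -3.5 %/century at a 0.18 mm reference
  # corresponds to ~0.000063 mm/yr in absolute terms
  slope <- log(1 - 3.5 / 100) / 100
  abs_per_year <- 0.18 * -expm1(slope)
  expect_equal(abs_per_year, 6.3e-5, tolerance = 0.02)
})

test_that("year-trend fits satisfy the back-transformation invariant", {
  tab <- makePanel(-20, seed = 11)
  fit <- fitYearTrend(tab, "crown_root_number", random_season = TRUE)
  expect_equal(fit$percent_change_per_century,
               (exp(100 * fit$slope_per_year) - 1) * 100)
  expect_equal(fit$model_kind, "mixed_random_intercept")
  expect_true(fit$p_value < 0.05)
  expect_true(is.finite(fit$shapiro_p))
})

test_that("the mixed model collapses to OLS with a single season", {
  tab <- makePanel(-15, seed = 5)
  one <- tab[tab$season == "season1", , drop = FALSE]
  mixed <- fitYearTrend(one, "crown_root_number", random_season = TRUE)
  ols <- fitYearTrend(one, "crown_root_number", random_season = FALSE)
  expect_equal(mixed$model_kind, "ols")
  expect_lt(abs(mixed$slope_per_year - ols$slope_per_year) /
              abs(ols$slope_per_year), 1e-8)
})

test_that("trend fits are equivariant under trait rescaling", {
  tab <- makePanel(-10, seed = 6)
  f1 <- fitYearTrend(tab, "crown_root_number")
  tab2 <- tab; tab2$value <- tab2$value * 37.5
  f2 <- fitYearTrend(tab2, "crown_root_number")
  expect_equal(f1$slope_per_year, f2$slope_per_year, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-8)
})

test_that("trend fitting rejects non-positive values with context", {
  tab <- makePanel(-10, seed = 2)
  tab$value[3] <- 0
  expect_error(fitYearTrend(tab, "crown_root_number"), "non-positive")
  expect_error(fitYearTrend(tab, "no_such_trait"), "not present")
})

test_that("planted trends are recovered within the 95% CI", {
  hits <- 0
  for (seed in 1:20) {
    tab <- makePanel(-20, n = 30, seed = seed)
    fit <- fitYearTrend(tab, "crown_root_number")
    if (fit$percent_change_ci95[1] <= -20 && -20 <= fit$percent_change_ci95[2])
      hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% nominal coverage over 20 replicates
})

test_that("cultivar contrasts isolate an elevated oldest cultivar", {
  set.seed(8)
  years <- c(1895, 1920, 1940, 1961, 1978, 2002)
  rows <- do.call(rbind, lapply(seq_along(years), function(i) {
    mu <- if (i == 1) 24 else 13   # only the oldest is elevated
    data.frame(plant_id = sprintf("c%d_%02d", i, 1:25),
               cultivar = paste0("cv", i), release_year = years[i],
               season = "s1", trait = "total_axes",
               value = exp(log(mu) + rnorm(25, 0, 0.2)),
               stringsAsFactors = FALSE)
  }))
  res <- cultivarContrasts(rows, "total_axes")
  expect_lt(res$anova[["Pr(>F)"]][1], 0.001)
  with_old <- grepl("cv1", res$tukey$comparison)
  expect_true(all(res$tukey$p_adj[with_old] < 0.001))
  expect_gt(min(res$tukey$p_adj[!with_old]), 0.05)
  # two groups reduce to a single comparison
  two <- rows[rows$cultivar %in% c("cv1", "cv2"), ]
  expect_equal(nrow(cultivarContrasts(two, "total_axes")$tukey), 1L)
  expect_error(cultivarContrasts(rows[rows$cultivar == "cv1", ], "total_axes"),
               ">= 2 cultivars")
})

test_that("crown-tiller relation recovers exact and noisy slopes", {
  tillers <- rep(3:8, each = 4)
  df <- data.frame(plant_id = paste0("p", seq_along(tillers)),
                   cultivar = "cv", release_year = 1900, season = "s1",
                   stringsAsFactors = FALSE)
  exact <- rbind(
    transform(df, trait = "tiller_number", value = tillers),
    transform(df, trait = "crown_root_number", value = 2.3 * tillers))
  res <- suppressWarnings(crownTillerRelation(exact))  # perfect fit
  expect_equal(res$slope, 2.3, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  set.seed(4)
  noisy <- rbind(
    transform(df, trait = "tiller_number", value = tillers),
    transform(df, trait = "crown_root_number",
              value = 2.3 * tillers + rnorm(length(tillers), 0, 1.5)))
  res2 <- crownTillerRelation(noisy)
  expect_gt(res2$slope, 0)
  expect_lt(res2$p_value, 0.001)
  const <- rbind(
    transform(df, trait = "tiller_number", value = 5),
    transform(df, trait = "crown_root_number", value = 2.3 * tillers))
  expect_error(crownTillerRelation(const), "constant")
})
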