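#' Derived breeding-effect quantities from the packaged trait panel
#'
#' Recomputes, from the packaged cultivar panel ([wheatTraitPanel()] and
#' [wheatTrendPanel()]), the derived quantities used to summarize the
#' breeding effect: the percent decrease in crown and seminal root number
#' between the oldest and the most modern cultivar, the absolute lateral
#' root diameter decrease per year implied by the fitted percent change per
#' century at the oldest cultivar's diameter, and the overall mean lateral
#' branching density.
#'
#' @return List with `crown_number_decrease_pct`,
#'   `seminal_number_decrease_pct`, `lateral_diameter_decrease_mm_per_yr`,
#'   `branching_density_mean_cm`, and `krs_decrease_pct_per_century`.
#' @export
breedingReport <- function() {
  panel <- wheatTraitPanel()
  trends <- wheatTrendPanel()
  oldest <- which.min(panel$release_year)
  newest <- which.max(panel$release_year)
  lat_pct <- trends$percent_change_per_century[
    trends$trait == "lateral_root_diameter_mm"]
  list(
    crown_number_decrease_pct =
      100 * (panel$crown_number[oldest] - panel$crown_number[newest]) /
      panel$crown_number[oldest],
    seminal_number_decrease_pct =
      100 * (panel$seminal_number[oldest] - panel$seminal_number[newest]) /
      panel$seminal_number[oldest],
    lateral_diameter_decrease_mm_per_yr =
      panel$lateral_diameter_mm[oldest] * (-lat_pct / 100) / 100,
    branching_density_mean_cm = mean(panel$branching_density_cm),
    krs_decrease_pct_per_century =
      -trends$percent_change_per_century[trends$trait == "krs"]
  )
}

#' Simulate Krs development for a packaged cultivar
#'
#' Convenience wrapper: simulates root growth for a packaged cultivar over
#' several replicate seeds and evaluates the Krs trajectory with the packaged
#' cultivar-scaled hydraulic parameters.
#'
#' @param cultivar Packaged cultivar name.
#' @param t_end Simulation length, days.
#' @param dt Growth time step, days.
#' @param seeds Integer vector of replicate seeds.
#' @param times Krs evaluation times; defaults to daily.
#' @return data.frame of [krsTrajectory()] rows with an extra `seed` column.
#' @export
simulateKrsDevelopment <- function(cultivar = "S. Dickkopf", t_end = 70,
                                   dt = 0.5, seeds = 1:6,
                                   times = seq(1, floor(t_end))) {
  params <- wheatCultivar(cultivar)
  hyd <- wheatHydraulics(cultivar)
  rows <- lapply(seeds, function(sd) {
    rs <- simulateGrowth(params, t_end = t_end, dt = dt, seed = sd)
    tr <- krsTrajectory(rs, hyd, times = times)
    tr$seed <- sd
    tr
  })
  out <- do.call(rbind, rows)
  out$cultivar <- cultivar
  out
}

# Mean trajectory across seeds (one row per time point).
meanTrajectory <- function(traj) {
  agg <- stats::aggregate(traj[c("krs", "krs_area", "krs_length",
                                 "total_length_m", "surface_area_m2")],
                          by = list(time = traj$time), FUN = mean)
  agg[order(agg$time), , drop = FALSE]
}

#' Summary dynamics of simulated Krs development for two cultivars
#'
#' Runs the 70-day growth and conductance simulation for an old and a modern
#' cultivar over replicate seeds and reduces the trajectories to the headline
#' dynamics: the orders of magnitude spanned by Krs, the final total root
#' lengths, the day-10-12 conductances and the time-averaged percent Krs
#' deficit of the modern relative to the old cultivar.
#'
#' @param old,modern Packaged cultivar names.
#' @param t_end Simulation length, days.
#' @param dt Growth time step, days.
#' @param seeds Replicate seeds.
#' @param deficit_window Days over which the mean percent deficit is taken.
#' @return List with `log10_span_old` (mean over seeds of
#'   log10(Krs(t_end)/Krs at the first day with roots) for the old cultivar),
#'   `log10_span_modern`, `final_length_old_m`, `final_length_modern_m`,
#'   `krs_day10_12_old`, `krs_day10_12_modern`, `deficit_pct` (mean over the
#'   window of (1 - Krs_modern/Krs_old) x 100 on the seed-averaged
#'   trajectories), and the two mean trajectories.
#' @export
krsDynamicsSummary <- function(old = "S. Dickkopf", modern = "Tommi",
                               t_end = 70, dt = 0.5, seeds = 1:6,
                               deficit_window = c(5, 70)) {
  traj_o <- simulateKrsDevelopment(old, t_end, dt, seeds)
  traj_m <- simulateKrsDevelopment(modern, t_end, dt, seeds)
  span <- function(traj) {
    per_seed <- vapply(split(traj, traj$seed), function(d) {
      d <- d[order(d$time), ]
      first <- which(d$total_length_m > 0 & d$krs > 0)[1L]
      log10(d$krs[nrow(d)] / d$krs[first])
    }, 0)
    mean(per_seed)
  }
  final_len <- function(traj) {
    mean(vapply(split(traj, traj$seed),
                function(d) d$total_length_m[which.max(d$time)], 0))
  }
  mo <- meanTrajectory(traj_o)
  mm <- meanTrajectory(traj_m)
  win <- mo$time >= deficit_window[1] & mo$time <= deficit_window[2]
  deficit <- mean((1 - mm$krs[win] / mo$krs[win]) * 100)
  day1012 <- function(tr) mean(tr$krs[tr$time >= 10 & tr$time <= 12])
  list(log10_span_old = span(traj_o),
       log10_span_modern = span(traj_m),
       final_length_old_m = final_len(traj_o),
       final_length_modern_m = final_len(traj_m),
       krs_day10_12_old = day1012(mo),
       krs_day10_12_modern = day1012(mm),
       deficit_pct = deficit,
       trajectory_old = mo,
       trajectory_modern = mm)
}

#' End-to-end reproduction report
#'
#' Chains the full pipeline on synthetic data and simulation: generates the
#' packaged synthetic bundle, runs the pressure-chamber estimation chain
#' (fit, outlier screen, per-cultivar summary), fits the release-year trends
#' for the core traits, and runs the two-cultivar growth/conductance
#' simulation, juxtaposing each computed quantity with the packaged measured
#' value.
#'
#' @param seed Integer seed driving all randomness.
#' @param seeds_sim Replicate seeds for the growth simulation (derived from
#'   `seed`).
#' @param t_end Simulation length, days.
#' @return List with components `chamber` (per-cultivar summary),
#'   `trends` (data.frame computed vs packaged percent change per century),
#'   `derived` ([breedingReport()]), and `dynamics`
#'   ([krsDynamicsSummary()] output).
#' @export
reproduceReport <- function(seed = 1L, seeds_sim = seed * 10L + 0:5,
                            t_end = 70) {
  cfg <- table1Defaults(seed = seed)
  bundle <- generateSynthBundle(cfg)
  est <- filterOutliers(fitSweeps(bundle$sweeps))
  chamber <- summarizeByCultivar(est)

  krs_rows <- data.frame(plant_id = est$plant_id, cultivar = est$cultivar,
                         release_year = est$release_year, season = "lab",
                         trait = "krs", value = est$krs,
                         stringsAsFactors = FALSE)
  krs_rows <- krs_rows[est$qc_pass & !est$outlier & est$krs > 0, , drop = FALSE]
  trend_panel <- wheatTrendPanel()
  trend_traits <- c("crown_root_number", "seminal_root_number",
                    "tiller_number", "lateral_root_diameter_mm")
  trends <- do.call(rbind, lapply(trend_traits, function(tr) {
    fit <- fitYearTrend(bundle$traits, tr, random_season = TRUE)
    data.frame(trait = tr,
               percent_change_per_century = fit$percent_change_per_century,
               p_value = fit$p_value,
               packaged_percent_change =
                 trend_panel$percent_change_per_century[trend_panel$trait == tr],
               stringsAsFactors = FALSE)
  }))
  krs_fit <- fitYearTrend(krs_rows, "krs", random_season = FALSE)
  trends <- rbind(trends, data.frame(
    trait = "krs", percent_change_per_century = krs_fit$percent_change_per_century,
    p_value = krs_fit$p_value,
    packaged_percent_change =
      trend_panel$percent_change_per_century[trend_panel$trait == "krs"]))

  dynamics <- krsDynamicsSummary(seeds = seeds_sim, t_end = t_end)
  list(chamber = chamber, trends = trends, derived = breedingReport(),
       dynamics = dynamics)
}
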