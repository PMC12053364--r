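#' Per-cultivar trait means implied by a log-linear breeding trend
#'
#' @param ref_mean Trait mean at the reference year.
#' @param percent_change_per_century Planted percent change per 100 years.
#' @param years Release years to evaluate at.
#' @param ref_year Reference year (default: earliest of `years`).
#' @return Numeric vector of means, one per year.
#' @export
trendMeans <- function(ref_mean, percent_change_per_century, years,
                       ref_year = min(years)) {
  ref_mean * (1 + percent_change_per_century / 100)^((years - ref_year) / 100)
}

#' Configuration for the synthetic-data generator
#'
#' Describes the generative model behind a synthetic shovelomics trait table
#' and a set of synthetic pressure-chamber sweeps: per-cultivar trait means
#' with lognormal plant-level noise and additive season effects on the log
#' scale, and linear Jv(P) sweeps built from the chamber protocol with
#' configurable fractions of deliberately non-linear (saturating) sweeps and
#' of planted three-measure outliers.
#'
#' @param cultivars data.frame with columns `name`, `release_year`.
#' @param traits Named list; each element a list with fields `means`
#'   (per-cultivar vector aligned with `cultivars`), `log_sd` (plant-level sd
#'   on the log scale), `season_sd` (sd of the per-season random intercept on
#'   the log scale) and `integer` (round to a count?).
#' @param plants_per_cultivar_per_season Plants per cultivar and season for
#'   the trait table.
#' @param seasons Character vector of season labels.
#' @param chamber List with fields `krs` (per-cultivar true conductance,
#'   m^3 MPa^-1 s^-1), `krs_log_sd` (total plant-level lognormal spread of
#'   Krs), `area_m2`, `length_m` (per-cultivar geometry means), `geom_log_sd`
#'   (spread of a shared plant-size factor driving geometry and part of Krs),
#'   `flow_noise_sd` (m^3 s^-1), `intercept_range` (m^3 s^-1),
#'   `fraction_nonlinear`, `fraction_outlier`, `outlier_factor`,
#'   `saturation_MPa`, `plants_per_cultivar`.
#' @param seed Default seed for [generateSynthBundle()].
#' @return An object of class `synth_config`.
#' @export
synthConfig <- function(cultivars, traits, plants_per_cultivar_per_season = 15L,
                        seasons = c("season_1", "season_2"), chamber = NULL,
                        seed = 1L) {
  cfg <- structure(list(cultivars = cultivars, traits = traits,
                        plants_per_cultivar_per_season =
                          as.integer(plants_per_cultivar_per_season),
                        seasons = seasons, chamber = chamber,
                        seed = as.integer(seed)),
                   class = "synth_config")
  validateSynthConfig(cfg)
  cfg
}

#' Validate a synthetic-data configuration
#'
#' @param config A [synthConfig()] candidate.
#' @return The config, invisibly; otherwise an error listing every offending
#'   field.
#' @export
validateSynthConfig <- function(config) {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  cv <- config$cultivars
  if (!is.data.frame(cv) || !all(c("name", "release_year") %in% names(cv)) ||
      nrow(cv) < 1L)
    note("cultivars: data.frame with columns name, release_year and >= 1 row")
  nc <- if (is.data.frame(cv)) nrow(cv) else 0L
  if (config$plants_per_cultivar_per_season < 1L)
    note("plants_per_cultivar_per_season: must be >= 1")
  if (length(config$seasons) < 1L) note("seasons: need >= 1 label")
  for (nm in names(config$traits)) {
    tr <- config$traits[[nm]]
    if (length(tr$means) != nc || any(tr$means <= 0))
      note(paste0("traits$", nm, "$means: one positive mean per cultivar"))
    if (is.null(tr$log_sd) || tr$log_sd < 0)
      note(paste0("traits$", nm, "$log_sd: must be >= 0"))
    if (is.null(tr$season_sd) || tr$season_sd < 0)
      note(paste0("traits$", nm, "$season_sd: must be >= 0"))
  }
  ch <- config$chamber
  if (!is.null(ch)) {
    if (length(ch$krs) != nc || any(ch$krs <= 0))
      note("chamber$krs: one positive conductance per cultivar")
    for (f in c("krs_log_sd", "geom_log_sd", "flow_noise_sd"))
      if (is.null(ch[[f]]) || any(ch[[f]] < 0)) note(paste0("chamber$", f, ": must be >= 0"))
    for (f in c("fraction_nonlinear", "fraction_outlier"))
      if (is.null(ch[[f]]) || ch[[f]] < 0 || ch[[f]] > 1)
        note(paste0("chamber$", f, ": must be in [0, 1]"))
    if (is.null(ch$outlier_factor) || ch$outlier_factor <= 0)
      note("chamber$outlier_factor: must be > 0")
    if (length(ch$area_m2) != nc || any(ch$area_m2 <= 0))
      note("chamber$area_m2: one positive area per cultivar")
    if (length(ch$length_m) != nc || any(ch$length_m <= 0))
      note("chamber$length_m: one positive length per cultivar")
    if (is.null(ch$plants_per_cultivar) || ch$plants_per_cultivar < 1L)
      note("chamber$plants_per_cultivar: must be >= 1")
  }
  if (length(errs))
    stop("invalid synthetic-data configuration:\n  ",
         paste(errs, collapse = "\n  "))
  invisible(config)
}

#' Generate a synthetic trait table and pressure-chamber sweeps
#'
#' Draws a plant-level shovelomics trait table (lognormal noise around the
#' per-cultivar means, additive per-season random intercepts on the log
#' scale, count traits rounded to integers >= 0) and a set of pressure-chamber
#' sweeps following the chamber protocol
#' (Jv = intercept + Krs P + noise), with configured fractions of saturating
#' non-linear sweeps and of planted outliers extreme in all three conductance
#' measures. The returned truth record suffices to recompute every planted
#' estimand.
#'
#' @param config A [synthConfig()].
#' @param seed Seed; defaults to the one in the config.
#' @return An object of class `synth_bundle`: list with `traits` (tidy long
#'   data.frame), `sweeps` (list of [pressureSweep()]), `truth` (generating
#'   parameters: config, per-season effects, per-plant chamber truth).
#' @export
generateSynthBundle <- function(config, seed = config$seed) {
  validateSynthConfig(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  cv <- config$cultivars
  npc <- config$plants_per_cultivar_per_season
  seasons <- config$seasons

  season_effects <- list()
  trait_rows <- list()
  for (nm in names(config$traits)) {
    tr <- config$traits[[nm]]
    eff <- stats::rnorm(length(seasons), 0, tr$season_sd)
    names(eff) <- seasons
    season_effects[[nm]] <- eff
    for (i in seq_len(nrow(cv))) {
      for (s in seq_along(seasons)) {
        v <- exp(log(tr$means[i]) + eff[s] + stats::rnorm(npc, 0, tr$log_sd))
        if (isTRUE(tr$integer)) v <- pmax(round(v), 0)
        trait_rows[[length(trait_rows) + 1L]] <- data.frame(
          plant_id = sprintf("%s_%s_p%02d", gsub("[^A-Za-z0-9]", "", cv$name[i]),
                             seasons[s], seq_len(npc)),
          cultivar = cv$name[i],
          release_year = cv$release_year[i],
          season = seasons[s],
          trait = nm,
          value = v,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  traits <- do.call(rbind, trait_rows)
  rownames(traits) <- NULL

  sweeps <- list()
  chamber_truth <- NULL
  ch <- config$chamber
  if (!is.null(ch)) {
    protocol <- chamberProtocol()
    p_sat <- if (is.null(ch$saturation_MPa)) 0.15 else ch$saturation_MPa
    n_pl <- as.integer(ch$plants_per_cultivar)
    truth_rows <- list()
    for (i in seq_len(nrow(cv))) {
      n_nl <- round(ch$fraction_nonlinear * n_pl)
      n_out <- round(ch$fraction_outlier * n_pl)
      status <- rep("clean", n_pl)
      pick <- sample.int(n_pl, min(n_pl, n_nl + n_out))
      if (n_nl > 0L) status[pick[seq_len(n_nl)]] <- "nonlinear"
      if (n_out > 0L && length(pick) > n_nl)
        status[pick[n_nl + seq_len(min(n_out, length(pick) - n_nl))]] <- "outlier"
      # plant-level variation: a shared lognormal size factor drives the
      # geometry and (part of) the conductance, so the normalized measures
      # are less variable than raw Krs, as in real cohorts
      resid_sd <- sqrt(max(ch$krs_log_sd^2 - ch$geom_log_sd^2, 0))
      for (j in seq_len(n_pl)) {
        size <- exp(stats::rnorm(1, 0, ch$geom_log_sd) - ch$geom_log_sd^2 / 2)
        krs_true <- ch$krs[i] * size *
          exp(stats::rnorm(1, 0, resid_sd) - resid_sd^2 / 2)
        # planted outliers are deliberately extreme in all three measures:
        # the factor applies to the cultivar mean, not to a plant draw that
        # could cancel it
        if (status[j] == "outlier") krs_true <- ch$krs[i] * ch$outlier_factor
        area <- ch$area_m2[i] * size
        len <- ch$length_m[i] * size
        intercept <- stats::runif(1, ch$intercept_range[1], ch$intercept_range[2])
        p_eff <- if (status[j] == "nonlinear") pmin(protocol, p_sat) else protocol
        flow <- intercept + krs_true * p_eff +
          stats::rnorm(length(protocol), 0, ch$flow_noise_sd)
        pid <- sprintf("%s_ch%02d", gsub("[^A-Za-z0-9]", "", cv$name[i]), j)
        sweeps[[length(sweeps) + 1L]] <- pressureSweep(
          plant_id = pid, cultivar = cv$name[i],
          release_year = cv$release_year[i],
          pressure_MPa = protocol, flow_m3_s = flow,
          root_surface_area_m2 = area, total_root_length_m = len)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          plant_id = pid, cultivar = cv$name[i], krs_true = krs_true,
          intercept = intercept, status = status[j],
          area_m2 = area, length_m = len, stringsAsFactors = FALSE)
      }
    }
    chamber_truth <- do.call(rbind, truth_rows)
    rownames(chamber_truth) <- NULL
  }

  structure(list(traits = traits, sweeps = sweeps,
                 truth = list(config = config, seed = as.integer(seed),
                              season_effects = season_effects,
                              chamber = chamber_truth)),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synthetic bundle: %d trait rows (%d traits), %d chamber sweeps\n",
              nrow(x$traits), length(unique(x$traits$trait)), length(x$sweeps)))
  invisible(x)
}

#' Synthetic-data configuration matching the packaged trait panel
#'
#' Returns the packaged [synthConfig()] whose per-cultivar trait and
#' conductance means equal the measured panel values ([wheatTraitPanel()]).
#' Plant-level standard deviations are recovered from the panel standard
#' errors at the midpoint sample sizes (field traits n = 29.5, chamber
#' traits n = 10); season effects default to a 5 percent log-scale sd.
#'
#' @param plants_per_cultivar_per_season Field plants per cultivar and season.
#' @param chamber_plants Chamber plants per cultivar.
#' @param fraction_nonlinear,fraction_outlier Planted defect fractions.
#' @param seed Default generation seed.
#' @return A [synthConfig()].
#' @export
table1Defaults <- function(plants_per_cultivar_per_season = 15L,
                           chamber_plants = 10L,
                           fraction_nonlinear = 0.1,
                           fraction_outlier = 0.05,
                           seed = 1L) {
  panel <- wheatTraitPanel()
  n_field <- mean(panelN()$field)
  n_chamber <- mean(panelN()$chamber)
  log_sd <- function(mean, se, n) {
    cvr <- pmin(se * sqrt(n) / mean, 1)
    sqrt(log(1 + cvr^2))
  }
  mk <- function(mean_col, se_col, n, integer = FALSE, season_sd = 0.05) {
    list(means = panel[[mean_col]],
         log_sd = mean(log_sd(panel[[mean_col]], panel[[se_col]], n)),
         season_sd = season_sd, integer = integer)
  }
  traits <- list(
    crown_root_diameter_mm = mk("crown_diameter_mm", "crown_diameter_se", n_field),
    seminal_root_diameter_mm = mk("seminal_diameter_mm", "seminal_diameter_se", n_field),
    lateral_root_diameter_mm = mk("lateral_diameter_mm", "lateral_diameter_se", n_field),
    crown_root_number = mk("crown_number", "crown_number_se", n_field, integer = TRUE),
    seminal_root_number = mk("seminal_number", "seminal_number_se", n_field, integer = TRUE),
    tiller_number = mk("tiller_number", "tiller_number_se", n_field, integer = TRUE),
    branching_density_cm = mk("branching_density_cm", "branching_density_se", n_field)
  )
  chamber <- list(
    krs = panel$krs,
    krs_log_sd = mean(log_sd(panel$krs, panel$krs_se, n_chamber)),
    area_m2 = panel$root_surface_area_cm2 * 1e-4,
    length_m = panel$total_root_length_cm / 100,
    geom_log_sd = mean(log_sd(panel$root_surface_area_cm2,
                              panel$root_surface_area_se, n_chamber)),
    flow_noise_sd = 5e-13,
    intercept_range = c(0, 5e-12),
    fraction_nonlinear = fraction_nonlinear,
    fraction_outlier = fraction_outlier,
    outlier_factor = 5,
    saturation_MPa = 0.15,
    plants_per_cultivar = as.integer(chamber_plants)
  )
  synthConfig(
    cultivars = data.frame(name = panel$cultivar,
                           release_year = panel$release_year,
                           stringsAsFactors = FALSE),
    traits = traits,
    plants_per_cultivar_per_season = plants_per_cultivar_per_season,
    seasons = c("season_2022_23", "season_2023_24"),
    chamber = chamber,
    seed = seed
  )
}
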