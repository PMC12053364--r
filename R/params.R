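#' Per-root-type architectural parameters
#'
#' Growth and branching parameters for one wheat root type. Axis elongation
#' follows the negative-exponential rule L(t) = Lmax (1 - exp(-r0 t / Lmax))
#' where t is axis age, so `initial_elongation_rate` is the slope at emergence
#' and `max_length` the asymptote. Laterals initiate on seminal and crown
#' parents behind the apical unbranched zone at regular spacing
#' (`lateral_spacing` = 1 / branching density).
#'
#' `emergence_delay` is interpreted per type: for seminal roots it is the
#' stagger between successive seminal emergences (root i emerges at i * delay
#' after sowing); for crown roots it is the day the first crown cohort (tiller
#' 0, the main stem) appears; for laterals it is the lag between the parent
#' tip clearing the insertion point plus the apical zone and the lateral
#' actually emerging.
#'
#' @param type_label One of `"seminal"`, `"crown"`, `"lateral"`.
#' @param mean_diameter Mean root diameter, mm.
#' @param diameter_cv Coefficient of variation of the lognormal per-axis
#'   diameter distribution (dimensionless).
#' @param max_length Asymptotic axis length, cm.
#' @param initial_elongation_rate Elongation rate at emergence, cm day^-1.
#' @param apical_unbranched_zone,basal_unbranched_zone Unbranched zone
#'   lengths, cm (parents only; ignored for laterals).
#' @param lateral_spacing Distance between successive laterals on the branched
#'   zone, cm (= 1/branching density); `NA` for laterals.
#' @param emergence_delay Days; see Details.
#' @return An object of class `root_type_params`.
#' @export
rootTypeParams <- function(type_label,
                           mean_diameter,
                           diameter_cv = 0.1,
                           max_length,
                           initial_elongation_rate,
                           apical_unbranched_zone = 2,
                           basal_unbranched_zone = 0.5,
                           lateral_spacing = NA_real_,
                           emergence_delay = 0) {
  type_label <- match.arg(type_label, c("seminal", "crown", "lateral"))
  if (mean_diameter <= 0) stop("mean_diameter must be > 0")
  if (max_length <= 0) stop("max_length must be > 0")
  if (initial_elongation_rate <= 0) stop("initial_elongation_rate must be > 0")
  if (diameter_cv < 0) stop("diameter_cv must be >= 0")
  if (type_label != "lateral") {
    if (!is.finite(lateral_spacing) || lateral_spacing <= 0)
      stop("lateral_spacing must be > 0 for seminal/crown roots")
  } else {
    lateral_spacing <- NA_real_
  }
  structure(list(type_label = type_label,
                 mean_diameter = mean_diameter,
                 diameter_cv = diameter_cv,
                 max_length = max_length,
                 initial_elongation_rate = initial_elongation_rate,
                 apical_unbranched_zone = apical_unbranched_zone,
                 basal_unbranched_zone = basal_unbranched_zone,
                 lateral_spacing = lateral_spacing,
                 emergence_delay = emergence_delay),
            class = "root_type_params")
}

#' Whole-cultivar architecture parameters
#'
#' Bundles the per-type growth parameters with cultivar-level axis dynamics:
#' number of seminal roots, tiller dynamics (one tiller per phyllochron up to
#' the final count, the first cohort standing for the main stem) and the number
#' of crown roots contributed per tiller.
#'
#' @param name Cultivar name.
#' @param release_year Calendar year of commercial release.
#' @param seminal_count_mean,seminal_count_sd Seminal root number per plant
#'   (mean must be >= 1).
#' @param tiller_final_count_mean,tiller_final_count_sd Final tiller number.
#' @param phyllochron Days between successive tiller (and crown cohort)
#'   emergences.
#' @param crown_roots_per_tiller Crown roots added per tiller (> 0).
#' @param root_type_params Named list with `seminal`, `crown`, `lateral`
#'   entries, each a [rootTypeParams()].
#' @return An object of class `cultivar_params`.
#' @seealso [wheatCultivar()] for the packaged calibrated cultivar sets,
#'   [deriveCultivarParams()] to build one from a trait table.
#' @export
cultivarParams <- function(name, release_year,
                           seminal_count_mean, seminal_count_sd = 0,
                           tiller_final_count_mean, tiller_final_count_sd = 0,
                           phyllochron = 9,
                           crown_roots_per_tiller,
                           root_type_params) {
  if (seminal_count_mean < 1) stop("seminal_count_mean must be >= 1")
  if (crown_roots_per_tiller <= 0) stop("crown_roots_per_tiller must be > 0")
  if (phyllochron <= 0) stop("phyllochron must be > 0")
  for (nm in c("seminal", "crown", "lateral")) {
    if (!inherits(root_type_params[[nm]], "root_type_params"))
      stop("root_type_params must contain a '", nm, "' entry")
  }
  structure(list(name = name,
                 release_year = release_year,
                 seminal_count_mean = seminal_count_mean,
                 seminal_count_sd = seminal_count_sd,
                 tiller_final_count_mean = tiller_final_count_mean,
                 tiller_final_count_sd = tiller_final_count_sd,
                 phyllochron = phyllochron,
                 crown_roots_per_tiller = crown_roots_per_tiller,
                 root_type_params = root_type_params[c("seminal", "crown", "lateral")]),
            class = "cultivar_params")
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf("cultivar '%s' (released %d)\n", x$name, as.integer(x$release_year)))
  cat(sprintf("  seminal roots: %.1f +/- %.1f, tillers: %.1f +/- %.1f, crown/tiller: %.2f\n",
              x$seminal_count_mean, x$seminal_count_sd,
              x$tiller_final_count_mean, x$tiller_final_count_sd,
              x$crown_roots_per_tiller))
  cat(sprintf("  phyllochron %.1f d; diameters (mm): crown %.2f, seminal %.2f, lateral %.2f\n",
              x$phyllochron,
              x$root_type_params$crown$mean_diameter,
              x$root_type_params$seminal$mean_diameter,
              x$root_type_params$lateral$mean_diameter))
  invisible(x)
}

#' Derive cultivar architecture parameters from a trait table
#'
#' Sets the cultivar-level parameters to the cultivar's trait means: seminal
#' and tiller counts (mean and across-plant sd), per-type diameters, lateral
#' spacing (= 1 / branching density) and crown roots per tiller (= mean crown
#' count / mean tiller count). Growth-rule parameters not observable with
#' shovelomics (elongation rates, maximum lengths, zones) come from the
#' packaged wheat defaults, scaled by release year.
#'
#' @param traits Trait table in tidy long format: columns `plant_id`,
#'   `cultivar`, `release_year`, `season`, `trait`, `value`. Recognised trait
#'   names: `crown_root_number`, `seminal_root_number`, `tiller_number`,
#'   `crown_root_diameter_mm`, `seminal_root_diameter_mm`,
#'   `lateral_root_diameter_mm`, `branching_density_cm`.
#' @param cultivar Cultivar name to extract.
#' @return A [cultivarParams()] object.
#' @export
deriveCultivarParams <- function(traits, cultivar) {
  stopifnot(is.data.frame(traits))
  rows <- traits[traits$cultivar == cultivar, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown cultivar: '", cultivar, "'")
  tmean <- function(nm) {
    v <- rows$value[rows$trait == nm]
    if (length(v) == 0L) stop("trait '", nm, "' missing for cultivar '", cultivar, "'")
    mean(v)
  }
  tsd <- function(nm) {
    v <- rows$value[rows$trait == nm]
    if (length(v) < 2L) 0 else stats::sd(v)
  }
  year <- rows$release_year[1L]
  sem_n <- tmean("seminal_root_number")
  til_n <- tmean("tiller_number")
  crw_n <- tmean("crown_root_number")
  bd <- tmean("branching_density_cm")
  if (bd <= 0) stop("branching density must be > 0")
  base <- wheatGrowthDefaults(year)
  tp <- list(
    seminal = rootTypeParams("seminal",
                             mean_diameter = tmean("seminal_root_diameter_mm"),
                             max_length = base$seminal$max_length,
                             initial_elongation_rate = base$seminal$initial_elongation_rate,
                             apical_unbranched_zone = base$seminal$apical_unbranched_zone,
                             basal_unbranched_zone = base$seminal$basal_unbranched_zone,
                             lateral_spacing = 1 / bd,
                             emergence_delay = base$seminal$emergence_delay),
    crown = rootTypeParams("crown",
                           mean_diameter = tmean("crown_root_diameter_mm"),
                           max_length = base$crown$max_length,
                           initial_elongation_rate = base$crown$initial_elongation_rate,
                           apical_unbranched_zone = base$crown$apical_unbranched_zone,
                           basal_unbranched_zone = base$crown$basal_unbranched_zone,
                           lateral_spacing = 1 / bd,
                           emergence_delay = base$crown$emergence_delay),
    lateral = rootTypeParams("lateral",
                             mean_diameter = tmean("lateral_root_diameter_mm"),
                             max_length = base$lateral$max_length,
                             initial_elongation_rate = base$lateral$initial_elongation_rate,
                             apical_unbranched_zone = base$lateral$apical_unbranched_zone,
                             basal_unbranched_zone = 0,
                             emergence_delay = base$lateral$emergence_delay)
  )
  cultivarParams(name = cultivar, release_year = year,
                 seminal_count_mean = sem_n, seminal_count_sd = tsd("seminal_root_number"),
                 tiller_final_count_mean = til_n,
                 tiller_final_count_sd = tsd("tiller_number"),
                 phyllochron = base$tillering_window / max(til_n - 1, 1),
                 crown_roots_per_tiller = crw_n / til_n,
                 root_type_params = tp)
}
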