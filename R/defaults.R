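#' Measured trait means for the packaged wheat cultivar panel
#'
#' Per-cultivar means and standard errors of the root morphological traits
#' (field-grown plants, shovelomics at the end of tillering, n = 27-32 plants)
#' and of the hydroponic hydraulic traits measured with the pressure chamber on
#' 10- to 12-day-old plants (n = 8-12). Six German winter wheat cultivars
#' released between 1895 and 2002.
#'
#' @return A data.frame with one row per cultivar. Diameters in mm, branching
#'   density in cm^-1, surface area in cm^2, total length in cm, krs in
#'   m^3 MPa^-1 s^-1 (absolute scale), krs_area in m MPa^-1 s^-1, krs_length
#'   in m^3 MPa^-1 s^-1 m^-1. Columns suffixed `_se` are standard errors on
#'   the same scale.
#' @export
wheatTraitPanel <- function() {
  d <- data.frame(
    cultivar = c("S. Dickkopf", "SG v. Stocken", "Heines II",
                 "Jubilar", "Okapi", "Tommi"),
    release_year = c(1895L, 1920L, 1940L, 1961L, 1978L, 2002L),
    crown_diameter_mm   = c(0.62, 0.58, 0.61, 0.61, 0.63, 0.60),
    crown_diameter_se   = c(0.009, 0.008, 0.009, 0.007, 0.011, 0.010),
    seminal_diameter_mm = c(0.30, 0.30, 0.30, 0.28, 0.32, 0.30),
    seminal_diameter_se = c(0.008, 0.008, 0.009, 0.005, 0.009, 0.007),
    lateral_diameter_mm = c(0.18, 0.17, 0.18, 0.17, 0.17, 0.17),
    lateral_diameter_se = c(0.001, 0.002, 0.002, 0.001, 0.002, 0.002),
    crown_number        = c(15.4, 12.8, 13.1, 13.0, 12.6, 11.9),
    crown_number_se     = c(0.8, 0.7, 0.6, 0.7, 0.6, 0.5),
    seminal_number      = c(8.2, 6.2, 5.6, 5.1, 6.2, 5.9),
    seminal_number_se   = c(0.5, 0.3, 0.2, 0.2, 0.3, 0.3),
    tiller_number       = c(6.6, 4.8, 4.2, 5.6, 4.9, 4.1),
    tiller_number_se    = c(0.2, 0.1, 0.1, 0.2, 0.2, 0.2),
    branching_density_cm    = c(1.10, 1.16, 1.10, 0.98, 0.91, 1.09),
    branching_density_se    = c(0.05, 0.15, 0.05, 0.06, 0.04, 0.06),
    root_surface_area_cm2   = c(7.8, 7.6, 7.4, 7.4, 7.8, 6.4),
    root_surface_area_se    = c(0.5, 0.9, 0.5, 0.9, 0.6, 0.6),
    total_root_length_cm    = c(71.5, 69.2, 69.5, 66.4, 70.4, 57.9),
    total_root_length_se    = c(4.7, 9.1, 6.2, 8.3, 6.0, 6.1),
    krs        = c(1.3, 1.1, 1.3, 1.2, 0.9, 0.7) * 1e-10,
    krs_se     = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1) * 1e-10,
    krs_area   = c(1.7, 1.5, 1.7, 1.6, 1.2, 1.1) * 1e-7,
    krs_area_se = c(0.2, 0.2, 0.2, 0.1, 0.1, 0.1) * 1e-7,
    krs_length = c(1.9, 1.6, 1.8, 1.8, 1.3, 1.2) * 1e-10,
    krs_length_se = c(0.2, 0.1, 0.3, 0.1, 0.2, 0.1) * 1e-10,
    stringsAsFactors = FALSE
  )
  d
}

#' Measured breeding trends for the packaged wheat cultivar panel
#'
#' Per-trait regression results of the release-year trend analysis on
#' log-transformed plant-level data: two-sided p-value of the year effect and
#' back-transformed percent change per 100 years.
#'
#' @return A data.frame with columns `trait`, `p_value`, `percent_change_per_century`.
#' @export
wheatTrendPanel <- function() {
  data.frame(
    trait = c("crown_root_diameter_mm", "seminal_root_diameter_mm",
              "lateral_root_diameter_mm", "crown_root_number",
              "seminal_root_number", "tiller_number", "branching_density_cm",
              "root_surface_area_cm2", "total_root_length_cm",
              "krs", "krs_area", "krs_length"),
    p_value = c(0.74, 0.92, 0.05, 0.001, 0.001, 0.001, 0.27,
                0.22, 0.19, 0.01, 0.01, 0.01),
    percent_change_per_century = c(0.6, 0.3, -3.5, -19.4, -23.4, -31.3, -9.2,
                                   -13.7, -15.1, -51.8, -38.1, -36.8),
    stringsAsFactors = FALSE
  )
}

# Panel sample sizes (ranges printed with the trait tables); midpoints are
# used when converting standard errors to per-plant standard deviations.
panelN <- function() list(field = c(27L, 32L), chamber = c(8L, 12L))

# Growth-rule defaults not observable from shovelomics (elongation rates,
# asymptotic lengths, unbranched zones, emergence timing). Calibrated for
# winter wheat so that 70-day simulations reproduce the documented total-length
# and conductance dynamics. Release-year scaling shrinks the asymptotic axis
# lengths (late-stage root system size) linearly from the oldest (1895,
# factor 1) to the most modern cultivar, leaving initial elongation rates
# untouched: young hydroponic plants of old and modern cultivars are similar
# in size per axis, while field-scale root systems diverge with age.
wheatGrowthDefaults <- function(release_year = 1895) {
  s <- growthScaleForYear(release_year)
  list(
    seminal = list(max_length = 160 * s, initial_elongation_rate = 1.4,
                   apical_unbranched_zone = 2, basal_unbranched_zone = 0.5,
                   emergence_delay = 0.4),
    crown = list(max_length = 160 * s, initial_elongation_rate = 3.5,
                 apical_unbranched_zone = 2, basal_unbranched_zone = 0.5,
                 emergence_delay = 12),
    lateral = list(max_length = 8 * s, initial_elongation_rate = 2,
                   apical_unbranched_zone = 1, basal_unbranched_zone = 0,
                   emergence_delay = 1),
    # tillering spans from the first crown cohort to roughly BBCH 30; the
    # phyllochron is derived per cultivar as window / (final tillers - 1)
    tillering_window = 50
  )
}

# Linear shrinkage of axis growth with release year, anchored at the two
# cultivars the dynamics were calibrated against (1895 -> 1, 2002 -> 0.70).
growthScaleForYear <- function(release_year) {
  s <- 1 + (0.70 - 1) * (release_year - 1895) / (2002 - 1895)
  max(min(s, 1.2), 0.3)
}

#' Packaged architecture parameters for a panel cultivar
#'
#' Builds the calibrated [cultivarParams()] for one of the six packaged
#' cultivars: trait means (counts, diameters, branching density) from the
#' measured panel ([wheatTraitPanel()]), growth-rule parameters from the
#' packaged wheat defaults with release-year scaling. Count standard
#' deviations are recovered from the panel standard errors at the midpoint
#' field sample size.
#'
#' @param name Cultivar name, e.g. `"S. Dickkopf"` or `"Tommi"`.
#' @return A [cultivarParams()] object.
#' @export
wheatCultivar <- function(name = "S. Dickkopf") {
  panel <- wheatTraitPanel()
  i <- match(name, panel$cultivar)
  if (is.na(i)) stop("unknown cultivar '", name, "'; see wheatTraitPanel()$cultivar")
  n_field <- mean(panelN()$field)
  year <- panel$release_year[i]
  base <- wheatGrowthDefaults(year)
  spacing <- 1 / panel$branching_density_cm[i]
  tp <- list(
    seminal = rootTypeParams("seminal",
                             mean_diameter = panel$seminal_diameter_mm[i],
                             max_length = base$seminal$max_length,
                             initial_elongation_rate = base$seminal$initial_elongation_rate,
                             apical_unbranched_zone = base$seminal$apical_unbranched_zone,
                             basal_unbranched_zone = base$seminal$basal_unbranched_zone,
                             lateral_spacing = spacing,
                             emergence_delay = base$seminal$emergence_delay),
    crown = rootTypeParams("crown",
                           mean_diameter = panel$crown_diameter_mm[i],
                           max_length = base$crown$max_length,
                           initial_elongation_rate = base$crown$initial_elongation_rate,
                           apical_unbranched_zone = base$crown$apical_unbranched_zone,
                           basal_unbranched_zone = base$crown$basal_unbranched_zone,
                           lateral_spacing = spacing,
                           emergence_delay = base$crown$emergence_delay),
    lateral = rootTypeParams("lateral",
                             mean_diameter = panel$lateral_diameter_mm[i],
                             max_length = base$lateral$max_length,
                             initial_elongation_rate = base$lateral$initial_elongation_rate,
                             apical_unbranched_zone = base$lateral$apical_unbranched_zone,
                             basal_unbranched_zone = 0,
                             emergence_delay = base$lateral$emergence_delay)
  )
  cultivarParams(
    name = name, release_year = year,
    seminal_count_mean = panel$seminal_number[i],
    seminal_count_sd = panel$seminal_number_se[i] * sqrt(n_field),
    tiller_final_count_mean = panel$tiller_number[i],
    tiller_final_count_sd = panel$tiller_number_se[i] * sqrt(n_field),
    phyllochron = base$tillering_window / max(panel$tiller_number[i] - 1, 1),
    crown_roots_per_tiller = panel$crown_number[i] / panel$tiller_number[i],
    root_type_params = tp
  )
}

#' Packaged age-dependent hydraulic parameters for wheat
#'
#' Piecewise-linear radial conductivity kr(age) and axial conductance kx(age)
#' per root type, on the scale of published wheat root hydraulics. Young
#' segments are radially permeable (kr of order 1e-7 m MPa^-1 s^-1) and kr
#' declines with suberization; kx rises with xylem maturation. The knot values
#' are calibrated jointly with the growth defaults so that simulated
#' conductances of the packaged cultivars reproduce the measured day-10-12
#' whole-root-system values and the documented 70-day dynamics.
#'
#' When a cultivar name is given, both kr and kx are multiplied by a
#' per-cultivar hydraulic scale (1 for the oldest cultivar, smaller for modern
#' ones) calibrated against the measured day-10-12 conductances.
#'
#' @param cultivar Optional cultivar name for per-cultivar hydraulic scaling.
#' @return A [hydraulicParams()] object.
#' @export
wheatHydraulics <- function(cultivar = NULL) {
  kr <- list(
    seminal = piecewiseLinear(c(0, 8, 20, 40, 70),
                              c(7.1e-8, 4.3e-8, 1.4e-8, 6.3e-9, 4.7e-9)),
    crown   = piecewiseLinear(c(0, 8, 20, 40, 70),
                              c(7.1e-8, 4.3e-8, 1.4e-8, 6.3e-9, 4.7e-9)),
    lateral = piecewiseLinear(c(0, 10, 25, 70),
                              c(8.7e-8, 4.3e-8, 1.7e-8, 1.2e-8))
  )
  kx <- list(
    seminal = piecewiseLinear(c(0, 15, 70), c(5.2e-12, 2.1e-11, 4.2e-11)),
    crown   = piecewiseLinear(c(0, 15, 70), c(1.0e-11, 4.2e-11, 8.7e-11)),
    lateral = piecewiseLinear(c(0, 70), c(3.5e-13, 6.9e-13))
  )
  h <- hydraulicParams(kr = kr, kx = kx)
  if (!is.null(cultivar)) {
    s <- hydraulicScaleForCultivar(cultivar)
    h <- scaleHydraulics(h, kr_factor = s, kx_factor = s)
  }
  h
}

# Per-cultivar hydraulic scale, linear in release year between the calibrated
# anchors (oldest cultivar 1, most modern 0.76).
hydraulicScaleForCultivar <- function(cultivar) {
  panel <- wheatTraitPanel()
  i <- match(cultivar, panel$cultivar)
  if (is.na(i)) stop("unknown cultivar '", cultivar, "'")
  year <- panel$release_year[i]
  1 + (0.76 - 1) * (year - 1895) / (2002 - 1895)
}
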