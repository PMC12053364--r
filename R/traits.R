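#' Pairwise comparison of root-diameter distributions between root types
#'
#' Two-sample Kolmogorov-Smirnov tests for every pair of root types
#' (crown-seminal, crown-lateral, seminal-lateral when all three are
#' present), testing whether the per-root diameter distributions differ
#' systematically between types.
#'
#' @param diameters data.frame with columns `root_type` and `diameter_mm`
#'   (one row per measured root).
#' @param min_n Minimum observations per type.
#' @return data.frame with columns `type_a`, `type_b`, `statistic` (KS D),
#'   `p_value`.
#' @export
compareDiameterDistributions <- function(diameters, min_n = 5L) {
  stopifnot(is.data.frame(diameters),
            all(c("root_type", "diameter_mm") %in% names(diameters)))
  types <- unique(diameters$root_type)
  if (length(types) < 2L) stop("need at least 2 root types to compare")
  counts <- table(diameters$root_type)
  if (any(counts < min_n))
    stop("each root type needs >= ", min_n, " observations; short: ",
         paste(names(counts)[counts < min_n], collapse = ", "))
  pairs <- utils::combn(sort(types), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- diameters$diameter_mm[diameters$root_type == pr[1L]]
    b <- diameters$diameter_mm[diameters$root_type == pr[2L]]
    ks <- suppressWarnings(stats::ks.test(a, b))
    data.frame(type_a = pr[1L], type_b = pr[2L],
               statistic = unname(ks$statistic), p_value = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Back-transformed percent change per century
#'
#' Converts a regression slope on the natural-log scale (per year) into the
#' percent change over 100 years implied by the log-linear model:
#' (exp(100 slope) - 1) x 100.
#'
#' @param slope_per_year Slope of log(trait) on release year.
#' @return Percent change per 100 years.
#' @examples
#' percentChangePerCentury(log(2) / 100)  # +100 (doubling per century)
#' @export
percentChangePerCentury <- function(slope_per_year) {
  if (any(!is.finite(slope_per_year))) stop("slope must be finite")
  (exp(100 * slope_per_year) - 1) * 100
}

#' Breeding trend of a trait across release years
#'
#' Fits log(value) ~ release_year on plant-level data. For field traits the
#' growing season enters as a random intercept (restricted maximum likelihood
#' via nlme, the model reducing to ordinary least squares when only one season
#' is present or the mixed fit fails); for hydroponic conductance traits plain
#' OLS is used (`random_season = FALSE`). The year slope is back-transformed
#' into the percent change per century, and residual normality is reported
#' via a Shapiro-Wilk test.
#'
#' @param table Trait table in tidy long format (`plant_id`, `cultivar`,
#'   `release_year`, `season`, `trait`, `value`).
#' @param trait Trait name to model.
#' @param random_season Include the season random intercept?
#' @return An object of class `trend_result`: list with `trait`,
#'   `slope_per_year`, `slope_se`, `ci95` (slope), `p_value`,
#'   `percent_change_per_century`, `percent_change_ci95`, `model_kind`
#'   (`"mixed_random_intercept"` or `"ols"`), `shapiro_p`, `n`.
#' @export
fitYearTrend <- function(table, trait, random_season = TRUE) {
  stopifnot(is.data.frame(table))
  rows <- table[table$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0L) stop("trait '", trait, "' not present in table")
  bad <- rows$value <= 0 | !is.finite(rows$value)
  if (any(bad))
    stop("trait '", trait, "' has non-positive values (cannot log-transform) ",
         "for plants: ", paste(utils::head(rows$plant_id[bad], 5L), collapse = ", "))
  d <- data.frame(logv = log(rows$value), year = rows$release_year,
                  season = factor(rows$season))
  use_mixed <- isTRUE(random_season) && nlevels(d$season) > 1L
  fit <- NULL
  kind <- "ols"
  if (use_mixed) {
    fit <- tryCatch(
      nlme::lme(logv ~ year, random = ~ 1 | season, data = d, method = "REML"),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("mixed model failed; falling back to OLS")
    } else {
      kind <- "mixed_random_intercept"
    }
  }
  if (kind == "mixed_random_intercept") {
    tt <- summary(fit)$tTable
    slope <- tt["year", "Value"]
    se <- tt["year", "Std.Error"]
    p <- tt["year", "p-value"]
    df <- tt["year", "DF"]
    resid_ <- stats::resid(fit, type = "response")
  } else {
    fit <- stats::lm(logv ~ year, data = d)
    sm <- summary(fit)$coefficients
    slope <- sm["year", "Estimate"]
    se <- sm["year", "Std. Error"]
    p <- sm["year", "Pr(>|t|)"]
    df <- fit$df.residual
    resid_ <- stats::resid(fit)
  }
  tcrit <- stats::qt(0.975, df)
  ci <- slope + c(-1, 1) * tcrit * se
  sh <- tryCatch(stats::shapiro.test(resid_)$p.value, error = function(e) NA_real_)
  structure(list(trait = trait,
                 slope_per_year = unname(slope),
                 slope_se = unname(se),
                 ci95 = unname(ci),
                 p_value = unname(p),
                 percent_change_per_century = percentChangePerCentury(slope),
                 percent_change_ci95 = percentChangePerCentury(ci),
                 model_kind = kind,
                 shapiro_p = sh,
                 n = nrow(d)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend for '%s' (%s, n = %d)\n", x$trait, x$model_kind, x$n))
  cat(sprintf("  slope %.3g log-units/yr (95%% CI %.3g to %.3g), p = %.3g\n",
              x$slope_per_year, x$ci95[1], x$ci95[2], x$p_value))
  cat(sprintf("  percent change per century: %+.1f%% (CI %+.1f%% to %+.1f%%)\n",
              x$percent_change_per_century, x$percent_change_ci95[1],
              x$percent_change_ci95[2]))
  cat(sprintf("  Shapiro-Wilk residual normality p = %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Cultivar contrasts for one trait
#'
#' One-way ANOVA on log-transformed plant-level values with cultivar as a
#' categorical factor, followed by Tukey HSD adjusted pairwise comparisons —
#' used to assess whether release-year trends are driven by specific
#' cultivars (e.g. the oldest one).
#'
#' @param table Tidy long trait table.
#' @param trait Trait name.
#' @return List with `anova` (the ANOVA table) and `tukey` (data.frame of
#'   pairwise comparisons with adjusted p-values).
#' @export
cultivarContrasts <- function(table, trait) {
  rows <- table[table$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0L) stop("trait '", trait, "' not present")
  if (any(rows$value <= 0)) stop("values must be > 0 for log transform")
  counts <- base::table(rows$cultivar)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 cultivars with >= 2 plants each")
  d <- data.frame(logv = log(rows$value), cultivar = factor(rows$cultivar))
  fit <- stats::aov(logv ~ cultivar, data = d)
  tk <- stats::TukeyHSD(fit)$cultivar
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(anova = summary(fit)[[1L]], tukey = tukey)
}

#' Relationship between crown root number and tiller number
#'
#' Pooled OLS of per-plant crown root number on tiller number across
#' cultivars, testing the link between crown root production and tillering.
#'
#' @param table Tidy long trait table containing `crown_root_number` and
#'   `tiller_number` for the same plants.
#' @return List with `slope`, `intercept`, `p_value`, `r_squared`, `n`.
#' @export
crownTillerRelation <- function(table) {
  cr <- table[table$trait == "crown_root_number", c("plant_id", "value")]
  ti <- table[table$trait == "tiller_number", c("plant_id", "value")]
  m <- merge(cr, ti, by = "plant_id", suffixes = c("_crown", "_tiller"))
  if (nrow(m) < 3L) stop("need >= 3 plants with both crown and tiller counts")
  if (stats::var(m$value_tiller) == 0)
    stop("tiller number is constant; slope undefined")
  fit <- stats::lm(value_crown ~ value_tiller, data = m)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = sm$coefficients["value_tiller", "Pr(>|t|)"],
       r_squared = sm$r.squared,
       n = nrow(m))
}
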