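#' Pressure protocol applied during a chamber sweep
#'
#' The measurement sequence applied after the pre-pressurization phase:
#' 0.16, 0.24, 0.1, 0.32 and 0.24 MPa (the 0.24 MPa step is deliberately
#' repeated and enters the fit as two separate points).
#'
#' @return Numeric vector of pressures in MPa.
#' @export
chamberProtocol <- function() c(0.16, 0.24, 0.10, 0.32, 0.24)

#' Construct a pressure-chamber sweep record
#'
#' One de-topped plant's ordered (pressure, flow) readings together with the
#' scanned root-system geometry used for normalization.
#'
#' @param plant_id Plant identifier.
#' @param cultivar Cultivar name.
#' @param release_year Release year of the cultivar.
#' @param pressure_MPa Applied pressures, MPa (> 0, >= 3 distinct values).
#' @param flow_m3_s Recorded sap flow at each pressure, m^3 s^-1.
#' @param root_surface_area_m2 Total root surface area, m^2 (> 0).
#' @param total_root_length_m Total root length, m (> 0).
#' @return An object of class `pressure_sweep`.
#' @export
pressureSweep <- function(plant_id, cultivar, release_year,
                          pressure_MPa, flow_m3_s,
                          root_surface_area_m2, total_root_length_m) {
  if (length(pressure_MPa) != length(flow_m3_s))
    stop("pressure and flow vectors must have equal length")
  if (any(pressure_MPa <= 0)) stop("pressures must be > 0")
  if (length(unique(pressure_MPa)) < 3L)
    stop("a sweep needs >= 3 distinct pressures")
  if (root_surface_area_m2 <= 0 || total_root_length_m <= 0)
    stop("root surface area and length must be > 0")
  structure(list(plant_id = as.character(plant_id),
                 cultivar = as.character(cultivar),
                 release_year = release_year,
                 pressure_MPa = as.numeric(pressure_MPa),
                 flow_m3_s = as.numeric(flow_m3_s),
                 root_surface_area_m2 = root_surface_area_m2,
                 total_root_length_m = total_root_length_m),
            class = "pressure_sweep")
}

#' Estimate Krs from one pressure-chamber sweep
#'
#' Ordinary least squares of sap flow Jv on applied pressure P with a free
#' intercept; the slope of the linear Jv(P) relationship is the whole
#' root-system conductance Krs. A sweep passes quality control when the fit is
#' acceptably linear (r-squared at or above `r2_threshold`) and the slope is
#' positive. Repeated pressures enter as separate points.
#'
#' @param sweep A [pressureSweep()].
#' @param r2_threshold Minimum r-squared for the linearity check.
#' @return A one-row data.frame (class `krs_estimate`): `plant_id`,
#'   `cultivar`, `release_year`, `krs`, `intercept`, `r_squared`, `krs_area`,
#'   `krs_length`, `qc_pass`, `outlier` (initialized `FALSE`; see
#'   [filterOutliers()]).
#' @export
fitSweep <- function(sweep, r2_threshold = 0.95) {
  stopifnot(inherits(sweep, "pressure_sweep"))
  fit <- stats::lm(flow ~ pressure,
                   data = data.frame(pressure = sweep$pressure_MPa,
                                     flow = sweep$flow_m3_s))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- summary(fit)$r.squared
  out <- data.frame(
    plant_id = sweep$plant_id,
    cultivar = sweep$cultivar,
    release_year = sweep$release_year,
    krs = slope,
    intercept = intercept,
    r_squared = r2,
    krs_area = slope / sweep$root_surface_area_m2,
    krs_length = slope / sweep$total_root_length_m,
    qc_pass = is.finite(r2) && r2 >= r2_threshold && slope > 0,
    outlier = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("krs_estimate", class(out))
  out
}

#' Fit a collection of sweeps
#'
#' @param sweeps List of [pressureSweep()] objects.
#' @param r2_threshold Passed to [fitSweep()].
#' @return data.frame of stacked [fitSweep()] rows.
#' @export
fitSweeps <- function(sweeps, r2_threshold = 0.95) {
  out <- do.call(rbind, lapply(sweeps, fitSweep, r2_threshold = r2_threshold))
  rownames(out) <- NULL
  out
}

#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs' test: G = max |x - mean(x)| / sd(x), with the critical
#' value at significance `alpha` computed from the t distribution,
#' G_crit = ((N-1)/sqrt(N)) sqrt(t^2 / (N - 2 + t^2)) where
#' t = qt(1 - alpha/(2N), N-2).
#'
#' @param x Numeric vector (length >= 3).
#' @param alpha Significance level.
#' @return List with `index` of the most extreme value, `G`, `critical`, and
#'   `significant`.
#' @export
grubbsTest <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3L) stop("Grubbs' test needs at least 3 observations")
  s <- stats::sd(x)
  if (s == 0) return(list(index = NA_integer_, G = 0,
                          critical = Inf, significant = FALSE))
  dev <- abs(x - mean(x))
  idx <- which.max(dev)
  G <- dev[idx] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2L)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2L + tq^2))
  list(index = idx, G = unname(G), critical = crit, significant = G > crit)
}

# Iterative single-outlier Grubbs flags (max `max_iter` removals).
grubbsFlags <- function(x, alpha = 0.05, max_iter = 2L) {
  flags <- rep(FALSE, length(x))
  active <- seq_along(x)
  for (k in seq_len(max_iter)) {
    if (length(active) < 3L) break
    g <- grubbsTest(x[active], alpha)
    if (!g$significant) break
    flags[active[g$index]] <- TRUE
    active <- active[-g$index]
  }
  flags
}

#' Flag outlying Krs estimates per cultivar
#'
#' Within each cultivar, among quality-passing estimates, a plant is flagged
#' as an outlier when its value lies outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] for
#' **all three** of `krs`, `krs_area` and `krs_length`, and iterative
#' two-sided Grubbs' tests at `alpha` confirm it in all three measures
#' (at most two removals per group and measure). With `rule = "any"` the IQR
#' condition becomes a disjunction over the three measures. Flagged rows are
#' annotated, never dropped.
#'
#' @param estimates data.frame of [fitSweep()] rows.
#' @param alpha Grubbs significance level.
#' @param rule `"all"` (default, conjunction over the three measures) or
#'   `"any"`.
#' @return The input data.frame with the `outlier` column filled in.
#' @export
filterOutliers <- function(estimates, alpha = 0.05, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(estimates))
  estimates$outlier <- FALSE
  measures <- c("krs", "krs_area", "krs_length")
  for (cv in unique(estimates$cultivar)) {
    idx <- which(estimates$cultivar == cv & estimates$qc_pass)
    if (length(idx) == 0L) next
    iqr_out <- sapply(measures, function(mm) {
      v <- estimates[[mm]][idx]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      lo <- q[1] - 1.5 * (q[2] - q[1])
      hi <- q[2] + 1.5 * (q[2] - q[1])
      v < lo | v > hi
    })
    iqr_flag <- if (rule == "all") apply(iqr_out, 1L, all) else apply(iqr_out, 1L, any)
    if (length(idx) < 3L) {
      if (any(iqr_flag))
        warning("cultivar '", cv, "': fewer than 3 estimates, ",
                "IQR-only outlier flag (Grubbs not applicable)")
      estimates$outlier[idx] <- iqr_flag
      next
    }
    gr <- sapply(measures, function(mm)
      grubbsFlags(estimates[[mm]][idx], alpha = alpha))
    gr_flag <- if (rule == "all") apply(gr, 1L, all) else apply(gr, 1L, any)
    estimates$outlier[idx] <- iqr_flag & gr_flag
  }
  estimates
}

#' Per-cultivar summary of Krs estimates
#'
#' Mean and standard error per cultivar of the quality-passing, non-outlier
#' estimates, for each of the three conductance measures.
#'
#' @param estimates data.frame of (optionally outlier-annotated)
#'   [fitSweep()] rows.
#' @return data.frame with one row per retained cultivar: `cultivar`,
#'   `release_year`, `n`, then `mean` and `se` columns for `krs`, `krs_area`,
#'   `krs_length`. SE is `NA` for single-estimate groups.
#' @export
summarizeByCultivar <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  keep <- estimates[estimates$qc_pass & !estimates$outlier, , drop = FALSE]
  cultivars <- unique(estimates$cultivar)
  rows <- list()
  for (cv in cultivars) {
    g <- keep[keep$cultivar == cv, , drop = FALSE]
    if (nrow(g) == 0L) {
      warning("cultivar '", cv, "' has no usable estimates; omitted")
      next
    }
    se <- function(v) if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    rows[[cv]] <- data.frame(
      cultivar = cv, release_year = g$release_year[1L], n = nrow(g),
      krs_mean = mean(g$krs), krs_se = se(g$krs),
      krs_area_mean = mean(g$krs_area), krs_area_se = se(g$krs_area),
      krs_length_mean = mean(g$krs_length), krs_length_se = se(g$krs_length),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
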