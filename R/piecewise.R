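#' Piecewise-linear age-dependent property
#'
#' Represents a non-negative property of root age (radial conductivity kr or
#' axial conductance kx) as a piecewise-linear function of age in days.
#' Between knots the value is linearly interpolated; beyond the first or last
#' knot it is held constant (clamped extrapolation).
#'
#' @param age Numeric vector of knot ages in days, strictly increasing.
#' @param value Numeric vector of knot values (same length as `age`), all >= 0.
#' @return An object of class `piecewise_linear`.
#' @examples
#' kr <- piecewiseLinear(c(0, 10), c(1e-7, 2e-7))
#' propertyAt(kr, 5)   # 1.5e-7
#' propertyAt(kr, 50)  # clamped to 2e-7
#' @export
piecewiseLinear <- function(age, value) {
  if (length(age) < 1L || length(age) != length(value))
    stop("'age' and 'value' must be non-empty vectors of equal length")
  if (any(!is.finite(age)) || any(!is.finite(value)))
    stop("knots must be finite")
  if (is.unsorted(age, strictly = TRUE))
    stop("knot ages must be strictly increasing")
  if (any(value < 0))
    stop("knot values must be >= 0")
  structure(list(age = as.numeric(age), value = as.numeric(value)),
            class = "piecewise_linear")
}

#' Evaluate a piecewise-linear property at given ages
#'
#' @param f A [piecewiseLinear()] object.
#' @param age Numeric vector of ages in days, all >= 0.
#' @return Numeric vector of interpolated values.
#' @export
propertyAt <- function(f, age) {
  stopifnot(inherits(f, "piecewise_linear"))
  if (any(age < 0)) stop("age must be >= 0")
  if (length(f$age) == 1L) return(rep(f$value, length.out = length(age)))
  stats::approx(f$age, f$value, xout = age, rule = 2)$y
}

#' @export
print.piecewise_linear <- function(x, ...) {
  cat("piecewise-linear property,", length(x$age), "knots\n")
  print(data.frame(age_d = x$age, value = x$value), row.names = FALSE)
  invisible(x)
}

#' Per-root-type hydraulic parameters
#'
#' Bundles the radial conductivity kr(age) (m MPa^-1 s^-1, per unit root
#' surface area) and axial conductance kx(age) (m^4 MPa^-1 s^-1) for the three
#' wheat root types as piecewise-linear functions of segment age.
#'
#' @param kr Named list with elements `seminal`, `crown`, `lateral`, each a
#'   [piecewiseLinear()] function for radial conductivity.
#' @param kx Named list with the same structure for axial conductance.
#' @return An object of class `hydraulic_params`.
#' @seealso [wheatHydraulics()] for the packaged calibrated defaults.
#' @export
hydraulicParams <- function(kr, kx) {
  types <- c("seminal", "crown", "lateral")
  for (nm in types) {
    if (!inherits(kr[[nm]], "piecewise_linear"))
      stop("kr must contain a piecewise_linear entry for type '", nm, "'")
    if (!inherits(kx[[nm]], "piecewise_linear"))
      stop("kx must contain a piecewise_linear entry for type '", nm, "'")
  }
  structure(list(kr = kr[types], kx = kx[types]), class = "hydraulic_params")
}

#' Rescale hydraulic parameters by constant factors
#'
#' Multiplies every kr knot by `kr_factor` and every kx knot by `kx_factor`.
#' Used both for per-cultivar hydraulic scaling and for sensitivity sweeps.
#'
#' @param hydraulics A [hydraulicParams()] object.
#' @param kr_factor,kx_factor Positive multipliers.
#' @return A rescaled `hydraulic_params` object.
#' @export
scaleHydraulics <- function(hydraulics, kr_factor = 1, kx_factor = 1) {
  stopifnot(inherits(hydraulics, "hydraulic_params"))
  if (kr_factor <= 0 || kx_factor <= 0) stop("scale factors must be > 0")
  sc <- function(f, a) piecewiseLinear(f$age, f$value * a)
  hydraulicParams(kr = lapply(hydraulics$kr, sc, a = kr_factor),
                  kx = lapply(hydraulics$kx, sc, a = kx_factor))
}

#' @export
print.hydraulic_params <- function(x, ...) {
  cat("hydraulic parameters (kr: m MPa^-1 s^-1, kx: m^4 MPa^-1 s^-1)\n")
  for (nm in names(x$kr)) {
    cat(sprintf("  %-8s kr knots: %s\n", nm,
                paste(sprintf("(%g d, %.3g)", x$kr[[nm]]$age, x$kr[[nm]]$value),
                      collapse = " ")))
    cat(sprintf("  %-8s kx knots: %s\n", nm,
                paste(sprintf("(%g d, %.3g)", x$kx[[nm]]$age, x$kx[[nm]]$value),
                      collapse = " ")))
  }
  invisible(x)
}
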