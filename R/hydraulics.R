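#' Conductance of a uniform root segment with distributed radial entry
#'
#' Exact transmission-line solution for the standing conductance of a root
#' segment of length `l` and radius `r` with uniform radial conductivity `kr`
#' (per unit surface area) and axial conductance `kx`, terminated distally by
#' a network of conductance `K_distal`. With
#' tau = sqrt(2 pi r kr / kx) (m^-1) and kappa = sqrt(2 pi r kr kx)
#' (m^3 MPa^-1 s^-1), the conductance seen from the proximal end is
#'
#'   K = kappa (K_distal + kappa tanh(tau l)) / (kappa + K_distal tanh(tau l))
#'
#' For `kr = 0` the segment is a pure axial resistor and the series
#' combination of `kx / l` with `K_distal` is returned. All arguments are
#' vectorized.
#'
#' @param l Segment length, m (> 0).
#' @param r Segment radius, m (> 0).
#' @param kr Radial conductivity, m MPa^-1 s^-1 (>= 0).
#' @param kx Axial conductance, m^4 MPa^-1 s^-1 (> 0).
#' @param K_distal Conductance of the network distal to the segment,
#'   m^3 MPa^-1 s^-1 (>= 0).
#' @return Conductance in m^3 MPa^-1 s^-1.
#' @examples
#' segmentConductance(0.1, 3e-4, 1e-7, 1e-12, 0)  # ~1.21e-11
#' @export
segmentConductance <- function(l, r, kr, kx, K_distal = 0) {
  if (any(l <= 0)) stop("segment length must be > 0")
  if (any(r <= 0)) stop("segment radius must be > 0")
  if (any(kx <= 0)) stop("axial conductance kx must be > 0")
  if (any(kr < 0)) stop("radial conductivity kr must be >= 0")
  if (any(K_distal < 0)) stop("K_distal must be >= 0")
  n <- max(length(l), length(r), length(kr), length(kx), length(K_distal))
  l <- rep_len(l, n); r <- rep_len(r, n); kr <- rep_len(kr, n)
  kx <- rep_len(kx, n); K_distal <- rep_len(K_distal, n)
  c2pr <- 2 * pi * r * kr
  kappa <- sqrt(c2pr * kx)
  th <- tanh(sqrt(c2pr / kx) * l)
  out <- numeric(n)
  pos <- kr > 0
  out[pos] <- kappa[pos] * (K_distal[pos] + kappa[pos] * th[pos]) /
    (kappa[pos] + K_distal[pos] * th[pos])
  if (any(!pos)) {
    g_ax <- kx[!pos] / l[!pos]
    kd <- K_distal[!pos]
    out[!pos] <- ifelse(kd == 0, 0, kd * g_ax / (kd + g_ax))
  }
  out
}

# Per-segment kr/kx assignment by root type and local age.
segmentProperties <- function(seg, hydraulics, t) {
  age <- pmax(t - seg$creation_day, 0)
  kr <- numeric(nrow(seg))
  kx <- numeric(nrow(seg))
  for (ty in unique(seg$type)) {
    idx <- seg$type == ty
    kr[idx] <- propertyAt(hydraulics$kr[[ty]], age[idx])
    kx[idx] <- propertyAt(hydraulics$kx[[ty]], age[idx])
  }
  list(kr = kr, kx = kx)
}

# Restrict the segment table to segments existing at time t with parent ids
# remapped to the new row indices (see rootSnapshot()).
segmentsAt <- function(system, t) rootSnapshot(system, t)$segments

#' Whole-root-system conductance of a root system
#'
#' Computes Krs, the conductance linking the water potential difference
#' between a uniform external medium and the root collar to the collar sap
#' flow, by folding the segment tree from the tips to the collar: each
#' segment's conductance is the transmission-line solution
#' ([segmentConductance()]) with `K_distal` equal to the plain sum of its
#' children's conductances (parallel combination at an ideal junction), and
#' Krs is the sum over segments attached at the collar. kr and kx are
#' evaluated per segment from its local age (`t` minus creation time).
#'
#' Segments produced by [simulateGrowth()] each carry a single creation time
#' (one growth increment per time step), so every segment is age-uniform at
#' the growth discretization and no further age subdivision is required;
#' `age_resolution` is retained to document that resolution and must not be
#' finer than the segment time stamps support.
#'
#' @param system A `root_system`.
#' @param hydraulics A [hydraulicParams()] object.
#' @param t Evaluation time, days; defaults to the system's time stamp.
#'   Segments created after `t` are excluded.
#' @param age_resolution Age resolution, days; defaults to the growth `dt`.
#' @return An object of class `krs_result`: list with `krs`
#'   (m^3 MPa^-1 s^-1), `krs_area` (m MPa^-1 s^-1), `krs_length`
#'   (m^3 MPa^-1 s^-1 m^-1), `time`, `total_length_m`, `surface_area_m2`.
#' @export
computeKrs <- function(system, hydraulics, t = system$simulation_time,
                       age_resolution = system$dt) {
  stopifnot(inherits(system, "root_system"),
            inherits(hydraulics, "hydraulic_params"))
  seg <- segmentsAt(system, t)
  if (nrow(seg) == 0L) {
    return(structure(list(krs = 0, krs_area = NA_real_, krs_length = NA_real_,
                          time = t, total_length_m = 0, surface_area_m2 = 0),
                     class = "krs_result"))
  }
  pr <- segmentProperties(seg, hydraulics, t)
  krs <- foldConductance(seg$parent_id, seg$depth, seg$length_m, seg$radius_m,
                         pr$kr, pr$kx)
  len <- sum(seg$length_m)
  area <- sum(2 * pi * seg$radius_m * seg$length_m)
  structure(list(krs = krs, krs_area = krs / area, krs_length = krs / len,
                 time = t, total_length_m = len, surface_area_m2 = area),
            class = "krs_result")
}

# Tips-to-collar fold, vectorized over depth levels.
foldConductance <- function(parent_id, depth, length_m, radius_m, kr, kx) {
  n <- length(parent_id)
  c2pr <- 2 * pi * radius_m * kr
  kappa <- sqrt(c2pr * kx)
  th <- tanh(sqrt(c2pr / kx) * length_m)
  g_ax <- kx / length_m
  K <- numeric(n)
  Kd <- numeric(n)
  levels <- split(seq_len(n), depth)
  for (lev in rev(seq_along(levels))) {
    idx <- levels[[lev]]
    kd <- Kd[idx]
    kp <- kappa[idx]; t_ <- th[idx]
    Ki <- ifelse(kr[idx] > 0,
                 kp * (kd + kp * t_) / (kp + kd * t_),
                 ifelse(kd == 0, 0, kd * g_ax[idx] / (kd + g_ax[idx])))
    K[idx] <- Ki
    p <- parent_id[idx]
    sel <- p > 0L
    if (any(sel)) {
      agg <- rowsum(Ki[sel], p[sel])
      tgt <- as.integer(rownames(agg))
      Kd[tgt] <- Kd[tgt] + agg[, 1L]
    }
  }
  sum(K[parent_id == 0L])
}

#' @export
print.krs_result <- function(x, ...) {
  cat(sprintf("Krs at day %.1f: %.4g m^3 MPa^-1 s^-1\n", x$time, x$krs))
  cat(sprintf("  per area: %.4g m MPa^-1 s^-1; per length: %.4g m^3 MPa^-1 s^-1 m^-1\n",
              x$krs_area, x$krs_length))
  cat(sprintf("  total length %.3f m, surface area %.2f cm^2\n",
              x$total_length_m, x$surface_area_m2 * 1e4))
  invisible(x)
}

#' Krs development over the growth trajectory
#'
#' Evaluates [computeKrs()] at a series of times on the same simulated root
#' system, giving the development of whole-root-system conductance with plant
#' age.
#'
#' @param system A `root_system` (full simulation).
#' @param hydraulics A [hydraulicParams()] object.
#' @param times Evaluation times in days; defaults to every full day from 1
#'   to the simulation end.
#' @return data.frame with columns `time`, `krs`, `krs_area`, `krs_length`,
#'   `total_length_m`, `surface_area_m2`.
#' @export
krsTrajectory <- function(system, hydraulics,
                          times = seq(1, floor(system$simulation_time))) {
  stopifnot(inherits(system, "root_system"))
  if (length(times) == 0L)
    return(data.frame(time = numeric(), krs = numeric(), krs_area = numeric(),
                      krs_length = numeric(), total_length_m = numeric(),
                      surface_area_m2 = numeric()))
  if (is.unsorted(times)) stop("times must be increasing")
  rows <- lapply(times, function(t) {
    res <- computeKrs(system, hydraulics, t = t)
    data.frame(time = t, krs = res$krs, krs_area = res$krs_area,
               krs_length = res$krs_length,
               total_length_m = res$total_length_m,
               surface_area_m2 = res$surface_area_m2)
  })
  do.call(rbind, rows)
}

#' Sensitivity of Krs to global rescaling of kr and/or kx
#'
#' Multiplies the radial and/or axial conductivities by each factor and
#' recomputes Krs on a fixed root system, quantifying how strongly the
#' network conductance responds to segment-scale parameter uncertainty.
#'
#' @param system A `root_system`.
#' @param hydraulics Baseline [hydraulicParams()].
#' @param factors Positive multipliers.
#' @param target `"both"`, `"kr"` or `"kx"` — which property to rescale.
#' @param t Evaluation time, days.
#' @return data.frame with columns `factor`, `target`, `krs`, `krs_area`,
#'   `krs_length`.
#' @export
sensitivitySweep <- function(system, hydraulics, factors,
                             target = c("both", "kr", "kx"),
                             t = system$simulation_time) {
  target <- match.arg(target)
  if (any(factors <= 0)) stop("factors must be > 0")
  rows <- lapply(factors, function(f) {
    h <- switch(target,
                both = scaleHydraulics(hydraulics, f, f),
                kr = scaleHydraulics(hydraulics, kr_factor = f),
                kx = scaleHydraulics(hydraulics, kx_factor = f))
    res <- computeKrs(system, h, t = t)
    data.frame(factor = f, target = target, krs = res$krs,
               krs_area = res$krs_area, krs_length = res$krs_length)
  })
  do.call(rbind, rows)
}
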