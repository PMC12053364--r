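#' @keywords internal
# Negative-exponential axis length (cm) at axis age a (days).
negExpLength <- function(a, Lmax, r0) {
  a <- pmax(a, 0)
  Lmax * (1 - exp(-r0 * a / Lmax))
}

# Segment grid for one axis: emergence time e, asymptote Lmax (cm), initial
# rate r0 (cm/d). Each segment covers one growth interval of width dt and is
# recorded at the interval start (its creation time); increments below
# `min_increment` (cm) are dropped, truncating the geometric tail of the
# negative-exponential growth curve.
axisSegments <- function(e, Lmax, r0, dt, t_end, min_increment = 0.01) {
  if (e >= t_end) return(NULL)
  m <- ceiling((t_end - e) / dt - 1e-9)
  starts <- e + (seq_len(m) - 1) * dt
  ends <- pmin(starts + dt, t_end)
  len <- negExpLength(ends - e, Lmax, r0) - negExpLength(starts - e, Lmax, r0)
  keep <- len >= min_increment
  if (!any(keep)) {
    # always keep at least the first increment so an emerged axis exists
    keep[1] <- TRUE
  } else {
    keep <- seq_len(m) <= max(which(keep))
  }
  list(creation = starts[keep], length_cm = len[keep])
}

#' Simulate winter wheat root system development
#'
#' Stochastic simulation of the root architecture of a single wheat plant.
#' Seminal roots emerge in the first days after sowing (staggered by the
#' seminal emergence delay); tillers appear every phyllochron up to the drawn
#' final tiller count, each cohort (the first standing for the main stem)
#' contributing `crown_roots_per_tiller` crown roots; laterals initiate on
#' seminal and crown parents behind the apical unbranched zone at regular
#' spacing. Every axis elongates with the negative-exponential rule
#' L(t) = Lmax (1 - exp(-r0 t / Lmax)). Growth is discretized in steps of
#' `dt`: each step appends a segment whose length is the elongation increment,
#' time-stamped with the step start, so the segment tree is also the full
#' growth trajectory (see [rootSnapshot()]).
#'
#' Geometry is topological: segments carry length, radius, type, age and the
#' parent link, which is all the hydraulic network model requires; 3D
#' coordinates are fabricated only on RSML export.
#'
#' @param params A [cultivarParams()] object.
#' @param t_end Simulation end, days after sowing (>= 0).
#' @param dt Time step, days (0 < dt <= 1).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param min_increment Smallest recorded elongation increment, cm.
#' @return An object of class `root_system`: a list with `segments` (a
#'   data.frame with columns `segment_id`, `parent_id` (0 = collar),
#'   `root_id`, `type`, `length_m`, `radius_m`, `creation_day`, `depth`),
#'   `simulation_time`, `dt`, `seed` and `cultivar`.
#' @examples
#' rs <- simulateGrowth(wheatCultivar("Tommi"), t_end = 20, dt = 0.5, seed = 1)
#' totalLength(rs)
#' @export
simulateGrowth <- function(params, t_end, dt = 0.5, seed = 1L,
                           min_increment = 0.01) {
  stopifnot(inherits(params, "cultivar_params"))
  if (!is.finite(t_end) || t_end < 0) stop("t_end must be >= 0")
  if (!is.finite(dt) || dt <= 0 || dt > 1) stop("dt must satisfy 0 < dt <= 1")
  empty <- data.frame(segment_id = integer(), parent_id = integer(),
                      root_id = integer(), type = character(),
                      length_m = numeric(), radius_m = numeric(),
                      creation_day = numeric(), depth = integer(),
                      stringsAsFactors = FALSE)
  sys <- structure(list(segments = empty, simulation_time = t_end, dt = dt,
                        seed = as.integer(seed), cultivar = params$name),
                   class = "root_system")
  if (t_end == 0) return(sys)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  tp <- params$root_type_params
  n_sem <- max(1L, round(stats::rnorm(1, params$seminal_count_mean,
                                      params$seminal_count_sd)))
  n_til <- max(1L, round(stats::rnorm(1, params$tiller_final_count_mean,
                                      params$tiller_final_count_sd)))

  sem_emerg <- tp$seminal$emergence_delay * seq_len(n_sem)
  cohort_times <- tp$crown$emergence_delay +
    (seq_len(n_til) - 1) * params$phyllochron
  cum_crown <- round(seq_len(n_til) * params$crown_roots_per_tiller)
  cohort_counts <- diff(c(0, cum_crown))
  crown_emerg <- rep(cohort_times, cohort_counts)

  axile_type <- c(rep("seminal", n_sem), rep("crown", length(crown_emerg)))
  axile_emerg <- c(sem_emerg, crown_emerg)
  keep <- axile_emerg < t_end
  axile_type <- axile_type[keep]
  axile_emerg <- axile_emerg[keep]
  n_axile <- length(axile_type)
  if (n_axile == 0L) return(sys)

  drawDiameter <- function(n, mean_mm, cv) {
    if (cv <= 0) return(rep(mean_mm, n))
    sigma <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mean_mm) - sigma^2 / 2, sdlog = sigma)
  }
  axile_diam <- numeric(n_axile)
  for (ty in c("seminal", "crown")) {
    idx <- which(axile_type == ty)
    axile_diam[idx] <- drawDiameter(length(idx), tp[[ty]]$mean_diameter,
                                    tp[[ty]]$diameter_cv)
  }

  # accumulators over all axes
  acc <- list(parent = list(), root = list(), type = list(), len = list(),
              rad = list(), creation = list())
  n_seg_total <- 0L
  push <- function(parent, root, type, len_cm, rad_mm, creation) {
    k <- length(acc$parent) + 1L
    acc$parent[[k]] <<- parent
    acc$root[[k]] <<- rep.int(root, length(len_cm))
    acc$type[[k]] <<- rep.int(type, length(len_cm))
    acc$len[[k]] <<- len_cm
    acc$rad[[k]] <<- rep.int(rad_mm, length(len_cm))
    acc$creation[[k]] <<- creation
    n_seg_total <<- n_seg_total + length(len_cm)
  }

  lat <- tp$lateral
  lat_parent_seg <- integer()   # global id of parent segment for each lateral
  lat_emerg <- numeric()
  root_counter <- 0L

  for (i in seq_len(n_axile)) {
    ty <- axile_type[i]
    p <- tp[[ty]]
    g <- axisSegments(axile_emerg[i], p$max_length, p$initial_elongation_rate,
                      dt, t_end, min_increment)
    if (is.null(g)) next
    ns <- length(g$length_cm)
    root_counter <- root_counter + 1L
    first_id <- n_seg_total + 1L
    parent <- c(0L, first_id + seq_len(ns - 1L) - 1L)
    push(parent, root_counter, ty, g$length_cm, axile_diam[i] / 2, g$creation)

    # lateral initiation sites on this axis
    spacing <- p$lateral_spacing
    x_max <- p$max_length - p$apical_unbranched_zone
    n_lat <- floor((x_max - p$basal_unbranched_zone) / spacing)
    if (n_lat >= 1L) {
      x <- p$basal_unbranched_zone + spacing * seq_len(n_lat)
      tip_pos <- x + p$apical_unbranched_zone
      ok <- tip_pos < p$max_length * (1 - 1e-9)
      x <- x[ok]; tip_pos <- tip_pos[ok]
      if (length(x)) {
        # parent-axis age at which the tip clears the insertion + apical zone
        a_x <- -(p$max_length / p$initial_elongation_rate) *
          log(1 - tip_pos / p$max_length)
        emerg <- axile_emerg[i] + a_x + lat$emergence_delay
        ok <- emerg < t_end
        x <- x[ok]; emerg <- emerg[ok]
        if (length(x)) {
          cum <- cumsum(g$length_cm)
          k <- findInterval(x * (1 - 1e-12), cum) + 1L
          k <- pmin(k, ns)
          lat_parent_seg <- c(lat_parent_seg, first_id - 1L + k)
          lat_emerg <- c(lat_emerg, emerg)
        }
      }
    }
  }

  if (length(lat_emerg)) {
    lat_diam <- drawDiameter(length(lat_emerg), lat$mean_diameter,
                             lat$diameter_cv)
    for (j in seq_along(lat_emerg)) {
      g <- axisSegments(lat_emerg[j], lat$max_length,
                        lat$initial_elongation_rate, dt, t_end, min_increment)
      if (is.null(g)) next
      ns <- length(g$length_cm)
      root_counter <- root_counter + 1L
      first_id <- n_seg_total + 1L
      parent <- c(lat_parent_seg[j], first_id + seq_len(ns - 1L) - 1L)
      push(parent, root_counter, "lateral", g$length_cm, lat_diam[j] / 2,
           g$creation)
    }
  }

  segments <- data.frame(
    segment_id = seq_len(n_seg_total),
    parent_id = unlist(acc$parent, use.names = FALSE),
    root_id = unlist(acc$root, use.names = FALSE),
    type = unlist(acc$type, use.names = FALSE),
    length_m = unlist(acc$len, use.names = FALSE) / 100,
    radius_m = unlist(acc$rad, use.names = FALSE) / 1000,
    creation_day = unlist(acc$creation, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  segments$depth <- segmentDepths(segments$parent_id)
  sys$segments <- segments
  sys
}

# Depth of each segment above the collar (collar children have depth 1).
# Parents always precede children in the table, so one forward pass suffices.
segmentDepths <- function(parent_id) {
  n <- length(parent_id)
  depth <- integer(n)
  for (i in seq_len(n)) {
    p <- parent_id[i]
    depth[i] <- if (p == 0L) 1L else depth[p] + 1L
  }
  depth
}

#' Construct a root system from a segment table
#'
#' Builds a `root_system` object from an explicit segment table, validating
#' the forest structure (unique ids, parents preceding children, positive
#' lengths and radii). Mainly useful for hand-built networks and file import.
#'
#' @param segments data.frame with columns `segment_id`, `parent_id` (0 or NA
#'   for collar attachment), `root_id`, `type`, `length_m`, `radius_m`,
#'   `creation_day`.
#' @param simulation_time Time stamp of the system, days.
#' @param dt Growth discretization the table was produced with (metadata).
#' @param seed Seed metadata.
#' @param cultivar Cultivar name metadata.
#' @return A `root_system` object.
#' @export
rootSystem <- function(segments, simulation_time = max(c(0, segments$creation_day)),
                       dt = NA_real_, seed = NA_integer_, cultivar = NA_character_) {
  req <- c("segment_id", "parent_id", "root_id", "type", "length_m",
           "radius_m", "creation_day")
  if (!all(req %in% names(segments)))
    stop("segment table must have columns: ", paste(req, collapse = ", "))
  segments$parent_id[is.na(segments$parent_id)] <- 0L
  if (anyDuplicated(segments$segment_id)) stop("segment ids must be unique")
  n <- nrow(segments)
  if (n > 0) {
    if (!identical(as.integer(segments$segment_id), seq_len(n)))
      stop("segment ids must be 1..n in table order")
    if (any(segments$parent_id >= segments$segment_id & segments$parent_id != 0L))
      stop("parents must precede children (parent_id < segment_id)")
    if (any(segments$length_m <= 0)) stop("segment lengths must be > 0")
    if (any(segments$radius_m <= 0)) stop("segment radii must be > 0")
    if (any(segments$creation_day < 0)) stop("creation days must be >= 0")
    par_creation <- c(0, segments$creation_day)[segments$parent_id + 1L]
    if (any(par_creation > segments$creation_day + 1e-9))
      stop("a parent segment cannot be younger than its child")
    if (!all(segments$type %in% c("seminal", "crown", "lateral")))
      stop("segment types must be seminal, crown or lateral")
    segments$depth <- segmentDepths(segments$parent_id)
  } else {
    segments$depth <- integer(0)
  }
  structure(list(segments = segments, simulation_time = simulation_time,
                 dt = dt, seed = seed, cultivar = cultivar),
            class = "root_system")
}

#' Snapshot of a simulated root system at an earlier time
#'
#' Restricts the segment tree to segments created at or before `t`. Because
#' segments time-stamp the growth increments, the snapshot at `t` is the root
#' system as it existed `t` days after sowing.
#'
#' @param system A `root_system`.
#' @param t Snapshot time, days (0 <= t <= simulation_time).
#' @return A `root_system` with `simulation_time = t`.
#' @export
rootSnapshot <- function(system, t) {
  stopifnot(inherits(system, "root_system"))
  if (t < 0) stop("snapshot time must be >= 0")
  seg <- system$segments
  keep <- which(seg$creation_day <= t + 1e-9)
  seg2 <- seg[keep, , drop = FALSE]
  if (nrow(seg2)) {
    # parents are never younger than children, so every parent is retained;
    # remap ids to the new row order
    newid <- integer(nrow(seg))
    newid[keep] <- seq_along(keep)
    p <- seg2$parent_id
    seg2$parent_id <- ifelse(p == 0L, 0L, newid[pmax(p, 1L)])
    seg2$segment_id <- seq_len(nrow(seg2))
    seg2$depth <- segmentDepths(seg2$parent_id)
    rownames(seg2) <- NULL
  }
  out <- system
  out$segments <- seg2
  out$simulation_time <- t
  out
}

#' Total root length of a root system
#'
#' @param system A `root_system`.
#' @return Total length in m (sum of segment lengths).
#' @export
totalLength <- function(system) {
  stopifnot(inherits(system, "root_system"))
  sum(system$segments$length_m)
}

#' Total root surface area of a root system
#'
#' @param system A `root_system`.
#' @return Surface area in m^2 (sum of 2 pi r l over segments).
#' @export
surfaceArea <- function(system) {
  stopifnot(inherits(system, "root_system"))
  sum(2 * pi * system$segments$radius_m * system$segments$length_m)
}

#' @export
print.root_system <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("root system%s at day %.1f: %d segments, %d roots\n",
              if (is.na(x$cultivar)) "" else paste0(" (", x$cultivar, ")"),
              x$simulation_time, nrow(seg), length(unique(seg$root_id))))
  if (nrow(seg)) {
    tl <- tapply(seg$length_m, seg$type, sum)
    cat(sprintf("  total length %.3f m (%s); surface area %.2f cm^2\n",
                totalLength(x),
                paste(sprintf("%s %.2f m", names(tl), tl), collapse = ", "),
                surfaceArea(x) * 1e4))
  }
  invisible(x)
}
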