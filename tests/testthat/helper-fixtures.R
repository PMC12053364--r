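# Shared fixtures: random segment trees, constant hydraulic parameter sets
# and small trait tables, all generated in code.

# Random valid segment forest. Parameter ranges keep tau * l per segment
# moderate so the discretized network oracle converges well.
randomSegmentTree <- function(n, seed, n_collar = 2L) {
  set.seed(seed)
  parent <- integer(n)
  type <- character(n)
  for (i in seq_len(n)) {
    if (i <= n_collar) {
      parent[i] <- 0L
      type[i] <- sample(c("seminal", "crown"), 1L)
    } else {
      parent[i] <- sample.int(i - 1L, 1L)
      type[i] <- sample(c("seminal", "crown", "lateral"), 1L)
    }
  }
  creation <- sort(stats::runif(n, 0, 20))
  data.frame(
    segment_id = seq_len(n),
    parent_id = parent,
    root_id = seq_len(n),  # topology is what matters; one root per segment is fine
    type = type,
    length_m = stats::runif(n, 0.005, 0.08),
    radius_m = stats::runif(n, 5e-5, 4e-4),
    creation_day = creation,
    stringsAsFactors = FALSE
  )
}

randomRootSystem <- function(n, seed, t = 25) {
  rootSystem(randomSegmentTree(n, seed), simulation_time = t)
}

# Age-constant hydraulics (single-knot piecewise functions).
constHydraulics <- function(kr_ax = 1e-7, kx_ax = 2e-12,
                            kr_lat = 2e-7, kx_lat = 4e-13) {
  hydraulicParams(
    kr = list(seminal = piecewiseLinear(0, kr_ax),
              crown = piecewiseLinear(0, kr_ax),
              lateral = piecewiseLinear(0, kr_lat)),
    kx = list(seminal = piecewiseLinear(0, kx_ax),
              crown = piecewiseLinear(0, kx_ax),
              lateral = piecewiseLinear(0, kx_lat)))
}

# Age-dependent hydraulics with distinct per-type dynamics.
agedHydraulics <- function() {
  hydraulicParams(
    kr = list(seminal = piecewiseLinear(c(0, 10, 30), c(2e-7, 8e-8, 3e-8)),
              crown = piecewiseLinear(c(0, 12), c(1.5e-7, 5e-8)),
              lateral = piecewiseLinear(c(0, 8, 25), c(3e-7, 1.2e-7, 6e-8))),
    kx = list(seminal = piecewiseLinear(c(0, 20), c(2e-12, 8e-12)),
              crown = piecewiseLinear(c(0, 20), c(4e-12, 1.5e-11)),
              lateral = piecewiseLinear(0, 4e-13)))
}

# A single unbranched axis as a root_system.
chainSystem <- function(lengths, radius = 3e-4, type = "seminal",
                        creation = rep(0, length(lengths))) {
  n <- length(lengths)
  rootSystem(data.frame(
    segment_id = seq_len(n),
    parent_id = c(0L, seq_len(n - 1L)),
    root_id = 1L, type = type,
    length_m = lengths, radius_m = radius, creation_day = creation,
    stringsAsFactors = FALSE), simulation_time = max(creation))
}

# Tidy long trait table from a wide per-plant data.frame.
longTraits <- function(df, traits) {
  out <- do.call(rbind, lapply(traits, function(tr)
    data.frame(plant_id = df$plant_id, cultivar = df$cultivar,
               release_year = df$release_year, season = df$season,
               trait = tr, value = df[[tr]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
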