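#' Discretized resistor-network conductance (verification oracle)
#'
#' Independent brute-force check of [computeKrs()]: each segment is split into
#' `nodes_per_segment` sub-edges; consecutive xylem nodes are connected by
#' axial resistors (conductance kx / dl) and each node is connected to a
#' uniform external medium by a radial resistor (conductance kr 2 pi r dl,
#' split half to each end node of the sub-edge). The sparse linear system for
#' the node potentials under a unit medium-collar potential difference is
#' solved with the Matrix package and the collar influx — numerically equal to
#' the conductance — is returned. As `nodes_per_segment` grows the discrete
#' ladder converges (second order) to the continuous transmission-line
#' solution.
#'
#' @param system A `root_system`.
#' @param hydraulics A [hydraulicParams()] object.
#' @param t Evaluation time, days.
#' @param nodes_per_segment Sub-edges per segment (>= 2).
#' @return Conductance in m^3 MPa^-1 s^-1.
#' @export
networkOracle <- function(system, hydraulics, t = system$simulation_time,
                          nodes_per_segment = 100L) {
  stopifnot(inherits(system, "root_system"),
            inherits(hydraulics, "hydraulic_params"))
  m <- as.integer(nodes_per_segment)
  if (m < 2L) stop("nodes_per_segment must be >= 2")
  seg <- segmentsAt(system, t)
  n <- nrow(seg)
  if (n == 0L) return(0)
  pr <- segmentProperties(seg, hydraulics, t)

  dl <- seg$length_m / m
  g_ax <- pr$kx / dl                       # per sub-edge axial conductance
  g_rad <- pr$kr * 2 * pi * seg$radius_m * dl  # per sub-edge radial conductance

  node_id <- function(j, i) (j - 1L) * m + i   # sub-node i of segment j
  base_node <- ifelse(seg$parent_id == 0L, 0L, node_id(seg$parent_id, m))

  # axial edges: (base, 1), (1,2), ..., (m-1, m) for every segment
  from <- c(base_node, as.vector(outer(seq_len(m - 1L), (seq_len(n) - 1L) * m, `+`)))
  to <- c(node_id(seq_len(n), 1L),
          as.vector(outer(seq_len(m - 1L) + 1L, (seq_len(n) - 1L) * m, `+`)))
  g_edge <- c(g_ax, rep(g_ax, each = m - 1L))

  # radial lumping: interior node i of segment j gets a full sub-edge
  # conductance, the distal node half, the base node half (possibly collar)
  N <- n * m
  rad <- numeric(N)
  interior <- as.vector(outer(seq_len(m - 1L), (seq_len(n) - 1L) * m, `+`))
  rad[interior] <- rad[interior] + rep(g_rad, each = m - 1L)
  # half lumps: sub-edge 1 to base, sub-edge m to distal node
  distal <- node_id(seq_len(n), m)
  rad[distal] <- rad[distal] + g_rad / 2
  rad_collar <- 0
  at_base <- base_node
  sel <- at_base > 0L
  if (any(sel)) {
    agg <- rowsum(g_rad[sel] / 2, at_base[sel])
    tgt <- as.integer(rownames(agg))
    rad[tgt] <- rad[tgt] + agg[, 1L]
  }
  rad_collar <- sum(g_rad[!sel] / 2)
  # interior lump double counts sub-edge 1 for node 1 and sub-edge m for
  # node m-1? No: interior covers nodes 1..m-1, each getting the mean of its
  # two flanking half sub-edges, i.e. one full sub-edge conductance — the
  # total lumped per segment is m * g_rad as required:
  #   base m/2? -> base 1/2 + (m-1) interior + distal 1/2 = m halves * 2 = m. OK.

  # assemble Laplacian over unknown nodes (collar is grounded at 0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  a <- from; b <- to
  ua <- a > 0L
  ii <- c(ii, a[ua], b, a[ua & b > 0L], b[ua & b > 0L])
  jj <- c(jj, a[ua], b, b[ua & b > 0L], a[ua & b > 0L])
  xx <- c(xx, g_edge[ua], g_edge, -g_edge[ua & b > 0L], -g_edge[ua & b > 0L])
  ii <- c(ii, seq_len(N)); jj <- c(jj, seq_len(N)); xx <- c(xx, rad)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  rhs <- rad * 1  # medium potential = 1
  x <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) stop("resistor network is singular ",
                                         "(all kr zero with closed tips?): ",
                                         conditionMessage(e)))

  # collar influx: axial edges from collar plus the collar radial lump
  collar_children <- which(seg$parent_id == 0L)
  flux <- sum(g_ax[collar_children] * x[node_id(collar_children, 1L)]) +
    rad_collar * 1
  flux
}
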