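#' Write a root system segment table to CSV
#'
#' Edge-list schema: `segment_id,parent_id,root_id,type,length_m,radius_m,
#' creation_day` (UTF-8, comma separated, '.' decimal, header mandatory).
#' Write-read-write round trips are byte identical.
#'
#' @param system A `root_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSegmentsCSV <- function(system, path) {
  stopifnot(inherits(system, "root_system"))
  seg <- system$segments
  out <- data.frame(segment_id = seg$segment_id,
                    parent_id = seg$parent_id,
                    root_id = seg$root_id,
                    type = seg$type,
                    length_m = sprintf("%.12g", seg$length_m),
                    radius_m = sprintf("%.12g", seg$radius_m),
                    creation_day = sprintf("%.12g", seg$creation_day),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a root system segment table from CSV
#'
#' @param path CSV written by [writeSegmentsCSV()] (or following the same
#'   schema).
#' @return A `root_system`.
#' @export
readSegmentsCSV <- function(path) {
  seg <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse segment CSV '", path,
                                           "': ", conditionMessage(e)))
  req <- c("segment_id", "parent_id", "root_id", "type", "length_m",
           "radius_m", "creation_day")
  missing <- setdiff(req, names(seg))
  if (length(missing))
    stop("segment CSV '", path, "' lacks columns: ",
         paste(missing, collapse = ", "))
  rootSystem(seg)
}

# Fabricated straight-line 3D directions: the hydraulic model is purely
# topological, so export geometry only needs to be consistent and collision
# free. Axile roots descend at a type-dependent angle fanned by the golden
# angle; laterals leave their parent nearly horizontally.
fabricateDirections <- function(root_index, type) {
  golden <- pi * (3 - sqrt(5))
  phi <- root_index * golden
  theta <- ifelse(type == "lateral", 75, ifelse(type == "crown", 35, 20)) * pi / 180
  cbind(cos(phi) * sin(theta), sin(phi) * sin(theta), -cos(theta))
}

#' Export root system snapshots to RSML
#'
#' Writes one RSML scene for the given snapshot of a simulated root system.
#' Each root axis becomes a `<root>` element (laterals nested inside their
#' parent axis) with a straight-line fabricated polyline, the root type as a
#' standard property, and per-point `diameter` and `creation_day` functions.
#' Point i of a polyline is the proximal end of the axis' i-th segment
#' (0-based in the file), so segment k spans points k-1 to k; the first
#' function sample is repeated so that samples align with points.
#'
#' @param system A `root_system`.
#' @param path Output file path.
#' @param time Snapshot time, days; defaults to the full system.
#' @return `path`, invisibly.
#' @export
writeRSML <- function(system, path, time = system$simulation_time) {
  stopifnot(inherits(system, "root_system"))
  snap <- rootSnapshot(system, time)
  seg <- snap$segments
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "m")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "rootkrs")
  if (!is.na(system$seed)) xml2::xml_add_child(meta, "seed", as.character(system$seed))
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1",
                               label = if (is.na(system$cultivar)) "plant"
                               else system$cultivar)
  if (nrow(seg)) {
    roots <- split(seq_len(nrow(seg)), seg$root_id)
    # per-root bookkeeping for coordinates and nesting
    base_parent_seg <- vapply(roots, function(ix) seg$parent_id[ix[1L]], 0L)
    seg_root <- seg$root_id
    points <- vector("list", length(roots))
    names(points) <- names(roots)
    root_node <- vector("list", length(roots))
    names(root_node) <- names(roots)
    # segment -> (root, ordinal within root)
    ord_in_root <- integer(nrow(seg))
    for (rid in names(roots)) ord_in_root[roots[[rid]]] <- seq_along(roots[[rid]])

    emit <- function(rid, parent_xml, base_xyz) {
      ix <- roots[[rid]]
      ty <- seg$type[ix[1L]]
      dirs <- fabricateDirections(as.integer(rid), ty)
      cum <- c(0, cumsum(seg$length_m[ix]))
      xyz <- cbind(base_xyz[1] + dirs[1] * cum,
                   base_xyz[2] + dirs[2] * cum,
                   base_xyz[3] + dirs[3] * cum)
      points[[rid]] <<- xyz
      node <- xml2::xml_add_child(parent_xml, "root", ID = rid,
                                  label = paste0(ty, "_", rid))
      props <- xml2::xml_add_child(node, "properties")
      xml2::xml_add_child(props, "property", name = "type", value = ty)
      geom <- xml2::xml_add_child(node, "geometry")
      poly <- xml2::xml_add_child(geom, "polyline")
      for (k in seq_len(nrow(xyz)))
        xml2::xml_add_child(poly, "point",
                            x = sprintf("%.12g", xyz[k, 1]),
                            y = sprintf("%.12g", xyz[k, 2]),
                            z = sprintf("%.12g", xyz[k, 3]))
      fns <- xml2::xml_add_child(node, "functions")
      addFun <- function(name, v) {
        fn <- xml2::xml_add_child(fns, "function", name = name,
                                  domain = "polyline")
        for (val in c(v[1L], v))
          xml2::xml_add_child(fn, "sample", value = sprintf("%.12g", val))
      }
      addFun("diameter", 2 * seg$radius_m[ix])
      addFun("creation_day", seg$creation_day[ix])
      root_node[[rid]] <<- node
      # children axes whose base parent segment lies on this root
      kids <- names(roots)[base_parent_seg != 0L &
                             seg_root[pmax(base_parent_seg, 1L)] == as.integer(rid)]
      for (kid in kids) {
        pseg <- base_parent_seg[[kid]]
        attach_xyz <- xyz[ord_in_root[pseg] + 1L, ]  # distal end of pseg
        emit(kid, node, attach_xyz)
      }
    }
    top <- names(roots)[base_parent_seg == 0L]
    for (rid in top) emit(rid, plant, c(0, 0, 0))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a root system from RSML
#'
#' Reads an RSML file written by [writeRSML()] (or following the same
#' conventions: per-point `diameter` and `creation_day` function samples with
#' the first sample repeated). Segment lengths are recovered from polyline
#' point distances; lateral attachment is recovered by matching the lateral
#' base point to its parent polyline.
#'
#' @param path RSML file path.
#' @return A `root_system`.
#' @export
readRSML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse RSML '", path, "': ",
                                           conditionMessage(e)))
  plant <- xml2::xml_find_first(doc, ".//plant")
  if (inherits(plant, "xml_missing")) stop("RSML '", path, "' has no <plant>")

  seg_rows <- list()
  root_counter <- 0L
  # returns global ids of the segments of this root (in order)
  readRoot <- function(node, parent_poly, parent_seg_ids) {
    poly_pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    xyz <- cbind(as.numeric(xml2::xml_attr(poly_pts, "x")),
                 as.numeric(xml2::xml_attr(poly_pts, "y")),
                 as.numeric(xml2::xml_attr(poly_pts, "z")))
    if (nrow(xyz) < 2L) stop("RSML root ", xml2::xml_attr(node, "ID"),
                             ": polyline needs >= 2 points")
    ty <- xml2::xml_attr(xml2::xml_find_first(
      node, "./properties/property[@name='type']"), "value")
    if (is.na(ty)) ty <- "lateral"
    getFun <- function(name) {
      v <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
        node, sprintf("./functions/function[@name='%s']/sample", name)),
        "value"))
      if (length(v) != nrow(xyz))
        stop("RSML root ", xml2::xml_attr(node, "ID"), ": function '", name,
             "' has ", length(v), " samples for ", nrow(xyz), " points")
      v[-1L]  # drop the repeated base-point sample; one value per segment
    }
    diam <- getFun("diameter")
    created <- getFun("creation_day")
    lens <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                            xyz[-nrow(xyz), , drop = FALSE])^2))
    n <- length(lens)
    # parent segment of the first segment
    if (is.null(parent_poly)) {
      p0 <- 0L
    } else {
      d <- sqrt(rowSums(sweep(parent_poly, 2L, xyz[1L, ])^2))
      j <- which.min(d)
      if (d[j] > 1e-9)
        stop("RSML root ", xml2::xml_attr(node, "ID"),
             ": base point does not lie on the parent polyline")
      if (j < 2L) stop("lateral attaches at the parent base point")
      p0 <- parent_seg_ids[j - 1L]
    }
    first_id <- length(seg_rows)
    ids <- first_id + seq_len(n)
    root_counter <<- root_counter + 1L
    rid <- root_counter
    for (k in seq_len(n)) {
      seg_rows[[length(seg_rows) + 1L]] <<- list(
        segment_id = ids[k],
        parent_id = if (k == 1L) p0 else ids[k - 1L],
        root_id = rid, type = ty, length_m = lens[k],
        radius_m = diam[k] / 2, creation_day = created[k])
    }
    kids <- xml2::xml_find_all(node, "./root")
    for (kid in kids) readRoot(kid, xyz, ids)
    ids
  }
  for (node in xml2::xml_find_all(plant, "./root"))
    readRoot(node, NULL, integer(0))
  if (length(seg_rows) == 0L)
    return(rootSystem(data.frame(segment_id = integer(), parent_id = integer(),
                                 root_id = integer(), type = character(),
                                 length_m = numeric(), radius_m = numeric(),
                                 creation_day = numeric())))
  seg <- do.call(rbind, lapply(seg_rows, as.data.frame))
  rootSystem(seg)
}

#' Write hydraulic parameters to a YAML file
#'
#' Per-type knot lists: `kr` and `kx` blocks, each with `seminal`, `crown`,
#' `lateral` entries holding `age` (days) and `value` vectors.
#'
#' @param hydraulics A [hydraulicParams()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeHydraulicsFile <- function(hydraulics, path) {
  stopifnot(inherits(hydraulics, "hydraulic_params"))
  to_list <- function(f) list(age = f$age, value = f$value)
  obj <- list(kr = lapply(hydraulics$kr, to_list),
              kx = lapply(hydraulics$kx, to_list))
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' Read hydraulic parameters from a YAML file
#'
#' @param path File written by [writeHydraulicsFile()].
#' @return A [hydraulicParams()] object.
#' @export
readHydraulicsFile <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse hydraulics file '",
                                           path, "': ", conditionMessage(e)))
  from_list <- function(x) piecewiseLinear(x$age, x$value)
  hydraulicParams(kr = lapply(obj$kr, from_list),
                  kx = lapply(obj$kx, from_list))
}

#' Write cultivar architecture parameters to a YAML file
#'
#' One block per root type plus the cultivar-level axis dynamics, mirroring
#' the structured parameter-file convention of whole-plant root models.
#'
#' @param params A [cultivarParams()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCultivarFile <- function(params, path) {
  stopifnot(inherits(params, "cultivar_params"))
  obj <- unclass(params)
  obj$root_type_params <- lapply(params$root_type_params, unclass)
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' Read cultivar architecture parameters from a YAML file
#'
#' @param path File written by [writeCultivarFile()].
#' @return A [cultivarParams()] object.
#' @export
readCultivarFile <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse cultivar file '",
                                           path, "': ", conditionMessage(e)))
  tp <- lapply(obj$root_type_params, function(x)
    rootTypeParams(x$type_label, x$mean_diameter, x$diameter_cv, x$max_length,
                   x$initial_elongation_rate, x$apical_unbranched_zone,
                   x$basal_unbranched_zone,
                   if (is.null(x$lateral_spacing)) NA_real_ else x$lateral_spacing,
                   x$emergence_delay))
  cultivarParams(obj$name, obj$release_year,
                 obj$seminal_count_mean, obj$seminal_count_sd,
                 obj$tiller_final_count_mean, obj$tiller_final_count_sd,
                 obj$phyllochron, obj$crown_roots_per_tiller, tp)
}

#' Write a tidy trait table to CSV
#' @param traits Tidy long trait data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeTraitsCSV <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trait table from CSV
#' @param path CSV with columns `plant_id`, `cultivar`, `release_year`,
#'   `season`, `trait`, `value`.
#' @return data.frame.
#' @export
readTraitsCSV <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("cannot parse trait CSV '", path,
                                         "': ", conditionMessage(e)))
  req <- c("plant_id", "cultivar", "release_year", "season", "trait", "value")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("trait CSV '", path, "' lacks columns: ",
         paste(missing, collapse = ", "))
  d
}

#' Write pressure-chamber sweeps to long-format CSV files
#'
#' Writes the readings CSV (`plant_id,cultivar,release_year,pressure_MPa,
#' flow_m3_s`) and the geometry CSV (`plant_id,area_m2,length_m`).
#'
#' @param sweeps List of [pressureSweep()] objects.
#' @param readings_path,geometry_path Output file paths.
#' @return Invisibly, c(readings_path, geometry_path).
#' @export
writeSweepsCSV <- function(sweeps, readings_path, geometry_path) {
  rd <- do.call(rbind, lapply(sweeps, function(s)
    data.frame(plant_id = s$plant_id, cultivar = s$cultivar,
               release_year = s$release_year, pressure_MPa = s$pressure_MPa,
               flow_m3_s = sprintf("%.12g", s$flow_m3_s),
               stringsAsFactors = FALSE)))
  gm <- do.call(rbind, lapply(sweeps, function(s)
    data.frame(plant_id = s$plant_id,
               area_m2 = sprintf("%.12g", s$root_surface_area_m2),
               length_m = sprintf("%.12g", s$total_root_length_m),
               stringsAsFactors = FALSE)))
  utils::write.csv(rd, readings_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(gm, geometry_path, row.names = FALSE, quote = FALSE)
  invisible(c(readings_path, geometry_path))
}

#' Read pressure-chamber sweeps from long-format CSV files
#'
#' @param readings_path,geometry_path Files written by [writeSweepsCSV()]
#'   (or following the same schemas).
#' @return List of [pressureSweep()] objects.
#' @export
readSweepsCSV <- function(readings_path, geometry_path) {
  rd <- utils::read.csv(readings_path, stringsAsFactors = FALSE)
  gm <- utils::read.csv(geometry_path, stringsAsFactors = FALSE)
  req <- c("plant_id", "cultivar", "release_year", "pressure_MPa", "flow_m3_s")
  if (!all(req %in% names(rd)))
    stop("readings CSV lacks columns: ",
         paste(setdiff(req, names(rd)), collapse = ", "))
  if (!all(c("plant_id", "area_m2", "length_m") %in% names(gm)))
    stop("geometry CSV lacks columns plant_id, area_m2, length_m")
  lapply(unique(rd$plant_id), function(pid) {
    r <- rd[rd$plant_id == pid, , drop = FALSE]
    g <- gm[gm$plant_id == pid, , drop = FALSE]
    if (nrow(g) != 1L) stop("geometry missing or duplicated for plant '", pid, "'")
    pressureSweep(pid, r$cultivar[1L], r$release_year[1L],
                  r$pressure_MPa, r$flow_m3_s, g$area_m2, g$length_m)
  })
}
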