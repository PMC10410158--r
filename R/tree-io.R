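#' Export a vascular tree to JSON or VTK polyline
#'
#' The JSON schema is
#' `{segments: [{label, generation, radius_m, length_m, parent, children,
#' outlet}], root, outlet_order, murray_exponent, total_path_length_m}` and
#' round-trips losslessly through [read_tree()]. The VTK format is a legacy
#' ASCII polyline centerline in the planar layout (one point per node, one
#' line cell per segment) with a point-data array `radius_m`, suitable for
#' ParaView inspection.
#'
#' @param tree A `vascular_tree`.
#' @param path Output file path.
#' @param format `"json"` (round-trippable) or `"vtk-polyline"`.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path, format = c("json", "vtk-polyline")) {
  stopifnot(inherits(tree, "vascular_tree"))
  format <- match.arg(format)
  if (format == "json") export_tree_json(tree, path) else export_tree_vtk(tree, path)
  invisible(path)
}

export_tree_json <- function(tree, path) {
  seg <- tree$segments
  recs <- lapply(seq_len(nrow(seg)), function(i) {
    kids <- tree_children(tree, seg$label[i])
    list(label = seg$label[i],
         generation = seg$generation[i],
         radius_m = seg$radius[i],
         length_m = seg$length[i],
         parent = if (is.na(seg$parent[i])) NULL else seg$parent[i],
         children = as.list(kids),
         outlet = if (is.na(seg$outlet[i])) NULL else seg$outlet[i])
  })
  obj <- list(segments = recs,
              root = tree$root,
              outlet_order = as.list(tree$outlet_order),
              murray_exponent = tree$config$murray_exponent,
              total_path_length_m = tree$config$total_path_length,
              inlet_diameter_m = tree$config$inlet_diameter,
              outlet_diameter_m = tree$config$outlet_diameter,
              n_generations = tree$config$n_generations,
              length_fractions = as.list(tree$config$length_fractions),
              bifurcation_half_angle_deg = tree$config$bifurcation_half_angle)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a vascular tree from its JSON export
#'
#' @param path Path to a file written by [export_tree()] with `format = "json"`.
#' @return A `vascular_tree` equal to the exported one.
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  cfg <- geometry_config(
    inlet_diameter = obj$inlet_diameter_m,
    outlet_diameter = obj$outlet_diameter_m,
    n_generations = obj$n_generations,
    total_path_length = obj$total_path_length_m,
    murray_exponent = obj$murray_exponent,
    bifurcation_half_angle = obj$bifurcation_half_angle_deg,
    length_fractions = unlist(obj$length_fractions))
  chr_or_na <- function(x) if (length(x)) as.character(x) else NA_character_
  seg <- do.call(rbind, lapply(obj$segments, function(s) {
    data.frame(label = s$label, generation = as.integer(s$generation),
               radius = s$radius_m, length = s$length_m,
               parent = chr_or_na(s$parent), outlet = chr_or_na(s$outlet),
               stringsAsFactors = FALSE)
  }))
  rownames(seg) <- seg$label
  structure(list(segments = seg, root = obj$root,
                 outlet_order = unlist(obj$outlet_order), config = cfg),
            class = "vascular_tree")
}

export_tree_vtk <- function(tree, path) {
  seg <- tree$segments
  xy <- tree_layout(tree)
  n_pts <- nrow(xy)
  idx <- stats::setNames(seq_len(n_pts) - 1L, rownames(xy))  # 0-based
  # per-point radius: a node carries the radius of the segment it terminates;
  # the inlet node carries the root radius
  rad <- c(seg[tree$root, "radius"], seg$radius)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vascular tree centerline", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n_pts)), con)
  writeLines(sprintf("%.9e %.9e 0.0", xy[, 1], xy[, 2]), con)
  n_cells <- nrow(seg)
  writeLines(sprintf("LINES %d %d", n_cells, 3L * n_cells), con)
  up <- ifelse(is.na(seg$parent), "INLET", seg$parent)
  writeLines(sprintf("2 %d %d", idx[up], idx[seg$label]), con)
  writeLines(c(sprintf("POINT_DATA %d", n_pts),
               "SCALARS radius_m double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9e", rad), con)
}
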