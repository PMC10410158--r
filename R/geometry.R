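#' Geometry configuration for an idealized bifurcating microvascular tree
#'
#' Collects the three primary geometric parameters of the idealized coronary
#' microvascular model: per-generation vessel lengths, vessel radii under a
#' generalized Murray taper, and the (layout-only) bifurcation angle. Defaults
#' reproduce the reference device: a 1 mm diameter inlet channel feeding
#' 8 outlets of 0.4 mm diameter through 3 sequential bifurcations, with a
#' total in-to-out path length of 1 cm.
#'
#' @param inlet_diameter Inlet channel diameter in metres.
#' @param outlet_diameter Terminal channel diameter in metres; must be smaller
#'   than `inlet_diameter`.
#' @param n_generations Number of bifurcation levels (3 gives \eqn{2^3 = 8}
#'   outlets and 4 channel generations).
#' @param total_path_length Root-to-outlet path length in metres (every path is
#'   equal in the symmetric tree).
#' @param murray_exponent Taper exponent m in \eqn{r_p^m = \sum r_c^m}.
#'   The default `"auto"` infers m so that repeated equal-split bifurcation maps
#'   `inlet_diameter` onto `outlet_diameter` exactly (about 2.2694 for the
#'   defaults); pass `3` for the classical Murray law, under which the terminal
#'   diameter becomes nominal (0.5 mm for the default inlet).
#' @param bifurcation_half_angle Half opening angle at each bifurcation in
#'   degrees. Layout/export only; a lumped-resistance model is angle-independent.
#' @param length_fractions Fractions of `total_path_length` assigned to each
#'   channel generation (length `n_generations + 1`, summing to 1). Default:
#'   equal fractions.
#' @return An object of class `geometry_config`.
#' @seealso [build_tree()], [infer_murray_exponent()]
#' @export
#' @examples
#' cfg <- geometry_config()
#' cfg$murray_exponent           # inferred, about 2.2694
#' geometry_config(murray_exponent = 3)$murray_exponent
geometry_config <- function(inlet_diameter = 1.0e-3,
                            outlet_diameter = 0.4e-3,
                            n_generations = 3L,
                            total_path_length = 1.0e-2,
                            murray_exponent = "auto",
                            bifurcation_half_angle = 30,
                            length_fractions = NULL) {
  stopifnot(is.numeric(inlet_diameter), inlet_diameter > 0,
            is.numeric(outlet_diameter), outlet_diameter > 0,
            is.numeric(total_path_length), total_path_length > 0)
  n_generations <- as.integer(n_generations)
  if (n_generations < 1L)
    stop("`n_generations` must be >= 1", call. = FALSE)
  if (outlet_diameter >= inlet_diameter)
    stop("`outlet_diameter` must be smaller than `inlet_diameter`", call. = FALSE)

  n_levels <- n_generations + 1L  # channel generations C1 .. C_{n+1}
  if (is.null(length_fractions))
    length_fractions <- rep(1 / n_levels, n_levels)
  if (length(length_fractions) != n_levels)
    stop("`length_fractions` must have one entry per channel generation (",
         n_levels, ")", call. = FALSE)
  if (any(length_fractions <= 0))
    stop("`length_fractions` must be strictly positive", call. = FALSE)
  if (abs(sum(length_fractions) - 1) > 1e-12)
    stop("`length_fractions` must sum to 1 (within 1e-12)", call. = FALSE)

  if (identical(murray_exponent, "auto")) {
    murray_exponent <- infer_murray_exponent(inlet_diameter, outlet_diameter,
                                             n_generations)
  } else {
    stopifnot(is.numeric(murray_exponent))
    if (murray_exponent <= 0)
      stop("`murray_exponent` must be > 0", call. = FALSE)
  }

  structure(
    list(inlet_diameter = inlet_diameter,
         outlet_diameter = outlet_diameter,
         n_generations = n_generations,
         total_path_length = total_path_length,
         murray_exponent = murray_exponent,
         bifurcation_half_angle = bifurcation_half_angle,
         length_fractions = length_fractions),
    class = "geometry_config")
}

#' Child radius under a generalized Murray bifurcation
#'
#' Solves \eqn{n \, r_c^m = r_p^m} for the common child radius at a symmetric
#' n-way bifurcation, i.e. \eqn{r_c = r_p \, n^{-1/m}}. With `exponent = 3`
#' this is the classical Murray law, under which fully developed laminar wall
#' shear stress is conserved across generations when flow splits equally.
#'
#' @param parent_radius Parent vessel radius (m), > 0.
#' @param n_children Number of equal children, >= 1.
#' @param exponent Taper exponent m > 0.
#' @return Child radius in metres.
#' @export
#' @examples
#' murray_child_radius(0.5e-3, 2, 3)        # 0.5 mm parent -> 0.3969 mm children
murray_child_radius <- function(parent_radius, n_children = 2L, exponent = 3) {
  if (!is.numeric(parent_radius) || parent_radius <= 0)
    stop("`parent_radius` must be > 0", call. = FALSE)
  if (!is.numeric(n_children) || n_children < 1)
    stop("`n_children` must be >= 1", call. = FALSE)
  if (!is.numeric(exponent) || exponent <= 0)
    stop("`exponent` must be > 0", call. = FALSE)
  parent_radius * n_children^(-1 / exponent)
}

#' Infer the Murray taper exponent from endpoint diameters
#'
#' Returns the exponent m under which `n_generations` successive symmetric
#' bifurcations map `inlet_diameter` onto `outlet_diameter`:
#' \eqn{m = n \ln 2 / \ln(d_{in}/d_{out})}. The printed device dimensions
#' (1 mm inlet, 0.4 mm outlets, 3 generations) are not consistent with a
#' strict exponent-3 taper (which would give 0.5 mm); the inferred exponent
#' (about 2.2694) honours both endpoints.
#'
#' @param inlet_diameter,outlet_diameter Endpoint diameters (m), with
#'   `0 < outlet_diameter < inlet_diameter`.
#' @param n_generations Number of bifurcation levels, >= 1.
#' @return The dimensionless exponent m.
#' @export
#' @examples
#' infer_murray_exponent(1e-3, 0.4e-3, 3)   # 2.2694
#' infer_murray_exponent(1e-3, 0.5e-3, 3)   # exactly 3
infer_murray_exponent <- function(inlet_diameter, outlet_diameter, n_generations) {
  stopifnot(is.numeric(inlet_diameter), is.numeric(outlet_diameter))
  if (!(outlet_diameter > 0 && outlet_diameter < inlet_diameter))
    stop("need 0 < outlet_diameter < inlet_diameter", call. = FALSE)
  n_generations <- as.integer(n_generations)
  if (n_generations < 1L)
    stop("`n_generations` must be >= 1", call. = FALSE)
  n_generations * log(2) / log(inlet_diameter / outlet_diameter)
}

#' Build the idealized bifurcating vascular tree
#'
#' Constructs a rooted symmetric binary tree of cylindrical segments. The root
#' channel is labeled `"C1"`; each subsequent channel generation g holds
#' \eqn{2^{g-1}} branches labeled `"Cg-Bk"` left to right, and the terminal
#' branch `Bk` drains outlet `"Ok"`. Radii follow the configured Murray taper;
#' segment lengths divide `total_path_length` by the configured per-generation
#' fractions, so every root-to-outlet path has equal length.
#'
#' @param config A [geometry_config()].
#' @return An object of class `vascular_tree`: a list with
#'   \describe{
#'     \item{segments}{data.frame with columns `label`, `generation`, `radius`,
#'       `length`, `parent` (`NA` for the root), `outlet` (`NA` for interior
#'       segments).}
#'     \item{root}{root label, `"C1"`.}
#'     \item{outlet_order}{outlet ids `"O1"` ... in left-to-right order.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
#' @examples
#' tree <- build_tree(geometry_config())
#' nrow(tree$segments)   # 15 segments: 1 + 2 + 4 + 8
#' tree$outlet_order
build_tree <- function(config = geometry_config()) {
  stopifnot(inherits(config, "geometry_config"))
  n_levels <- config$n_generations + 1L
  m <- config$murray_exponent
  r0 <- config$inlet_diameter / 2

  label <- character(0); generation <- integer(0)
  radius <- numeric(0); len <- numeric(0)
  parent <- character(0); outlet <- character(0)

  for (g in seq_len(n_levels)) {
    nb <- 2L^(g - 1L)
    labs <- if (g == 1L) "C1" else paste0("C", g, "-B", seq_len(nb))
    r_g <- r0 * 2^(-(g - 1L) / m)
    l_g <- config$total_path_length * config$length_fractions[g]
    if (g == 1L) {
      par_g <- NA_character_
    } else if (g == 2L) {
      par_g <- rep("C1", 2L)
    } else {
      par_g <- paste0("C", g - 1L, "-B", rep(seq_len(nb %/% 2L), each = 2L))
    }
    out_g <- if (g == n_levels) paste0("O", seq_len(nb)) else rep(NA_character_, nb)
    label <- c(label, labs); generation <- c(generation, rep(g, nb))
    radius <- c(radius, rep(r_g, nb)); len <- c(len, rep(l_g, nb))
    parent <- c(parent, par_g); outlet <- c(outlet, out_g)
  }

  segments <- data.frame(label = label, generation = generation,
                         radius = radius, length = len,
                         parent = parent, outlet = outlet,
                         stringsAsFactors = FALSE)
  rownames(segments) <- segments$label
  structure(
    list(segments = segments, root = "C1",
         outlet_order = paste0("O", seq_len(2L^config$n_generations)),
         config = config),
    class = "vascular_tree")
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat("vascular_tree:", nrow(x$segments), "segments,",
      length(x$outlet_order), "outlets\n")
  cat("  inlet diameter ", format(2 * x$segments[x$root, "radius"]),
      " m, terminal diameter ",
      format(2 * x$segments[x$segments$label ==
        terminal_segments(x)[1], "radius"]), " m\n", sep = "")
  cat("  Murray exponent", format(x$config$murray_exponent),
      "| path length", format(x$config$total_path_length), "m\n")
  invisible(x)
}

#' Children of a segment
#' @param tree A `vascular_tree`.
#' @param label Segment label.
#' @return Character vector of child labels (empty for terminal segments).
#' @export
tree_children <- function(tree, label) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (!label %in% tree$segments$label)
    stop("unknown segment label: ", label, call. = FALSE)
  tree$segments$label[!is.na(tree$segments$parent) &
                        tree$segments$parent == label]
}

#' Terminal (outlet-bearing) segment labels, in outlet order
#' @param tree A `vascular_tree`.
#' @return Character vector of terminal segment labels ordered by outlet id.
#' @export
terminal_segments <- function(tree) {
  stopifnot(inherits(tree, "vascular_tree"))
  term <- tree$segments[!is.na(tree$segments$outlet), ]
  term$label[match(tree$outlet_order, term$outlet)]
}

#' Outlets reachable downstream of a segment
#'
#' @param tree A `vascular_tree`.
#' @param label Segment label (e.g. `"C2-B1"`).
#' @return Character vector of outlet ids drained by the segment, in outlet
#'   order. For the root this is every outlet; for a terminal segment its own.
#' @export
#' @examples
#' tree <- build_tree()
#' downstream_outlets(tree, "C2-B1")   # O1..O4
downstream_outlets <- function(tree, label) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (!label %in% tree$segments$label)
    stop("unknown segment label: ", label, call. = FALSE)
  seg <- tree$segments
  acc <- character(0); stack <- label
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    out <- seg[cur, "outlet"]
    if (!is.na(out)) acc <- c(acc, out)
    else stack <- c(stack, tree_children(tree, cur))
  }
  tree$outlet_order[tree$outlet_order %in% acc]
}

# Planar layout used for export: root at the origin, flow along +y, outlets
# spread left-to-right by a dyadic offset whose overall width is set by the
# bifurcation half-angle. One point per node of the binary tree.
tree_layout <- function(tree) {
  seg <- tree$segments
  half <- tree$config$bifurcation_half_angle * pi / 180
  width <- tree$config$total_path_length * tan(half)
  # node = distal end of each segment, plus the inlet node
  xy <- matrix(0, nrow = nrow(seg) + 1L, ncol = 2)
  rownames(xy) <- c("INLET", seg$label)
  node_of <- function(lab) if (is.na(lab)) "INLET" else lab
  for (i in seq_len(nrow(seg))) {
    lab <- seg$label[i]
    up <- node_of(seg$parent[i])
    dx <- 0
    if (!is.na(seg$parent[i])) {
      sibs <- tree_children(tree, seg$parent[i])
      side <- if (match(lab, sibs) == 1L) -1 else 1
      dx <- side * width / 2^(seg$generation[i] - 1L)
    }
    xy[lab, ] <- xy[up, ] + c(dx, seg$length[i])
  }
  xy
}
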