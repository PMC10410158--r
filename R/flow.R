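#' Fluid properties
#'
#' Defaults are nominal 20 degC water (the perfusion experiments use water in
#' place of blood): density 1000 kg/m3, dynamic viscosity 1e-3 Pa s.
#'
#' @param density Fluid density in kg/m3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1.0e-3) {
  stopifnot(is.numeric(density), density > 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Inlet/outlet boundary conditions
#'
#' The inlet can be prescribed either as a flat mean velocity over the root
#' cross-section (default 0.012 m/s, the CFD boundary condition) or as a
#' volumetric flowrate (default 3.25e-9 m3/s, i.e. the 195 uL/min pump rate).
#' The two printed values are independent constants and are not mutually
#' consistent; choose via `inlet_mode`. All open outlets share a single
#' reference pressure (default 0 Pa) — only pressure differences matter.
#'
#' @param inlet_mode `"velocity"` or `"flowrate"`.
#' @param inlet_velocity Mean inlet velocity (m/s), used when
#'   `inlet_mode = "velocity"`.
#' @param inlet_flowrate Inlet volumetric flow (m3/s), used when
#'   `inlet_mode = "flowrate"`.
#' @param outlet_pressure Common reference pressure at open outlets (Pa).
#' @return An object of class `flow_bc`.
#' @export
flow_bc <- function(inlet_mode = c("velocity", "flowrate"),
                    inlet_velocity = 0.012,
                    inlet_flowrate = 195e-9 / 60,
                    outlet_pressure = 0) {
  inlet_mode <- match.arg(inlet_mode)
  if (inlet_mode == "velocity" && !(is.numeric(inlet_velocity) && inlet_velocity > 0))
    stop("`inlet_velocity` must be > 0", call. = FALSE)
  if (inlet_mode == "flowrate" && !(is.numeric(inlet_flowrate) && inlet_flowrate > 0))
    stop("`inlet_flowrate` must be > 0", call. = FALSE)
  structure(list(inlet_mode = inlet_mode, inlet_velocity = inlet_velocity,
                 inlet_flowrate = inlet_flowrate,
                 outlet_pressure = outlet_pressure),
            class = "flow_bc")
}

#' Occlusion pattern
#'
#' The set of blocked terminal outlets defining a perfusion-impairment
#' scenario. Occlusion is modeled as an exact zero-flow constraint (the
#' experimental blocks are sealed syringes, i.e. effectively infinite outlet
#' resistance).
#'
#' @param occluded_outlets Character vector of outlet ids (possibly empty).
#' @return An object of class `occlusion_pattern`.
#' @export
occlusion_pattern <- function(occluded_outlets = character(0)) {
  occluded_outlets <- as.character(occluded_outlets)
  if (anyDuplicated(occluded_outlets))
    occluded_outlets <- unique(occluded_outlets)
  structure(list(occluded_outlets = occluded_outlets),
            class = "occlusion_pattern")
}

#' Hagen-Poiseuille hydraulic resistance of a cylindrical segment
#'
#' \eqn{R = 8 \mu L / (\pi r^4)}, valid for fully developed steady laminar
#' Newtonian flow — the regime of the device (Reynolds numbers far below
#' transition).
#'
#' @param segment A one-row segment record with `radius` and `length` (m), or
#'   a list with those fields.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa s/m3.
#' @export
#' @examples
#' seg <- list(radius = 0.5e-3, length = 2.5e-3)
#' segment_resistance(seg, fluid_properties())   # about 1.02e8 Pa s/m3
segment_resistance <- function(segment, fluid = fluid_properties()) {
  r <- segment$radius; L <- segment$length
  if (!is.numeric(r) || any(r <= 0)) stop("radius must be > 0", call. = FALSE)
  if (!is.numeric(L) || any(L <= 0)) stop("length must be > 0", call. = FALSE)
  8 * fluid$viscosity * L / (pi * r^4)
}

#' Reynolds number of a segment at a given flow
#'
#' \eqn{Re = \rho \bar V d / \mu} with \eqn{\bar V = Q / (\pi r^2)} and
#' \eqn{d = 2r}. For the default geometry and a 0.012 m/s mean inlet velocity
#' in water this gives Re = 12 at the root — small enough that the laminar,
#' steady treatment is well justified.
#'
#' @param segment Segment record with a `radius` field (m).
#' @param flow Volumetric flow through the segment (m3/s), >= 0.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(segment, flow, fluid = fluid_properties()) {
  r <- segment$radius
  if (!is.numeric(r) || any(r <= 0)) stop("radius must be > 0", call. = FALSE)
  if (!is.numeric(flow) || any(flow < 0)) stop("flow must be >= 0", call. = FALSE)
  v <- flow / (pi * r^2)
  fluid$density * v * (2 * r) / fluid$viscosity
}

inlet_flow_from_bc <- function(tree, bc) {
  if (bc$inlet_mode == "velocity") {
    r0 <- tree$segments[tree$root, "radius"]
    bc$inlet_velocity * pi * r0^2
  } else {
    bc$inlet_flowrate
  }
}

#' Solve steady laminar flow on the tree as a resistance network
#'
#' Assembles the nodal conductance (Laplacian) system for the tree with
#' Hagen-Poiseuille segment resistances: mass conservation at every interior
#' node, \eqn{\Delta P = R Q} on every segment, prescribed inlet flow (from
#' velocity times root area when `inlet_mode = "velocity"`), a common
#' reference pressure at all open outlets, and exact zero flow through
#' occluded terminal segments (which are removed from the conductance graph;
#' their dangling outlet nodes take the stagnant upstream pressure). The
#' system is symmetric positive definite and solved exactly.
#'
#' @param tree A `vascular_tree`.
#' @param fluid A [fluid_properties()].
#' @param bc A [flow_bc()].
#' @param occlusion An [occlusion_pattern()].
#' @return An object of class `flow_solution`: list with
#'   \describe{
#'     \item{segment}{data.frame `label`, `flow` (m3/s), `fraction`
#'       (flow / inlet flow), `reynolds`.}
#'     \item{node_pressure}{named vector of nodal pressures (Pa); names are
#'       `"INLET"` plus the label of the segment whose distal end the node is.}
#'     \item{inlet_flow}{inlet volumetric flow (m3/s).}
#'     \item{mode}{`"resistance"`.}
#'   }
#' @export
#' @examples
#' sol <- solve_network(build_tree())
#' outlet_fractions(sol, build_tree())   # 0.125 at each of the 8 outlets
solve_network <- function(tree, fluid = fluid_properties(), bc = flow_bc(),
                          occlusion = occlusion_pattern()) {
  stopifnot(inherits(tree, "vascular_tree"))
  seg <- tree$segments
  bad <- setdiff(occlusion$occluded_outlets, tree$outlet_order)
  if (length(bad))
    stop("occluded outlets not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  open_out <- setdiff(tree$outlet_order, occlusion$occluded_outlets)
  if (!length(open_out))
    stop("infeasible boundary conditions: all outlets occluded", call. = FALSE)

  q_in <- inlet_flow_from_bc(tree, bc)
  occluded_seg <- seg$label[!is.na(seg$outlet) &
                              seg$outlet %in% occlusion$occluded_outlets]
  active <- setdiff(seg$label, occluded_seg)

  # nodes: INLET plus distal end of each segment; distal node shares the
  # segment's label. Open-outlet nodes are Dirichlet (reference pressure).
  nodes <- c("INLET", seg$label)
  dirichlet <- seg$label[!is.na(seg$outlet) & seg$outlet %in% open_out]
  unknown <- setdiff(c("INLET", active), dirichlet)

  g <- 1 / segment_resistance(seg[active, ], fluid)
  names(g) <- active
  up <- ifelse(is.na(seg[active, "parent"]), "INLET", seg[active, "parent"])
  names(up) <- active

  n <- length(unknown)
  A <- matrix(0, n, n, dimnames = list(unknown, unknown))
  b <- stats::setNames(rep(0, n), unknown)
  b["INLET"] <- q_in
  p0 <- bc$outlet_pressure
  for (lab in active) {
    i <- up[[lab]]; j <- lab; gij <- g[[lab]]
    iu <- i %in% unknown; ju <- j %in% unknown
    if (iu) A[i, i] <- A[i, i] + gij
    if (ju) A[j, j] <- A[j, j] + gij
    if (iu && ju) { A[i, j] <- A[i, j] - gij; A[j, i] <- A[j, i] - gij }
    if (iu && !ju) b[i] <- b[i] + gij * p0
    if (ju && !iu) b[j] <- b[j] + gij * p0
  }
  p_unknown <- tryCatch(solve(A, b), error = function(e)
    stop("singular flow system (", conditionMessage(e), "); check tree ",
         "connectivity and resistances", call. = FALSE))

  pressure <- stats::setNames(rep(p0, length(nodes)), nodes)
  pressure[unknown] <- p_unknown
  # stagnant occluded outlet nodes inherit the upstream nodal pressure
  for (lab in occluded_seg) {
    upn <- seg[lab, "parent"]; if (is.na(upn)) upn <- "INLET"
    pressure[lab] <- pressure[upn]
  }

  flow <- stats::setNames(rep(0, nrow(seg)), seg$label)
  flow[active] <- g * (pressure[up] - pressure[active])
  # a tree with a single source admits no genuine backflow; clip roundoff
  # negatives in stagnant branches
  stopifnot(min(flow) > -1e-9 * q_in)
  flow <- pmax(flow, 0)

  new_flow_solution(tree, flow, q_in, fluid, pressure = pressure,
                    mode = "resistance")
}

new_flow_solution <- function(tree, flow, inlet_flow, fluid, pressure = NULL,
                              mode) {
  seg <- tree$segments
  re <- if (is.null(fluid)) rep(NA_real_, nrow(seg)) else
    reynolds_number(seg, unname(flow[seg$label]), fluid)
  structure(
    list(segment = data.frame(label = seg$label,
                              flow = unname(flow[seg$label]),
                              fraction = unname(flow[seg$label]) / inlet_flow,
                              reynolds = re,
                              row.names = seg$label,
                              stringsAsFactors = FALSE),
         node_pressure = pressure,
         inlet_flow = inlet_flow,
         mode = mode),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution (", x$mode, " mode): inlet flow ",
      format(x$inlet_flow), " m3/s\n", sep = "")
  print(x$segment, digits = 4)
  invisible(x)
}

#' Per-outlet flow fractions of a solution
#'
#' @param solution A `flow_solution`.
#' @param tree The `vascular_tree` it was computed on.
#' @return Named vector of outlet flow fractions in outlet order.
#' @export
outlet_fractions <- function(solution, tree) {
  stopifnot(inherits(solution, "flow_solution"), inherits(tree, "vascular_tree"))
  term <- terminal_segments(tree)
  stats::setNames(solution$segment[term, "fraction"], tree$outlet_order)
}

#' Aggregate prescribed outlet out-splits up the tree
#'
#' The coupling mode: outlet boundary conditions are measured dimensionless
#' out-splits, and each segment's flow is the inlet flow times the sum of
#' out-splits over its downstream outlets. Splits are used raw by default —
#' printed tables can sum to slightly more or less than 1 due to rounding —
#' so conservation \eqn{Q_{parent} = \sum Q_{child}} holds exactly while the
#' root fraction equals the split total. Pressures are not computed in this
#' mode.
#'
#' @param tree A `vascular_tree`.
#' @param inlet_flow Inlet volumetric flow (m3/s).
#' @param splits Either a named numeric vector of out-splits covering every
#'   outlet, or a `split_table` with `scenario` naming the column to use.
#' @param scenario Scenario name, required when `splits` is a `split_table`
#'   holding more than one scenario.
#' @param renormalize If `TRUE`, rescale the splits to sum to 1 first
#'   (default `FALSE`: raw printed values reproduce the reference WSS tables
#'   best).
#' @param fluid Optional [fluid_properties()] for Reynolds numbers.
#' @return A `flow_solution` with `mode = "splits"` and no nodal pressures.
#' @export
#' @examples
#' tree <- build_tree()
#' sol <- flows_from_splits(tree, 3.25e-9, table2_splits(), scenario = "control")
#' sol$segment["C2-B2", "fraction"]   # 0.494
flows_from_splits <- function(tree, inlet_flow, splits, scenario = NULL,
                              renormalize = FALSE, fluid = fluid_properties()) {
  stopifnot(inherits(tree, "vascular_tree"), inlet_flow > 0)
  if (inherits(splits, "split_table") || is.data.frame(splits))
    splits <- outlet_splits(splits, scenario)
  missing_out <- setdiff(tree$outlet_order, names(splits))
  if (length(missing_out))
    stop("splits missing outlets: ", paste(missing_out, collapse = ", "),
         call. = FALSE)
  splits <- splits[tree$outlet_order]
  if (sum(splits) <= 0) stop("out-splits sum to zero", call. = FALSE)
  if (renormalize) splits <- splits / sum(splits)

  seg <- tree$segments
  flow <- vapply(seg$label, function(lab)
    inlet_flow * sum(splits[downstream_outlets(tree, lab)]), numeric(1))
  new_flow_solution(tree, flow, inlet_flow, fluid, pressure = NULL,
                    mode = "splits")
}
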