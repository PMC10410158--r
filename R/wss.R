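#' Round half away from zero
#'
#' The rounding convention of the reference tables (base `round()` rounds
#' half to even). Used when reproducing printed 2-decimal WSS values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Per-branch wall shear stress tables
#'
#' A `wss_table` is a data.frame with columns `branch`, `scenario`, `wss_pa`
#' and `provenance` (`"model"` for Poiseuille-computed values, `"reference"`
#' for values taken from an external CFD table, `"rescaled"` for values
#' obtained by flow-ratio rescaling of a reference).
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `wss_table`.
#' @export
wss_table <- function(df) {
  need <- c("branch", "scenario", "wss_pa", "provenance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("WSS table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$wss_pa < 0)) stop("wss_pa must be >= 0", call. = FALSE)
  class(df) <- c("wss_table", "data.frame")
  df
}

#' @rdname wss_table
#' @param path CSV path.
#' @export
read_wss_table <- function(path) {
  wss_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname wss_table
#' @param x A `wss_table`.
#' @export
write_wss_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged reference per-branch WSS table (CFD, four scenarios)
#'
#' Area-weighted averaged wall shear stress per branch from the reference 3D
#' CFD analyses of the four impairment scenarios, in Pa. Used as the
#' reference that the flow-ratio rescaling model is validated against; the
#' control column is the default rescaling reference.
#'
#' @param scenario Optional scenario name to subset to.
#' @return A `wss_table`.
#' @export
table3_reference <- function(scenario = NULL) {
  tbl <- read_wss_table(system.file("extdata", "table3_wss.csv",
                                    package = "murraynet", mustWork = TRUE))
  if (!is.null(scenario)) {
    if (!scenario %in% tbl$scenario)
      stop("scenario not in reference table: ", scenario, call. = FALSE)
    tbl <- tbl[tbl$scenario == scenario, , drop = FALSE]
  }
  tbl
}

#' Poiseuille wall shear stress of a segment
#'
#' \eqn{\tau = 4 \mu Q / (\pi r^3)}, the wall shear stress of fully developed
#' steady laminar pipe flow. Note this is a fully-developed closure: 3D CFD of
#' the same geometry with a flat inlet profile reports higher area-averaged
#' WSS (entrance and junction effects), so absolute levels from this closure
#' are indicative while ratios across scenarios are the validated quantity
#' (see [rescale_wss()]).
#'
#' @param segment Segment record with a `radius` field (m).
#' @param flow Volumetric flow (m3/s), >= 0.
#' @param fluid A [fluid_properties()].
#' @return Wall shear stress in Pa.
#' @export
#' @examples
#' poiseuille_wss(list(radius = 0.5e-3), 9.4248e-9)   # 0.096 Pa
poiseuille_wss <- function(segment, flow, fluid = fluid_properties()) {
  r <- segment$radius
  if (!is.numeric(r) || any(r <= 0)) stop("radius must be > 0", call. = FALSE)
  if (!is.numeric(flow) || any(flow < 0)) stop("flow must be >= 0", call. = FALSE)
  4 * fluid$viscosity * flow / (pi * r^3)
}

#' Poiseuille WSS table for a whole flow solution
#'
#' @param tree A `vascular_tree`.
#' @param solution A `flow_solution` on that tree.
#' @param fluid A [fluid_properties()].
#' @param scenario Scenario name recorded in the output.
#' @return A `wss_table` with `provenance = "model"`.
#' @export
wss_from_flow <- function(tree, solution, fluid = fluid_properties(),
                          scenario = "scenario") {
  stopifnot(inherits(tree, "vascular_tree"), inherits(solution, "flow_solution"))
  seg <- tree$segments
  tau <- poiseuille_wss(seg, solution$segment[seg$label, "flow"], fluid)
  wss_table(data.frame(branch = seg$label, scenario = scenario,
                       wss_pa = tau, provenance = "model",
                       stringsAsFactors = FALSE))
}

#' Per-branch flow fractions implied by a set of out-splits
#'
#' The fraction of inlet flow carried by each branch is the sum of out-splits
#' over its downstream outlets. This is the quantity whose scenario-to-control
#' ratio drives the WSS rescaling model.
#'
#' @param tree A `vascular_tree`.
#' @param splits Named out-split vector or a `split_table`.
#' @param scenario Scenario name when `splits` is a multi-scenario table.
#' @return Named numeric vector of branch flow fractions.
#' @export
branch_fractions <- function(tree, splits, scenario = NULL) {
  if (inherits(splits, "split_table") || is.data.frame(splits))
    splits <- outlet_splits(splits, scenario)
  vapply(stats::setNames(tree$segments$label, tree$segments$label),
         function(lab) sum(splits[downstream_outlets(tree, lab)]), numeric(1))
}

#' Rescale a reference WSS table by branch flow-fraction ratios
#'
#' At fixed inlet velocity and geometry, area-averaged WSS in a branch scales
#' with the flow it carries, so a scenario's WSS can be predicted from a
#' reference scenario's WSS as
#' \eqn{\tau_s(b) = \tau_{ref}(b) \, f_s(b) / f_{ref}(b)}, where f is the
#' branch flow fraction ([branch_fractions()]). Branches with
#' \eqn{f_s(b) = 0} get exactly 0. This proportionality reproduces the
#' reference CFD tables across occlusion scenarios to within the tables'
#' printed precision.
#'
#' @param reference A `wss_table` holding one scenario (the reference).
#' @param reference_fractions Named per-branch flow fractions of the
#'   reference scenario.
#' @param scenario_fractions Named per-branch flow fractions of the target
#'   scenario.
#' @param scenario Name recorded for the output scenario.
#' @return A `wss_table` with `provenance = "rescaled"`, same branch order as
#'   `reference`.
#' @export
#' @examples
#' tree <- build_tree()
#' t2 <- table2_splits()
#' pred <- rescale_wss(table3_reference("control"),
#'                     branch_fractions(tree, t2, "control"),
#'                     branch_fractions(tree, t2, "case_3/8"),
#'                     scenario = "case_3/8")
#' round(pred$wss_pa[pred$branch == "C2-B2"], 2)   # 0.40
rescale_wss <- function(reference, reference_fractions, scenario_fractions,
                        scenario = "rescaled") {
  stopifnot(is.data.frame(reference))
  miss <- setdiff(reference$branch, names(reference_fractions))
  if (length(miss))
    stop("reference fractions missing branches: ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(reference$branch, names(scenario_fractions))
  if (length(miss))
    stop("scenario fractions missing branches: ",
         paste(miss, collapse = ", "), call. = FALSE)
  f_ref <- reference_fractions[reference$branch]
  f_sc <- scenario_fractions[reference$branch]
  bad <- reference$wss_pa > 0 & f_ref <= 0
  if (any(bad))
    stop("zero reference fraction for branch with nonzero reference WSS: ",
         paste(reference$branch[bad], collapse = ", "), call. = FALSE)
  tau <- ifelse(f_sc == 0, 0,
                reference$wss_pa * ifelse(f_ref > 0, f_sc / f_ref, 0))
  wss_table(data.frame(branch = reference$branch, scenario = scenario,
                       wss_pa = unname(tau), provenance = "rescaled",
                       stringsAsFactors = FALSE))
}

#' Summarize a per-branch WSS table
#'
#' @param table A non-empty `wss_table` (one scenario).
#' @param zero_threshold WSS at or below this (Pa) counts as zero-flow; the
#'   default 0.05 Pa absorbs near-zero CFD artifacts in reference tables.
#' @return A list: `max_branch`, `max_wss`, `min_branch`, `min_wss`,
#'   `n_zero` (branches at or below `zero_threshold`), `mean_nonzero`.
#' @export
#' @examples
#' wss_summary(table3_reference("case_5/8"))$max_branch   # "C4-B7"
wss_summary <- function(table, zero_threshold = 0.05) {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) stop("empty WSS table", call. = FALSE)
  w <- table$wss_pa
  zero <- w <= zero_threshold
  list(max_branch = table$branch[which.max(w)], max_wss = max(w),
       min_branch = table$branch[which.min(w)], min_wss = min(w),
       n_zero = sum(zero),
       mean_nonzero = if (all(zero)) NA_real_ else mean(w[!zero]))
}
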