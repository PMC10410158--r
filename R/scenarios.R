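#' Define a perfusion-impairment scenario
#'
#' A scenario is a named occlusion pattern, optionally carrying the measured
#' out-splits observed under that occlusion.
#'
#' @param name Scenario name (unique within a study).
#' @param occluded_outlets Character vector of blocked outlet ids, or an
#'   [occlusion_pattern()].
#' @param measured_splits Optional `split_table` restricted to this scenario;
#'   occluded outlets must have zero split in it.
#' @return An object of class `perfusion_scenario`.
#' @export
perfusion_scenario <- function(name, occluded_outlets = character(0),
                               measured_splits = NULL) {
  if (!inherits(occluded_outlets, "occlusion_pattern"))
    occluded_outlets <- occlusion_pattern(occluded_outlets)
  if (!is.null(measured_splits)) {
    sp <- outlet_splits(measured_splits, name)
    occ <- occluded_outlets$occluded_outlets
    if (any(sp[names(sp) %in% occ] != 0))
      stop("occluded outlets must have zero measured split in scenario ",
           name, call. = FALSE)
  }
  structure(list(name = name, occlusion = occluded_outlets,
                 measured_splits = measured_splits),
            class = "perfusion_scenario")
}

#' The four built-in impairment scenarios
#'
#' `control` (all outlets open) plus three progressively impaired
#' configurations in which one, three and five of the eight outlets are
#' blocked (`case_1/8`, `case_3/8`, `case_5/8`). Occlusion sets are
#' reconstructed from the exact-zero rows of the packaged measurement table
#' ([table2_splits()]), which each scenario carries as its measured splits:
#' control = none, case_1/8 = O3, case_3/8 = O1-O3,
#' case_5/8 = O1-O3, O5, O8.
#'
#' @return Named list of four `perfusion_scenario` objects.
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function() {
  tbl <- table2_splits()
  scens <- c("control", "case_1/8", "case_3/8", "case_5/8")
  out <- lapply(scens, function(sc) {
    sp <- outlet_splits(tbl, sc)
    perfusion_scenario(sc, names(sp)[sp == 0],
                       measured_splits = split_table(tbl[tbl$scenario == sc, ]))
  })
  stats::setNames(out, scens)
}

#' Number of zero-flow branches under an occlusion set
#'
#' A branch carries zero flow exactly when every outlet downstream of it is
#' occluded; the count is a pure function of topology and the occlusion set.
#'
#' @param tree A `vascular_tree`.
#' @param occluded_outlets Character vector of blocked outlet ids.
#' @return Integer count of zero-flow segments.
#' @export
zero_flow_count <- function(tree, occluded_outlets) {
  sum(vapply(tree$segments$label, function(lab)
    all(downstream_outlets(tree, lab) %in% occluded_outlets), logical(1)))
}

#' Run the full tree -> flow -> WSS -> comparison pipeline
#'
#' Builds the tree once, computes each scenario's flow field (from its
#' measured out-splits in `"splits"` mode, or by solving the resistance
#' network under its occlusion pattern in `"resistance"` mode), derives both
#' Poiseuille ("model") and reference-rescaled WSS per branch, and assembles
#' per-branch and per-outlet ratios against the control scenario. The
#' pipeline is deterministic: identical inputs give identical outputs.
#'
#' @param config A [geometry_config()].
#' @param fluid A [fluid_properties()].
#' @param bc A [flow_bc()].
#' @param scenarios List of [perfusion_scenario()]s; must include one named
#'   `control_name`.
#' @param mode `"splits"` (requires `measured_splits` on every scenario) or
#'   `"resistance"`.
#' @param reference_wss Optional `wss_table` (single scenario) used as the
#'   rescaling reference for the control scenario; defaults to the packaged
#'   CFD control column when every built-in branch label is present in the
#'   tree, otherwise to the control Poiseuille table.
#' @param control_name Name of the reference scenario (default `"control"`).
#' @return An object of class `scenario_comparison`: list with `tree`,
#'   `scenarios`, per-scenario `splits` (named outlet vectors), `wss` (long
#'   `wss_table`, rescaled and model provenance), `wss_ratio` and
#'   `split_ratio` (long data.frames of scenario/control ratios; zero-flow
#'   entries recorded as 0), and `zero_flow_counts`.
#' @export
#' @examples
#' cmp <- run_pipeline(scenarios = builtin_scenarios(), mode = "splits")
#' cmp$zero_flow_counts
run_pipeline <- function(config = geometry_config(),
                         fluid = fluid_properties(),
                         bc = flow_bc(),
                         scenarios = builtin_scenarios(),
                         mode = c("splits", "resistance"),
                         reference_wss = NULL,
                         control_name = "control") {
  mode <- match.arg(mode)
  if (!length(scenarios)) stop("no scenarios given", call. = FALSE)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  if (!control_name %in% names(scenarios))
    stop("scenarios must include the control scenario `", control_name, "`",
         call. = FALSE)
  if (mode == "splits") {
    no_sp <- names(scenarios)[vapply(scenarios, function(s)
      is.null(s$measured_splits), logical(1))]
    if (length(no_sp))
      stop("splits mode needs measured_splits on every scenario; missing: ",
           paste(no_sp, collapse = ", "), call. = FALSE)
  }

  tree <- build_tree(config)
  q_in <- inlet_flow_from_bc(tree, bc)

  sols <- lapply(scenarios, function(sc) {
    if (mode == "splits")
      flows_from_splits(tree, q_in, sc$measured_splits, scenario = sc$name,
                        fluid = fluid)
    else
      solve_network(tree, fluid, bc, sc$occlusion)
  })
  splits <- lapply(sols, outlet_fractions, tree = tree)

  if (is.null(reference_wss)) {
    ref_cfd <- tryCatch(table3_reference(control_name), error = function(e) NULL)
    reference_wss <- if (!is.null(ref_cfd) &&
                         all(ref_cfd$branch %in% tree$segments$label)) ref_cfd
      else wss_from_flow(tree, sols[[control_name]], fluid, control_name)
  }

  frac <- lapply(sols, function(s)
    stats::setNames(s$segment$fraction, s$segment$label))
  wss_rescaled <- lapply(names(scenarios), function(nm)
    rescale_wss(reference_wss, frac[[control_name]], frac[[nm]], scenario = nm))
  wss_model <- lapply(names(scenarios), function(nm)
    wss_from_flow(tree, sols[[nm]], fluid, nm))
  wss_all <- wss_table(do.call(rbind, c(wss_rescaled, wss_model)))

  ratio_of <- function(x, x0) ifelse(x == 0, 0, ifelse(x0 > 0, x / x0, 0))
  wss_ratio <- do.call(rbind, lapply(names(scenarios), function(nm)
    data.frame(branch = tree$segments$label, scenario = nm,
               ratio = ratio_of(unname(frac[[nm]]),
                                unname(frac[[control_name]])),
               stringsAsFactors = FALSE)))
  split_ratio <- do.call(rbind, lapply(names(scenarios), function(nm)
    data.frame(outlet_id = tree$outlet_order, scenario = nm,
               ratio = ratio_of(unname(splits[[nm]]),
                                unname(splits[[control_name]])),
               stringsAsFactors = FALSE)))

  zf <- vapply(scenarios, function(sc) {
    occ <- if (mode == "splits") {
      sp <- splits[[sc$name]]; names(sp)[sp == 0]
    } else sc$occlusion$occluded_outlets
    zero_flow_count(tree, occ)
  }, integer(1))

  structure(list(tree = tree, scenarios = scenarios, splits = splits,
                 wss = wss_all, wss_ratio = wss_ratio,
                 split_ratio = split_ratio, zero_flow_counts = zf,
                 control = control_name, mode = mode),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("scenario_comparison (", x$mode, " mode): ",
      paste(names(x$scenarios), collapse = ", "), "\n", sep = "")
  cat("zero-flow branches:",
      paste(names(x$zero_flow_counts), x$zero_flow_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Compensation index of a scenario
#'
#' The largest per-outlet ratio of scenario out-split to control out-split
#' over the still-open outlets. Values above 1 quantify how strongly the flow
#' lost to occluded outlets is redistributed onto (compensated by) the open
#' ones; under a conserved total split it is at least 1 whenever any outlet
#' is occluded.
#'
#' @param comparison A `scenario_comparison`.
#' @param scenario Scenario name present in the comparison.
#' @return The dimensionless index (1 for the control compared to itself,
#'   up to measurement rounding).
#' @export
#' @examples
#' cmp <- run_pipeline(scenarios = builtin_scenarios(), mode = "splits")
#' compensation_index(cmp, "case_5/8")   # about 2.82, at outlet O7
compensation_index <- function(comparison, scenario) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  if (!scenario %in% names(comparison$scenarios))
    stop("unknown scenario: ", scenario, call. = FALSE)
  sp <- comparison$splits[[scenario]]
  sp0 <- comparison$splits[[comparison$control]]
  open <- setdiff(names(sp),
                  comparison$scenarios[[scenario]]$occlusion$occluded_outlets)
  max(sp[open] / sp0[open])
}

#' Read a study configuration from YAML
#'
#' The file may hold `geometry`, `fluid`, `bc`, `mode` and a `scenarios` list
#' (each entry: `name`, optional `occlusions`, optional `splits_file` whose
#' CSV is read as a [split_table()]); omitted sections fall back to package
#' defaults, and an omitted `scenarios` section means the four built-ins.
#'
#' @param path YAML file path.
#' @return A named list of arguments suitable for `do.call(run_pipeline, ...)`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  args$config <- do.call(geometry_config, as.list(y$geometry %||% list()))
  args$fluid <- do.call(fluid_properties, as.list(y$fluid %||% list()))
  args$bc <- do.call(flow_bc, as.list(y$bc %||% list()))
  args$mode <- y$mode %||% "splits"
  args$scenarios <- if (is.null(y$scenarios)) builtin_scenarios() else
    lapply(y$scenarios, function(s) {
      ms <- if (!is.null(s$splits_file)) read_split_table(s$splits_file)
      perfusion_scenario(s$name, as.character(s$occlusions %||% character(0)),
                         measured_splits = ms)
    })
  args
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario comparison to disk
#'
#' Emits `comparison.csv` (branch x scenario WSS, 2-dp rescaled values with
#' full-precision model values alongside), `ratios.csv` (branch and outlet
#' ratios vs control) and `summary.json` (zero-flow counts, compensation
#' indices, per-scenario WSS summary).
#'
#' @param comparison A `scenario_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- comparison$wss
  w$wss_pa <- ifelse(w$provenance == "rescaled",
                     round_half_up(w$wss_pa, 2), signif(w$wss_pa, 3))
  utils::write.csv(w, file.path(dir, "comparison.csv"), row.names = FALSE,
                   quote = FALSE)
  ratios <- rbind(
    data.frame(id = comparison$wss_ratio$branch, kind = "branch",
               scenario = comparison$wss_ratio$scenario,
               ratio = signif(comparison$wss_ratio$ratio, 3)),
    data.frame(id = comparison$split_ratio$outlet_id, kind = "outlet",
               scenario = comparison$split_ratio$scenario,
               ratio = signif(comparison$split_ratio$ratio, 3)))
  utils::write.csv(ratios, file.path(dir, "ratios.csv"), row.names = FALSE,
                   quote = FALSE)
  summ <- list(
    scenarios = names(comparison$scenarios),
    mode = comparison$mode,
    zero_flow_counts = as.list(comparison$zero_flow_counts),
    compensation_index = stats::setNames(
      lapply(names(comparison$scenarios), function(nm)
        compensation_index(comparison, nm)), names(comparison$scenarios)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
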