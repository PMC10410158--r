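#' Split tables: per-outlet flowrates and out-splits
#'
#' A `split_table` is a data.frame with columns `scenario`, `outlet_id`,
#' `flowrate` and `out_split`; the inlet total appears as a row with
#' `outlet_id = "INLET"` and `out_split = 1`. Out-splits are the outlet
#' flowrates normalized by the total measured flow and are the quantity the
#' flow model consumes; the `flowrate` column is carried in whatever
#' consistent unit the measurement used. A packaged fixture
#' ([table2_splits()]) reproduces the reference measurements for the four
#' impairment scenarios verbatim.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `split_table`.
#' @export
split_table <- function(df) {
  need <- c("scenario", "outlet_id", "flowrate", "out_split")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("split table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$out_split < 0))
    stop("out_split values must be >= 0", call. = FALSE)
  class(df) <- c("split_table", "data.frame")
  df
}

#' @rdname split_table
#' @param path CSV path.
#' @export
read_split_table <- function(path) {
  split_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname split_table
#' @param x A `split_table`.
#' @export
write_split_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged reference out-split measurements (four impairment scenarios)
#'
#' Outlet volume-collection measurements for the `control`, `case_1/8`,
#' `case_3/8` and `case_5/8` scenarios: per-outlet flowrates and the
#' dimensionless out-splits used as outlet boundary conditions. Occluded
#' outlets read exactly zero. The flowrate magnitudes are treated as relative
#' (their declared unit is not consistent with the 195 uL/min pump setting);
#' analyses consume the out-splits.
#'
#' @return A `split_table` with all four scenarios.
#' @export
table2_splits <- function() {
  read_split_table(system.file("extdata", "table2_splits.csv",
                               package = "murraynet", mustWork = TRUE))
}

scenario_rows <- function(tbl, scenario = NULL) {
  stopifnot(is.data.frame(tbl))
  scen <- unique(tbl$scenario)
  if (is.null(scenario)) {
    if (length(scen) > 1L)
      stop("table holds scenarios ", paste(scen, collapse = ", "),
           "; pass `scenario`", call. = FALSE)
    scenario <- scen
  }
  if (!scenario %in% scen)
    stop("scenario not in table: ", scenario, call. = FALSE)
  tbl[tbl$scenario == scenario, , drop = FALSE]
}

#' Extract the per-outlet out-splits of one scenario
#'
#' @param tbl A `split_table`.
#' @param scenario Scenario name; may be omitted if the table holds one.
#' @return Named numeric vector of out-splits, one per outlet.
#' @export
outlet_splits <- function(tbl, scenario = NULL) {
  rows <- scenario_rows(tbl, scenario)
  rows <- rows[rows$outlet_id != "INLET", ]
  stats::setNames(rows$out_split, rows$outlet_id)
}

#' Inlet (total) flowrate recorded for one scenario
#'
#' @inheritParams outlet_splits
#' @return The inlet-row flowrate, in the table's unit.
#' @export
inlet_flowrate <- function(tbl, scenario = NULL) {
  rows <- scenario_rows(tbl, scenario)
  inl <- rows[rows$outlet_id == "INLET", "flowrate"]
  if (!length(inl)) stop("no INLET row for scenario", call. = FALSE)
  inl
}

#' Relative mass-balance residual of a measured split table
#'
#' \eqn{(\sum_k Q_{O_k} - Q_{inlet}) / Q_{inlet}}: how far the summed outlet
#' flowrates drift from the recorded inlet total. Printed measurement tables
#' typically close to within a fraction of a percent.
#'
#' @inheritParams outlet_splits
#' @return Dimensionless residual (0 for a perfectly consistent table).
#' @export
#' @examples
#' mass_balance_residual(table2_splits(), "control")   # about -1e-3
mass_balance_residual <- function(tbl, scenario = NULL) {
  rows <- scenario_rows(tbl, scenario)
  inl <- rows[rows$outlet_id == "INLET", "flowrate"]
  if (!length(inl)) stop("no INLET row for scenario", call. = FALSE)
  if (inl == 0) stop("inlet flowrate is zero", call. = FALSE)
  (sum(rows[rows$outlet_id != "INLET", "flowrate"]) - inl) / inl
}
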