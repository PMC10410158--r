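# Deterministic substreams: each draw site uses the global seed plus a
# counter, so adding outlets/segments never reshuffles earlier draws, and the
# caller's RNG state is left untouched.
substream_draw <- function(seed, counter, rfun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 1009L * as.integer(counter)) %% 2147483629L)
  rfun()
}

#' Measurement noise model for outlet volume collection
#'
#' Noise is multiplicative on the collected volume (reading a meniscus or
#' weighing scales with the amount collected). The default relative standard
#' deviation 0.03 is calibrated to the spread of the reference control
#' out-splits (0.121-0.129 around the ideal 0.125). The truncated-Gaussian
#' variant clips the multiplicative factor at zero; the lognormal variant has
#' unit mean.
#'
#' @param relative_sd Relative standard deviation, >= 0.
#' @param distribution `"gaussian-truncated-at-zero"` or `"lognormal"`.
#' @param seed Integer seed; draws are deterministic given it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.03,
                        distribution = c("gaussian-truncated-at-zero",
                                         "lognormal"),
                        seed = 1L) {
  stopifnot(is.numeric(relative_sd), relative_sd >= 0)
  structure(list(relative_sd = relative_sd,
                 distribution = match.arg(distribution),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Fabrication-induced channel width jitter
#'
#' Fabricated channel widths vary along the flow path by up to about 20 um.
#' The default `width_sd` is chosen so that 99% of Gaussian width deviations
#' fall within that 20 um envelope (`width_sd = 20e-6 / qnorm(0.995)`).
#'
#' @param width_sd Standard deviation of the channel *width* (diameter)
#'   perturbation, in metres.
#' @param seed Integer seed.
#' @return An object of class `fabrication_jitter`.
#' @export
fabrication_jitter <- function(width_sd = 20e-6 / stats::qnorm(0.995),
                               seed = 1L) {
  stopifnot(is.numeric(width_sd), width_sd >= 0)
  structure(list(width_sd = width_sd, seed = as.integer(seed)),
            class = "fabrication_jitter")
}

#' Apply fabrication jitter to a tree's radii
#'
#' Each segment's radius receives an independent Gaussian perturbation of
#' half a width (diameter) deviation. Deterministic given the jitter seed;
#' draws use one substream per segment (by position), so extending the tree
#' does not reshuffle existing segments' perturbations.
#'
#' @param tree A `vascular_tree`.
#' @param jitter A [fabrication_jitter()].
#' @return A perturbed copy of `tree`.
#' @export
perturb_geometry <- function(tree, jitter = fabrication_jitter()) {
  stopifnot(inherits(tree, "vascular_tree"),
            inherits(jitter, "fabrication_jitter"))
  if (jitter$width_sd == 0) return(tree)
  seg <- tree$segments
  dw <- vapply(seq_len(nrow(seg)), function(i)
    substream_draw(jitter$seed, i, function()
      stats::rnorm(1, 0, jitter$width_sd)), numeric(1))
  new_r <- seg$radius + dw / 2
  if (any(new_r <= 0))
    stop("jitter produced a non-positive radius; reduce `width_sd`",
         call. = FALSE)
  tree$segments$radius <- new_r
  tree
}

#' Simulate an outlet volume-collection measurement
#'
#' Emulates one experimental run: the resistance network is solved at the
#' pump flowrate under the given occlusion, each open outlet's true flow is
#' converted to a collected volume over the run duration, multiplicative
#' measurement noise is applied per outlet, occluded outlets collect exactly
#' zero (sealed blocks, no leak term), and out-splits are normalized by the
#' measured total so they sum to 1 exactly. The returned table's inlet row
#' carries the measured total, making the table mass-consistent by
#' construction. Deterministic given the noise seed (one substream per
#' outlet).
#'
#' @param tree A `vascular_tree`.
#' @param fluid A [fluid_properties()].
#' @param pump_rate Inlet volumetric flow (m3/s); default 195 uL/min.
#' @param occlusion An [occlusion_pattern()].
#' @param noise A [noise_model()].
#' @param duration Collection time in seconds (default 60).
#' @param scenario Scenario name recorded in the output.
#' @return A `split_table` with an extra `volume_ul` column (collected
#'   volumes in microlitres); `flowrate` is in m3/s.
#' @export
#' @examples
#' tab <- simulate_measurements(build_tree(), noise = noise_model(0, seed = 1))
#' tab$volume_ul[tab$outlet_id != "INLET"]   # 24.375 uL at each outlet
simulate_measurements <- function(tree,
                                  fluid = fluid_properties(),
                                  pump_rate = 195e-9 / 60,
                                  occlusion = occlusion_pattern(),
                                  noise = noise_model(),
                                  duration = 60,
                                  scenario = "simulated") {
  stopifnot(pump_rate > 0, duration > 0, inherits(noise, "noise_model"))
  sol <- solve_network(tree, fluid,
                       flow_bc("flowrate", inlet_flowrate = pump_rate),
                       occlusion)
  q_out <- outlet_fractions(sol, tree) * pump_rate        # m3/s, exact zeros
  vol <- q_out * duration                                  # m3
  sd <- noise$relative_sd
  factors <- vapply(seq_along(vol), function(i)
    substream_draw(noise$seed, i, function() {
      if (sd == 0) return(1)
      if (noise$distribution == "lognormal")
        stats::rlnorm(1, meanlog = -log(1 + sd^2) / 2,
                      sdlog = sqrt(log(1 + sd^2)))
      else max(0, stats::rnorm(1, 1, sd))
    }), numeric(1))
  meas <- vol * factors
  meas[tree$outlet_order %in% occlusion$occluded_outlets] <- 0
  total <- sum(meas)
  if (total <= 0) stop("no volume collected; check occlusions", call. = FALSE)
  out <- data.frame(
    scenario = scenario,
    outlet_id = c("INLET", tree$outlet_order),
    flowrate = c(total, meas) / duration,
    out_split = c(1, meas / total),
    volume_ul = c(total, meas) * 1e9,
    stringsAsFactors = FALSE)
  split_table(out)
}

#' Detect occluded outlets from a measured split table
#'
#' Flags outlets whose out-split is at or below a threshold. Because blocked
#' outlets collect exactly zero volume while open ones keep fractions well
#' above any plausible noise floor, recovery is robust over a wide threshold
#' range.
#'
#' @param splits A `split_table` (one scenario) or named out-split vector.
#' @param threshold Out-split cut-off in `[0, 1)`; default 0.01.
#' @param scenario Scenario name when `splits` holds several.
#' @return An [occlusion_pattern()] of the flagged outlets.
#' @export
#' @examples
#' detect_occlusions(table2_splits(), scenario = "case_3/8")
detect_occlusions <- function(splits, threshold = 0.01, scenario = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  if (inherits(splits, "split_table") || is.data.frame(splits))
    splits <- outlet_splits(splits, scenario)
  occlusion_pattern(names(splits)[splits <= threshold])
}
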