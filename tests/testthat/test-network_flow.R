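test_that("segment_resistance is Hagen-Poiseuille with its scalings", {
  fl <- fluid_properties()
  R <- segment_resistance(list(radius = 0.5e-3, length = 2.5e-3), fl)
  expect_equal(R, 8 * 1e-3 * 2.5e-3 / (pi * (0.5e-3)^4), tolerance = 1e-12)
  expect_equal(R, 1.0186e8, tolerance = 1e-4)
  expect_equal(segment_resistance(list(radius = 0.5e-3, length = 5e-3), fl),
               2 * R, tolerance = 1e-12)
  expect_equal(segment_resistance(list(radius = 0.25e-3, length = 2.5e-3), fl),
               16 * R, tolerance = 1e-12)
  expect_error(segment_resistance(list(radius = 0, length = 1e-3), fl),
               "radius")
})

test_that("reynolds_number gives Re = 12 at the printed inlet condition", {
  fl <- fluid_properties()
  seg <- list(radius = 0.5e-3)
  q <- 0.012 * pi * (0.5e-3)^2
  expect_equal(reynolds_number(seg, q, fl), 12.0, tolerance = 1e-12)
  expect_equal(reynolds_number(seg, 0, fl), 0)
  expect_equal(reynolds_number(seg, 2 * q, fl), 24.0, tolerance = 1e-12)
})

test_that("unoccluded symmetric tree splits flow equally over all outlets", {
  tree <- default_tree()
  sol <- solve_network(tree)
  expect_equal(unname(outlet_fractions(sol, tree)), rep(0.125, 8),
               tolerance = 1e-12)
  expect_equal(sol$segment["C1", "fraction"], 1, tolerance = 1e-12)
  # velocity-mode inlet flow is V * pi r^2
  expect_equal(sol$inlet_flow, 0.012 * pi * (0.5e-3)^2, tolerance = 1e-12)
})

test_that("occlusions enforce exact zero flow and conserve the inlet flow", {
  tree <- default_tree()
  # all but one outlet blocked: the open outlet takes everything
  sol <- solve_network(tree, occlusion = occlusion_pattern(paste0("O", 1:7)))
  fr <- outlet_fractions(sol, tree)
  expect_identical(unname(fr[paste0("O", 1:7)]), rep(0, 7))
  expect_equal(unname(fr["O8"]), 1, tolerance = 1e-12)
  expect_error(solve_network(tree,
                             occlusion = occlusion_pattern(paste0("O", 1:8))),
               "all outlets occluded")
  expect_error(solve_network(tree, occlusion = occlusion_pattern("O9")),
               "not in tree")
  # open-outlet flows sum to the inlet flow
  sol3 <- solve_network(tree, occlusion = occlusion_pattern("O3"))
  expect_equal(sum(outlet_fractions(sol3, tree)), 1, tolerance = 1e-10)
})

test_that("nodal solve matches the series-parallel oracle on random patterns", {
  tree <- default_tree()
  fl <- fluid_properties()
  bc <- flow_bc("flowrate", inlet_flowrate = 3.25e-9)
  set.seed(11)
  for (rep in 1:25) {
    occ <- sample(paste0("O", 1:8), sample(0:7, 1))
    sol <- solve_network(tree, fl, bc, occlusion_pattern(occ))
    oracle <- sp_flows(tree, fl, 3.25e-9, occ)
    expect_equal(sol$segment$flow, unname(oracle[sol$segment$label]),
                 tolerance = 1e-10)
  }
})

test_that("junction mass conservation holds in both modes", {
  tree <- default_tree()
  sol_r <- solve_network(tree, occlusion = occlusion_pattern(c("O2", "O5")))
  sol_s <- flows_from_splits(tree, 3.25e-9, table2_splits(), "case_3/8")
  for (sol in list(sol_r, sol_s)) {
    q <- stats::setNames(sol$segment$flow, sol$segment$label)
    for (lab in tree$segments$label[is.na(tree$segments$outlet)]) {
      kids <- tree_children(tree, lab)
      expect_equal(q[[lab]], sum(q[kids]), tolerance = 1e-10)
    }
  }
})

test_that("feeding solver fractions back through flows_from_splits reproduces the solve", {
  tree <- default_tree()
  set.seed(23)
  for (rep in 1:10) {
    occ <- sample(paste0("O", 1:8), sample(0:6, 1))
    sol <- solve_network(tree, occlusion = occlusion_pattern(occ))
    again <- flows_from_splits(tree, sol$inlet_flow,
                               outlet_fractions(sol, tree))
    expect_equal(again$segment$flow, sol$segment$flow, tolerance = 1e-10)
  }
})

test_that("mirrored occlusion patterns give mirrored outlet flows", {
  tree <- default_tree()
  mirror <- function(ids) paste0("O", 9 - as.integer(sub("O", "", ids)))
  set.seed(37)
  for (rep in 1:10) {
    occ <- sample(paste0("O", 1:8), sample(1:6, 1))
    f1 <- outlet_fractions(solve_network(tree,
            occlusion = occlusion_pattern(occ)), tree)
    f2 <- outlet_fractions(solve_network(tree,
            occlusion = occlusion_pattern(mirror(occ))), tree)
    expect_equal(unname(f1), unname(rev(f2)), tolerance = 1e-10)
  }
})

test_that("occluding one more outlet never starves a still-open outlet", {
  tree <- default_tree()
  set.seed(53)
  for (rep in 1:10) {
    occ <- sample(paste0("O", 1:8), sample(0:6, 1))
    extra <- sample(setdiff(paste0("O", 1:8), occ), 1)
    f_before <- outlet_fractions(solve_network(tree,
                  occlusion = occlusion_pattern(occ)), tree)
    f_after <- outlet_fractions(solve_network(tree,
                  occlusion = occlusion_pattern(c(occ, extra))), tree)
    still_open <- setdiff(paste0("O", 1:8), c(occ, extra))
    expect_true(all(f_after[still_open] >= f_before[still_open] - 1e-12))
  }
})

test_that("flows_from_splits aggregates measured out-splits up the tree", {
  tree <- default_tree()
  t2 <- table2_splits()
  ctrl <- flows_from_splits(tree, 3.25e-9, t2, "control")
  expect_equal(ctrl$segment["C2-B2", "fraction"], 0.494, tolerance = 1e-12)
  c38 <- flows_from_splits(tree, 3.25e-9, t2, "case_3/8")
  expect_equal(c38$segment["C2-B2", "fraction"], 0.83, tolerance = 1e-12)
  # a pure path indicator: all flow through one outlet's ancestry
  ind <- stats::setNames(c(1, rep(0, 7)), paste0("O", 1:8))
  sol <- flows_from_splits(tree, 1e-9, ind)
  on_path <- c("C1", "C2-B1", "C3-B1", "C4-B1")
  expect_equal(sol$segment[on_path, "flow"], rep(1e-9, 4),
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_equal(sum(sol$segment$flow > 0), 4)
  expect_error(flows_from_splits(tree, 1e-9, ind[1:5]), "missing outlets")
})

test_that("mass_balance_residual reproduces the printed table closures", {
  t2 <- table2_splits()
  expect_equal(mass_balance_residual(t2, "control"), -0.0010, tolerance = 1e-2)
  expect_equal(mass_balance_residual(t2, "case_5/8"), 0, tolerance = 1e-12)
  perfect <- split_table(data.frame(
    scenario = "s", outlet_id = c("INLET", "O1", "O2"),
    flowrate = c(2, 1, 1), out_split = c(1, 0.5, 0.5)))
  expect_equal(mass_balance_residual(perfect), 0)
  zero <- split_table(data.frame(scenario = "s",
    outlet_id = c("INLET", "O1"), flowrate = c(0, 0), out_split = c(1, 0)))
  expect_error(mass_balance_residual(zero), "zero")
})
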