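test_that("murray_child_radius matches the closed form r_p * n^(-1/m)", {
  expect_equal(murray_child_radius(0.5e-3, 2, 3.0), 0.5e-3 * 2^(-1 / 3),
               tolerance = 1e-12)
  expect_equal(murray_child_radius(0.5e-3, 2, 3.0), 3.9685e-4,
               tolerance = 1e-4)
  expect_equal(murray_child_radius(0.5e-3, 2, 2.2694), 3.684e-4,
               tolerance = 1e-4)
  # a single child preserves the radius for any exponent
  for (m in c(0.5, 2, 3, 7))
    expect_identical(murray_child_radius(0.37e-3, 1, m), 0.37e-3)
  expect_error(murray_child_radius(-1e-3, 2, 3), "parent_radius")
  expect_error(murray_child_radius(1e-3, 2, 0), "exponent")
})

test_that("infer_murray_exponent inverts the taper", {
  expect_equal(infer_murray_exponent(1.0e-3, 0.4e-3, 3),
               3 * log(2) / log(2.5), tolerance = 1e-12)
  expect_equal(infer_murray_exponent(1.0e-3, 0.4e-3, 3), 2.2694,
               tolerance = 1e-4)
  expect_equal(infer_murray_exponent(1.0e-3, 0.5e-3, 3), 3.0,
               tolerance = 1e-12)
  expect_equal(infer_murray_exponent(1.0e-3, 0.9e-3, 1), 6.579,
               tolerance = 1e-3)
  expect_error(infer_murray_exponent(1e-3, 1e-3, 3), "outlet_diameter")
  # building with the inferred exponent reproduces both endpoint diameters
  for (d_out in c(0.3e-3, 0.4e-3, 0.5e-3)) {
    cfg <- geometry_config(outlet_diameter = d_out)
    tree <- build_tree(cfg)
    term <- terminal_segments(tree)
    expect_equal(2 * tree$segments[tree$root, "radius"], 1e-3)
    expect_equal(2 * tree$segments[term, "radius"], rep(d_out, 8),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("build_tree produces the labeled symmetric tree with conserved quantities", {
  tree <- default_tree()
  seg <- tree$segments
  expect_equal(nrow(seg), 15)
  expect_equal(tree$outlet_order, paste0("O", 1:8))
  expect_setequal(seg$label[seg$generation == 3],
                  paste0("C3-B", 1:4))
  expect_equal(seg[!is.na(seg$outlet), "outlet"], paste0("O", 1:8))
  # every non-root parent exists, terminals have no children
  expect_true(all(seg$parent[-1] %in% seg$label))
  for (lab in terminal_segments(tree))
    expect_length(tree_children(tree, lab), 0)
  for (lab in seg$label[is.na(seg$outlet)])
    expect_length(tree_children(tree, lab), 2)

  # path-length conservation on every root-to-outlet path
  for (term in terminal_segments(tree)) {
    len <- 0; cur <- term
    while (!is.na(cur)) { len <- len + seg[cur, "length"]; cur <- seg[cur, "parent"] }
    expect_equal(len, 1e-2, tolerance = 1e-12)
  }

  # per-generation taper ratio is 2^(-1/m) = 0.4^(1/3)
  kids <- tree_children(tree, "C1")
  expect_equal(seg[kids[1], "radius"] / seg["C1", "radius"], 0.4^(1 / 3),
               tolerance = 1e-12)

  # single-bifurcation tree
  small <- build_tree(geometry_config(n_generations = 1))
  expect_equal(nrow(small$segments), 3)
  expect_equal(small$outlet_order, c("O1", "O2"))
})

test_that("Murray conservation holds at every interior junction for any exponent", {
  for (m in c(2, 2.2694412, 3)) {
    tree <- build_tree(geometry_config(murray_exponent = m))
    seg <- tree$segments
    for (lab in seg$label[is.na(seg$outlet)]) {
      kids <- tree_children(tree, lab)
      expect_equal(seg[lab, "radius"]^m, sum(seg[kids, "radius"]^m),
                   tolerance = 1e-12)
    }
  }
})

test_that("length_fractions and config invariants are enforced", {
  expect_error(geometry_config(length_fractions = c(0.5, 0.5)), "generation")
  expect_error(geometry_config(length_fractions = c(0.4, 0.3, 0.2, 0.2)),
               "sum to 1")
  cfg <- geometry_config(length_fractions = c(0.4, 0.3, 0.2, 0.1))
  tree <- build_tree(cfg)
  expect_equal(tree$segments["C1", "length"], 4e-3)
  expect_equal(tree$segments["C4-B5", "length"], 1e-3)
  expect_error(geometry_config(n_generations = 0), "n_generations")
  expect_error(geometry_config(outlet_diameter = 2e-3), "smaller")
})

test_that("downstream_outlets follows the left-to-right branch labeling", {
  tree <- default_tree()
  expect_equal(downstream_outlets(tree, "C2-B1"), paste0("O", 1:4))
  expect_equal(downstream_outlets(tree, "C2-B2"), paste0("O", 5:8))
  expect_equal(downstream_outlets(tree, "C1"), paste0("O", 1:8))
  expect_equal(downstream_outlets(tree, "C3-B2"), c("O3", "O4"))
  expect_equal(downstream_outlets(tree, "C4-B7"), "O7")
  expect_error(downstream_outlets(tree, "C9-B9"), "unknown")
})

test_that("JSON export round-trips losslessly and VTK has one point per node", {
  tree <- default_tree()
  jpath <- withr::local_tempfile(fileext = ".json")
  export_tree(tree, jpath, "json")
  back <- read_tree(jpath)
  expect_equal(back$segments, tree$segments)
  expect_equal(back$outlet_order, tree$outlet_order)
  expect_equal(back$config$murray_exponent, tree$config$murray_exponent)
  expect_equal(length(jsonlite::read_json(jpath)$segments), 15)

  vpath <- withr::local_tempfile(fileext = ".vtk")
  export_tree(tree, vpath, "vtk-polyline")
  lines <- readLines(vpath)
  expect_match(lines[grep("^POINTS", lines)], "POINTS 16 double")
  expect_match(lines[grep("^LINES", lines)], "LINES 15 45")
  expect_equal(sum(grepl("^2 ", lines)), 15)
  expect_error(export_tree(tree, vpath, "stl"), "arg")
})
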