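# Independent series-parallel reduction of the bifurcating resistor ladder.
# Used as the oracle the linear nodal solve is checked against: effective
# resistance of each subtree by recursion (occluded terminals = Inf), then
# flow divided top-down in proportion to subtree conductances.

sp_effective_resistance <- function(tree, fluid, label, occluded) {
  seg <- tree$segments
  R <- segment_resistance(seg[label, ], fluid)
  out <- seg[label, "outlet"]
  if (!is.na(out)) {
    if (out %in% occluded) return(Inf)
    return(R)
  }
  kids <- tree_children(tree, label)
  Rk <- vapply(kids, function(k)
    sp_effective_resistance(tree, fluid, k, occluded), numeric(1))
  g <- sum(1 / Rk[is.finite(Rk)])
  if (g == 0) return(Inf)
  R + 1 / g
}

sp_flows <- function(tree, fluid, inlet_flow, occluded = character(0)) {
  flows <- stats::setNames(numeric(nrow(tree$segments)), tree$segments$label)
  recurse <- function(label, Q) {
    flows[label] <<- Q
    kids <- tree_children(tree, label)
    if (!length(kids)) return(invisible(NULL))
    gk <- vapply(kids, function(k) {
      Rk <- sp_effective_resistance(tree, fluid, k, occluded)
      if (is.finite(Rk)) 1 / Rk else 0
    }, numeric(1))
    for (k in kids)
      recurse(k, if (sum(gk) > 0) Q * gk[[k]] / sum(gk) else 0)
  }
  recurse(tree$root, inlet_flow)
  flows
}

default_tree <- function() build_tree(geometry_config())
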