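test_that("converged ring meshes reproduce the published element counts", {
  r8 <- make_ring(ring_preset("deviceA_8peaks"))
  r5 <- make_ring(ring_preset("deviceA_5peaks"))
  expect_equal(nrow(r8$elements), 240L)
  expect_equal(nrow(r5$elements), 160L)
  # counts are even multiples of the peak number (apexes fall on nodes)
  expect_equal(nrow(r8$elements) %% 16, 0)
  expect_equal(nrow(r5$elements) %% 10, 0)
  # thin 34 mm ring: plane circle, ~107 elements at 1 mm
  rt <- make_ring(ring_preset("thin34"))
  expect_equal(nrow(rt$elements), 107L)
  expect_equal(sqrt(rowSums(rt$nodes[, 1:2]^2)), rep(17, 107))
})

test_that("ring generation is deterministic and length-consistent", {
  s <- ring_preset("deviceA_8peaks")
  expect_identical(make_ring(s), make_ring(s))
  m <- make_ring(s)
  nxt <- c(2:nrow(m$nodes), 1)
  poly_len <- sum(sqrt(rowSums((m$nodes[nxt, ] - m$nodes)^2)))
  ana_len <- ring_wire_length(s$nominal_diameter, s$crown_height, s$n_peaks)
  expect_rel_equal(poly_len, ana_len, 5e-3)   # chords underestimate arcs
  expect_rel_equal(poly_len, nrow(m$elements) * mean(
    sqrt(rowSums((m$nodes[nxt, ] - m$nodes)^2))), 1e-12)
})

test_that("invalid ring specifications are rejected", {
  expect_error(ring_spec("peaks8", nominal_diameter = -1))
  expect_error(ring_spec("peaks8", nominal_diameter = 30,
                         target_element_size = 0))
  expect_error(ring_spec("peaks8", nominal_diameter = 30, n_peaks = 7))
  expect_error(ring_spec("peaks8", nominal_diameter = 10,
                         crown_height = 12))
})

test_that("mean-radius diameter behaves under the stress-free map and scaling", {
  r8 <- make_ring(ring_preset("deviceA_8peaks"))
  expect_rel_equal(measure_diameter(r8), 35.1, 1e-6)
  # radial map to the sutured state gives the catalogue 30 mm
  folded <- fold_ring_nodes(r8$nodes, 1 / 1.17)
  expect_rel_equal(measure_diameter(folded, axis = c(0, 0, 1)), 30, 1e-3)
  expect_rel_equal(measure_diameter(r8$nodes * 0.5), 35.1 / 2, 1e-6)
  expect_error(measure_diameter(r8, ring_id = 5))
})

test_that("the length-preserving fold conserves every segment", {
  r8 <- make_ring(ring_preset("deviceA_8peaks"))
  xf <- fold_ring_nodes(r8$nodes, 0.6)
  nxt <- c(2:nrow(xf), 1)
  L0 <- sqrt(rowSums((r8$nodes[nxt, ] - r8$nodes)^2))
  L1 <- sqrt(rowSums((xf[nxt, ] - xf)^2))
  expect_lt(max(abs(L1 / L0 - 1)), 1e-12)
  # the thin circle buckles out of plane instead of shortening
  rt <- make_ring(ring_preset("thin34"))
  xt <- fold_ring_nodes(rt$nodes, 0.8)
  Lt0 <- sqrt(rowSums((rt$nodes[c(2:107, 1), ] - rt$nodes)^2))
  Lt1 <- sqrt(rowSums((xt[c(2:107, 1), ] - xt)^2))
  # the loop-closure correction perturbs thin-ring segments slightly
  expect_lt(max(abs(Lt1 / Lt0 - 1)), 5e-3)
  expect_gt(diff(range(xt[, 3])), 1)   # buckles out of plane
})

test_that("device assembly matches the catalogue geometries", {
  devC <- make_device(device_preset("C"))
  expect_equal(length(devC$beam$rings), 11L)
  expect_equal(diff(range(devC$membrane$nodes[, 3])), 200, tolerance = 0.01)
  expect_equal(devC$spec$graft_diameter, 34)
  expect_equal(devC$spec$configuration, "FreeFlo")
  devA <- device_preset("A")
  expect_equal(devA$graft_diameter, 30)
  expect_equal(devA$configuration, "ClosedWeb")
  # rings are meshed at the stress-free diameter (nominal x 1.17)
  r1 <- devC$beam$rings[[1]]
  expect_rel_equal(measure_diameter(devC$beam, 1), 34 * 1.17, 1e-3)
  # Free-Flo: the proximal peaks ring has no proximal-apex sutures
  sut <- devC$membrane$suture_map
  expect_false(any(sut[, "stent_node"] %in% r1$apex_prox))
  expect_true(any(sut[, "stent_node"] %in% r1$apex_dist))
})

test_that("suture pairs coincide in the sutured configuration", {
  dev <- make_device(device_preset("desk"))
  pr <- dev$spec$prestress_ratio
  sut <- dev$membrane$suture_map
  # fold each ring onto the sutured diameter; its sutured nodes must
  # land exactly on their graft partners
  for (r in dev$beam$rings) {
    sel <- sut[, "stent_node"] %in% r$nodes
    if (!any(sel)) next
    folded <- fold_ring_nodes(dev$beam$nodes[r$nodes, , drop = FALSE],
                              1 / (1 + pr))
    sn <- sut[sel, "stent_node"]; gn <- sut[sel, "graft_node"]
    gap <- sqrt(rowSums((folded[match(sn, r$nodes), , drop = FALSE] -
                           dev$membrane$nodes[gn, , drop = FALSE])^2))
    expect_lt(max(gap), 1e-6)
  }
  # merged-node count equals the suture map length
  model <- fe_model(beam = dev$beam, membrane = dev$membrane)
  expect_equal(nrow(model$ties), nrow(sut))
})

test_that("zero pre-stress ratio leaves rings at nominal diameter", {
  spec <- device_preset("desk")
  spec$prestress_ratio <- 0
  dev <- make_device(spec)
  expect_rel_equal(measure_diameter(dev$beam, 1), 24, 1e-3)
})

test_that("overlapping rings are rejected", {
  D <- 24
  rs <- function(kind) ring_spec(kind, nominal_diameter = D,
                                 target_element_size = 2)
  expect_error(device_spec(list(
    list(spec = rs("peaks8"), position = 30),
    list(spec = rs("peaks5"), position = 28)),
    graft_diameter = D, graft_length = 40), "overlap")
})
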