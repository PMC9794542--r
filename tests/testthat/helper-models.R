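# small mesh builders used across tests

straight_beam_mesh <- function(n_el = 20, L = 20, r = 0.25) {
  nodes <- cbind(seq(0, L, length.out = n_el + 1), 0, 0)
  structure(list(nodes = nodes,
                 elements = cbind(seq_len(n_el), seq_len(n_el) + 1L),
                 section_radius = rep(r, n_el),
                 part = rep(1L, n_el),
                 ring_id = rep(1L, n_el),
                 node_ring = rep(1L, n_el + 1),
                 rings = list(list(spec = NULL, nodes = seq_len(n_el + 1),
                                   apex_prox = integer(0),
                                   apex_dist = integer(0)))),
            class = "beam_mesh")
}

unit_square_membrane <- function(thickness = 0.1) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  structure(list(nodes = nodes,
                 triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                 thickness = thickness, suture_map = NULL),
            class = "membrane_mesh")
}

# two parallel 3-element strips closer than the wire diameter
parallel_strips_mesh <- function(gap = 0.4, r = 0.25) {
  nodes <- rbind(cbind(0:3, 0, 0), cbind(0:3, gap, 0))
  structure(list(nodes = nodes,
                 elements = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L),
                                  c(5L, 6L), c(6L, 7L), c(7L, 8L)),
                 section_radius = rep(r, 6), part = rep(1L, 6),
                 ring_id = rep(1L, 6), node_ring = rep(1L, 8),
                 rings = list(list(spec = NULL, nodes = 1:8,
                                   apex_prox = integer(0),
                                   apex_dist = integer(0)))),
            class = "beam_mesh")
}

# reduced device for protocol tests: three rings, coarse meshes
tiny_device <- function(prestress_ratio = 0.17) {
  D <- 20; pr <- prestress_ratio
  h8 <- crown_height_auto("peaks8", D * (1 + pr))
  h5 <- crown_height_auto("peaks5", D * (1 + pr))
  rs <- function(kind, size = 3)
    ring_spec(kind, nominal_diameter = D,
              crown_height = crown_height_auto(kind, D * (1 + pr)),
              target_element_size = size)
  rings <- list(
    list(spec = rs("peaks8"), position = 40 - h8 / 2),
    list(spec = rs("thin"), position = 40 - h8 - 2),
    list(spec = rs("peaks5"), position = h5 / 2 + 2))
  make_device(device_spec(rings, graft_diameter = D, graft_length = 40,
                          configuration = "FreeFlo", prestress_ratio = pr,
                          graft_element_size = 4))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
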