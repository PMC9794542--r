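#' Stent ring specification
#'
#' A stent ring is a closed Nitinol wire: peaks rings are sinusoidal
#' zig-zags on a cylinder, `z(theta) = (crown_height/2) * cos(n_peaks *
#' theta)`; the thin proximal ring is a plane circle.
#'
#' @param kind `"peaks8"`, `"peaks5"` or `"thin"`
#' @param nominal_diameter diameter of the cylinder the wire is sampled
#'   on (mm); for standalone rings this is the stress-free diameter,
#'   inside a device it is the sutured diameter
#' @param crown_height peak-to-valley axial height (mm); `NULL` picks the
#'   default height for the kind, scaled with diameter (see
#'   [crown_height_auto()])
#' @param wire_diameter wire cross-section diameter (mm)
#' @param n_peaks number of peaks (8 or 5 for peaks rings)
#' @param target_element_size beam element size (mm)
#' @return object of class `ring_spec`
#' @export
ring_spec <- function(kind = c("peaks8", "peaks5", "thin"),
                      nominal_diameter, crown_height = NULL,
                      wire_diameter = NULL, n_peaks = NULL,
                      target_element_size = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(nominal_diameter) || nominal_diameter <= 0)
    stop("nominal_diameter must be positive")
  if (target_element_size <= 0) stop("target_element_size must be positive")
  if (is.null(n_peaks)) n_peaks <- switch(kind, peaks8 = 8, peaks5 = 5, thin = 0L)
  if (kind != "thin" && !n_peaks %in% c(5, 8))
    stop("n_peaks must be 5 or 8 for peaks rings")
  if (is.null(wire_diameter))
    wire_diameter <- if (kind == "thin") 0.2 else 0.5
  if (wire_diameter <= 0) stop("wire_diameter must be positive")
  if (is.null(crown_height))
    crown_height <- crown_height_auto(kind, nominal_diameter)
  if (kind != "thin" && crown_height >= nominal_diameter)
    stop("crown_height must be below nominal_diameter")
  structure(list(kind = kind, nominal_diameter = nominal_diameter,
                 crown_height = crown_height, wire_diameter = wire_diameter,
                 n_peaks = n_peaks, target_element_size = target_element_size),
            class = "ring_spec")
}

#' Analytic wire length of a ring centerline
#'
#' @param D cylinder diameter (mm)
#' @param h crown height (mm, 0 for a circle)
#' @param n_peaks number of peaks
#' @return length (mm)
#' @export
ring_wire_length <- function(D, h, n_peaks) {
  R <- D / 2
  if (n_peaks == 0 || h == 0) return(pi * D)
  a <- h * n_peaks / 2
  th <- seq(0, 2 * pi, length.out = 4001)
  f <- sqrt(R^2 + (a * sin(n_peaks * th))^2)
  sum((f[-1] + f[-length(f)]) / 2) * diff(th[1:2])
}

# Reference crown heights are fixed, once, by requiring that the 8- and
# 5-peaks rings meshed at the device-A stress-free diameter
# (30 mm x 1.17 = 35.1 mm) have wire lengths of 240 mm and 160 mm, the
# converged mesh counts at 1 mm elements; heights scale linearly with
# the meshed diameter for other sizes.
.crown_ref <- local({
  solve_h <- function(L, D, n) {
    stats::uniroot(function(h) ring_wire_length(D, h, n) - L,
                   c(1e-3, D), tol = 1e-10)$root
  }
  list(D = 35.1,
       peaks8 = function() solve_h(240, 35.1, 8),
       peaks5 = function() solve_h(160, 35.1, 5))
})
.crown_cache <- new.env(parent = emptyenv())

#' Default crown height for a ring kind at a given diameter
#' @param kind ring kind
#' @param D meshed diameter (mm)
#' @return crown height (mm)
#' @export
crown_height_auto <- function(kind, D) {
  if (kind == "thin") return(0)
  key <- kind
  if (is.null(.crown_cache[[key]]))
    .crown_cache[[key]] <- .crown_ref[[kind]]()
  .crown_cache[[key]] * D / .crown_ref$D
}

#' Generate the beam mesh of a single stent ring
#'
#' Samples the ring centerline at uniform angular increments. The
#' element count is `round(wire length / target size)` rounded to a
#' multiple of `2 * n_peaks` for peaks rings so that every apex falls on
#' a node.
#'
#' @param spec a [ring_spec()]
#' @param axial_position z-coordinate of the ring mid-plane (mm)
#' @param diameter optional override of the meshed diameter (mm); crown
#'   height is kept as in the spec
#' @return object of class `beam_mesh` with fields `nodes` (n x 3),
#'   `elements` (m x 2), `section_radius`, `part`, `ring_id` per
#'   element, `node_ring` per node, and per-ring metadata in `rings`
#' @export
make_ring <- function(spec, axial_position = 0, diameter = NULL) {
  stopifnot(inherits(spec, "ring_spec"))
  D <- if (is.null(diameter)) spec$nominal_diameter else diameter
  if (D <= 0) stop("diameter must be positive")
  h <- spec$crown_height
  n <- spec$n_peaks
  L <- ring_wire_length(D, h, n)
  n_el <- round(L / spec$target_element_size)
  if (spec$kind != "thin") {
    n_el <- max(2 * n, round(n_el / (2 * n)) * 2 * n)
  } else {
    n_el <- max(8, n_el)
  }
  th <- seq(0, 2 * pi, length.out = n_el + 1)[-(n_el + 1)]
  R <- D / 2
  # thin rings carry a small harmonic out-of-plane imperfection
  # (0.2 percent of the diameter) that seeds the physical buckling mode
  # under radial compression; perfect circles would instead build up
  # axial strain until the solver aborts
  z <- if (spec$kind == "thin") 0.002 * D * cos(8 * th)
       else (h / 2) * cos(n * th)
  nodes <- cbind(R * cos(th), R * sin(th), z + axial_position)
  elements <- cbind(seq_len(n_el), c(seq_len(n_el)[-1], 1L))
  apex_prox <- if (spec$kind == "thin") integer(0) else
    1L + (0:(n - 1)) * (n_el / n)
  apex_dist <- if (spec$kind == "thin") integer(0) else
    1L + (n_el / (2 * n)) + (0:(n - 1)) * (n_el / n)
  structure(list(
    nodes = nodes,
    elements = elements,
    section_radius = rep(spec$wire_diameter / 2, n_el),
    part = rep(1L, n_el),
    ring_id = rep(1L, n_el),
    node_ring = rep(1L, n_el),
    rings = list(list(spec = spec, axial_position = axial_position,
                      meshed_diameter = D, nodes = seq_len(n_el),
                      apex_prox = apex_prox, apex_dist = apex_dist))),
    class = "beam_mesh")
}

#' Length-preserving radial fold of a ring wire
#'
#' Maps ring nodes to a smaller (or equal) diameter about the device
#' axis while conserving every wire segment's length: in-plane
#' coordinates scale by `lambda`, axial increments are recomputed
#' (legs rotate toward the axis, crowns lengthen), mirroring how a
#' sutured or crimped zig-zag ring actually folds.
#'
#' @param x n x 3 ring node coordinates (device axis = z through x=y=0)
#' @param lambda radial scale factor in (0, 1]
#' @param n_waves number of out-of-plane half-wave pairs a plane circle
#'   buckles into when folded
#' @return n x 3 folded coordinates
#' @export
fold_ring_nodes <- function(x, lambda, n_waves = 8) {
  if (lambda >= 1) return(x)
  m <- nrow(x)
  nxt <- c(2:m, 1)
  dxy <- x[nxt, 1:2, drop = FALSE] - x[, 1:2, drop = FALSE]
  dz <- x[nxt, 3] - x[, 3]
  L <- sqrt(rowSums(dxy^2) + dz^2)
  dxy2 <- dxy * lambda
  h2 <- pmax(L^2 - rowSums(dxy2^2), 0)
  sgn <- sign(dz)
  if (max(abs(dz)) < 1e-9 * max(L)) {
    # plane circle: fold into n_waves out-of-plane half-waves so the
    # wire length is conserved (a compressed circle must buckle)
    sgn <- sign(cos(2 * pi * n_waves * (seq_len(m) - 0.5) / m))
    sgn[sgn == 0] <- 1
  }
  dz2 <- sgn * sqrt(h2)
  dz2 <- dz2 - mean(dz2)            # enforce closure of the loop
  z2 <- cumsum(c(0, dz2[-m]))
  z2 <- z2 - mean(z2) + mean(x[, 3])
  cbind(x[, 1:2, drop = FALSE] * lambda, z2)
}

bind_beam_meshes <- function(meshes) {
  off <- 0L; rid <- 0L
  nodes <- NULL; elements <- NULL; srad <- NULL; part <- NULL
  ring_id <- NULL; node_ring <- NULL; rings <- list()
  for (m in meshes) {
    rid <- rid + 1L
    nodes <- rbind(nodes, m$nodes)
    elements <- rbind(elements, m$elements + off)
    srad <- c(srad, m$section_radius)
    part <- c(part, m$part)
    ring_id <- c(ring_id, rep(rid, nrow(m$elements)))
    node_ring <- c(node_ring, rep(rid, nrow(m$nodes)))
    r <- m$rings[[1]]
    r$nodes <- r$nodes + off
    r$apex_prox <- r$apex_prox + off
    r$apex_dist <- r$apex_dist + off
    rings[[rid]] <- r
    off <- off + nrow(m$nodes)
  }
  structure(list(nodes = nodes, elements = elements, section_radius = srad,
                 part = part, ring_id = ring_id, node_ring = node_ring,
                 rings = rings), class = "beam_mesh")
}

#' Stent-graft device specification
#'
#' @param rings list of entries `list(spec = ring_spec, position = z mm)`
#'   ordered proximal (high z) to distal; ring specs carry the *sutured*
#'   diameter, meshing happens at the stress-free diameter
#' @param graft_diameter graft cylinder diameter (mm)
#' @param graft_length graft length (mm)
#' @param graft_thickness membrane thickness (mm)
#' @param configuration `"FreeFlo"` (bare proximal peaks ring) or
#'   `"ClosedWeb"`
#' @param prestress_ratio stress-free diameter = sutured x
#'   `(1 + prestress_ratio)`
#' @param graft_element_size membrane target element size (mm)
#' @return object of class `device_spec`
#' @export
device_spec <- function(rings, graft_diameter, graft_length,
                        graft_thickness = 0.1,
                        configuration = c("FreeFlo", "ClosedWeb"),
                        prestress_ratio = 0.17,
                        graft_element_size = 1) {
  configuration <- match.arg(configuration)
  stopifnot(graft_length > 0, graft_diameter > 0, prestress_ratio >= 0)
  pos <- vapply(rings, `[[`, numeric(1), "position")
  if (is.unsorted(rev(pos), strictly = TRUE))
    stop("rings must be ordered proximal (high z) to distal")
  # overlapping rings (axial spans at meshed crowns) are invalid
  spans <- t(vapply(rings, function(r) {
    h <- r$spec$crown_height * (1 + prestress_ratio)
    c(r$position - h / 2, r$position + h / 2)
  }, numeric(2)))
  if (length(rings) > 1) {
    for (i in seq_len(length(rings) - 1))
      if (spans[i + 1, 2] > spans[i, 1] && rings[[i + 1]]$spec$kind != "thin" &&
          rings[[i]]$spec$kind != "thin")
        stop("overlapping rings in device specification")
  }
  structure(list(rings = rings, graft_diameter = graft_diameter,
                 graft_length = graft_length, graft_thickness = graft_thickness,
                 configuration = configuration, prestress_ratio = prestress_ratio,
                 graft_element_size = graft_element_size),
            class = "device_spec")
}

#' Assemble the beam and membrane meshes of a device
#'
#' Rings are meshed at their stress-free diameter (sutured diameter
#' times `1 + prestress_ratio`) and placed at their axial positions; the
#' graft cylinder is meshed at the sutured diameter. The suture map
#' pairs graft nodes with ring apex nodes (all nodes, for the thin
#' ring); graft nodes are snapped so that pairs coincide exactly once the
#' rings are mapped radially to the sutured diameter. For `FreeFlo`
#' devices the proximal peaks ring stays bare.
#'
#' @param spec a [device_spec()]
#' @return list with `beam` (class `beam_mesh`) and `membrane` (class
#'   `membrane_mesh` with `nodes`, `triangles`, `thickness`,
#'   `suture_map`)
#' @export
make_device <- function(spec) {
  stopifnot(inherits(spec, "device_spec"))
  pr <- spec$prestress_ratio
  Dg <- spec$graft_diameter
  # graft grid
  es <- spec$graft_element_size
  n_circ <- max(8, 2 * round(pi * Dg / es / 2))
  n_ax <- max(2, round(spec$graft_length / es))
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  zz <- seq(0, spec$graft_length, length.out = n_ax + 1)
  gn <- as.matrix(expand.grid(i = seq_len(n_circ), j = seq_len(n_ax + 1)))
  gnodes <- cbind(Dg / 2 * cos(th[gn[, 1]]), Dg / 2 * sin(th[gn[, 1]]),
                  zz[gn[, 2]])
  idx <- function(i, j) (j - 1L) * n_circ + i   # 1-based grid indexing
  gi <- rep(seq_len(n_circ), n_ax)
  gj <- rep(seq_len(n_ax), each = n_circ)
  i2 <- ifelse(gi == n_circ, 1L, gi + 1L)
  a <- idx(gi, gj); b <- idx(i2, gj); c2 <- idx(i2, gj + 1L); d <- idx(gi, gj + 1L)
  alt <- (gi + gj) %% 2 == 0     # alternate the quad diagonal
  tris <- rbind(cbind(a, b, ifelse(alt, c2, d)),
                cbind(ifelse(alt, a, b), c2, d))
  tris <- tris[c(rbind(seq_along(a), seq_along(a) + length(a))), , drop = FALSE]
  dimnames(tris) <- NULL
  # ring meshes at stress-free diameter; thin ring element count matched
  # to the graft circumferential count so sutures are one-to-one
  ring_meshes <- lapply(spec$rings, function(r) {
    s <- r$spec
    if (s$kind == "thin") {
      L <- pi * s$nominal_diameter * (1 + pr)
      s$target_element_size <- L / n_circ
    }
    make_ring(s, axial_position = r$position,
              diameter = s$nominal_diameter * (1 + pr))
  })
  beam <- bind_beam_meshes(ring_meshes)
  # suture map: pairs (graft node, stent node); the Free-Flo bare ring
  # is uncovered but still sewn at its distal apexes to the graft edge
  bare <- rep(FALSE, length(spec$rings))
  if (spec$configuration == "FreeFlo") {
    first_peaks <- which(vapply(spec$rings, function(r) r$spec$kind != "thin",
                                logical(1)))[1]
    bare[first_peaks] <- TRUE
  }
  suture <- NULL
  used <- logical(nrow(gnodes))
  for (k in seq_along(beam$rings)) {
    r <- beam$rings[[k]]
    if (r$spec$kind == "thin") snodes <- r$nodes
    else if (bare[k]) snodes <- r$apex_dist
    else snodes <- c(r$apex_prox, r$apex_dist)
    folded <- fold_ring_nodes(beam$nodes[r$nodes, , drop = FALSE],
                              1 / (1 + pr))
    for (sn in snodes) {
      # sutured position: length-preserving fold to the graft diameter
      tgt <- folded[match(sn, r$nodes), ]
      d2 <- (gnodes[, 1] - tgt[1])^2 + (gnodes[, 2] - tgt[2])^2 +
            (gnodes[, 3] - tgt[3])^2
      d2[used] <- Inf                # one suture per graft node
      g <- which.min(d2)
      if (!is.finite(d2[g])) next
      gnodes[g, ] <- tgt   # snap graft node onto the sutured apex position
      used[g] <- TRUE
      suture <- rbind(suture, c(g, sn))
    }
  }
  if (!is.null(suture)) colnames(suture) <- c("graft_node", "stent_node")
  membrane <- structure(list(nodes = gnodes, triangles = tris,
                             thickness = spec$graft_thickness,
                             suture_map = suture,
                             n_circ = n_circ, n_ax = n_ax),
                        class = "membrane_mesh")
  list(beam = beam, membrane = membrane, spec = spec)
}

#' Mean-radius diameter of a ring
#'
#' Twice the mean in-plane distance of the ring nodes from the best-fit
#' ring axis (principal-component normal of the node cloud).
#'
#' @param mesh a `beam_mesh` or an n x 3 node matrix
#' @param ring_id ring index (ignored when `mesh` is a plain matrix)
#' @param axis optional fixed ring axis (length-3); by default the
#'   best-fit axis (smallest principal component of the node cloud) is
#'   used, which is appropriate for open rings but not for heavily
#'   crimped ones
#' @return diameter (mm)
#' @export
measure_diameter <- function(mesh, ring_id = 1, axis = NULL) {
  if (inherits(mesh, "beam_mesh")) {
    if (ring_id > length(mesh$rings)) stop("no such ring")
    nodes <- mesh$nodes[mesh$rings[[ring_id]]$nodes, , drop = FALSE]
  } else nodes <- mesh
  if (is.null(nodes) || nrow(nodes) == 0) stop("empty ring")
  ctr <- colMeans(nodes)
  X <- sweep(nodes, 2, ctr)
  ax <- if (is.null(axis)) svd(X, nu = 0, nv = 3)$v[, 3]
        else axis / sqrt(sum(axis^2))
  inplane <- X - outer(as.numeric(X %*% ax), ax)
  2 * mean(sqrt(rowSums(inplane^2)))
}

#' Device presets
#'
#' `"A"` (30 x 30 x 150 Closed-Web), `"B"` (46 x 46 x 150 Free-Flo) and
#' `"C"` (34 x 34 x 200 Free-Flo) follow the commercial size chart;
#' `"desk"` is a reduced five-ring device (24 mm x 60 mm Free-Flo) meant
#' for fast deployment simulations.
#'
#' @param name preset name
#' @param graft_element_size membrane element size (mm); defaults to 1
#'   for the full devices and 2.5 for `"desk"`
#' @param ring_element_size beam element size (mm)
#' @return a [device_spec()]
#' @export
device_preset <- function(name = c("A", "B", "C", "desk"),
                          graft_element_size = NULL,
                          ring_element_size = NULL) {
  name <- match.arg(name)
  par <- switch(name,
    A = list(D = 30, L = 150, conf = "ClosedWeb", n5 = 7),
    B = list(D = 46, L = 150, conf = "FreeFlo", n5 = 7),
    C = list(D = 34, L = 200, conf = "FreeFlo", n5 = 9),
    desk = list(D = 24, L = 60, conf = "FreeFlo", n5 = 3))
  if (is.null(graft_element_size))
    graft_element_size <- if (name == "desk") 2.5 else 1
  if (is.null(ring_element_size))
    ring_element_size <- if (name == "desk") 2 else 1
  D <- par$D
  pr <- 0.17
  h8 <- crown_height_auto("peaks8", D * (1 + pr))
  h5 <- crown_height_auto("peaks5", D * (1 + pr))
  # crown heights belong to the stress-free (meshed) configuration
  rs <- function(kind, size) ring_spec(kind, nominal_diameter = D,
                                       crown_height = crown_height_auto(kind, D * (1 + pr)),
                                       target_element_size = size)
  rings <- list(list(spec = rs("peaks8", ring_element_size),
                     position = par$L - h8 / 2))
  z_thin <- par$L - h8 - 2
  rings <- c(rings, list(list(spec = rs("thin", ring_element_size),
                              position = z_thin)))
  z_top <- z_thin - 2 - h5 / 2
  z_bot <- h5 / 2
  zpos <- seq(z_top, z_bot, length.out = par$n5)
  for (z in zpos)
    rings <- c(rings, list(list(spec = rs("peaks5", ring_element_size),
                                position = z)))
  device_spec(rings, graft_diameter = D, graft_length = par$L,
              configuration = par$conf, prestress_ratio = pr,
              graft_element_size = graft_element_size)
}

#' Ring presets for the standalone crimp experiments
#'
#' Standalone ring specs carry the *stress-free* diameter (the sutured
#' diameter of the parent device times 1.17, as measured after removing
#' the sutures).
#'
#' @param name one of `"deviceA_8peaks"`, `"deviceA_5peaks"`,
#'   `"deviceB_8peaks"`, `"thin34"`
#' @param target_element_size beam element size (mm)
#' @return a [ring_spec()]
#' @export
ring_preset <- function(name = c("deviceA_8peaks", "deviceA_5peaks",
                                 "deviceB_8peaks", "thin34"),
                        target_element_size = 1) {
  name <- match.arg(name)
  switch(name,
    deviceA_8peaks = ring_spec("peaks8", nominal_diameter = 30 * 1.17,
                               target_element_size = target_element_size),
    deviceA_5peaks = ring_spec("peaks5", nominal_diameter = 30 * 1.17,
                               target_element_size = target_element_size),
    deviceB_8peaks = ring_spec("peaks8", nominal_diameter = 46 * 1.17,
                               target_element_size = target_element_size),
    thin34 = ring_spec("thin", nominal_diameter = 34,
                       target_element_size = target_element_size))
}
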