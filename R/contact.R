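#' Rigid contact surfaces
#'
#' Analytic rigid surfaces for penalty contact: planes (crimper jaws)
#' and tubes around a centerline polyline (crimping catheter, delivery
#' sheath, vessel). Tubes are inner surfaces: nodes are confined to
#' radius <= R, optionally only inside an active arc-length window
#' (sheath retraction moves the window).
#'
#' @param point,normal plane point and unit normal (normal points to
#'   the allowed side)
#' @param point_to optional end position of the plane point (prescribed
#'   motion over a phase)
#' @param mu Coulomb friction coefficient
#' @param k_scale multiplier on the automatic penalty stiffness
#'   (`0.1 m / dt^2` per node)
#' @return a surface list understood by the solver phases
#' @export
rigid_plane <- function(point, normal, point_to = point, mu = 0, k_scale = 1) {
  normal <- normal / sqrt(sum(normal^2))
  list(kind = "plane", normal = normal, point_from = as.numeric(point),
       point_to = as.numeric(point_to), mu = mu, k_scale = k_scale)
}

#' @rdname rigid_plane
#' @param centerline k x 3 polyline points (mm)
#' @param centerline_to optional morph target polyline (same row count):
#'   the tube centerline moves from `centerline` to `centerline_to` over
#'   the phase (the virtual-catheter crimp-and-morph)
#' @param radius,radius_to tube radius at phase start/end (mm)
#' @param window,window_to active arc-length interval at start/end (mm)
#' @export
rigid_tube <- function(centerline, radius, radius_to = radius,
                       window = c(-Inf, Inf), window_to = window,
                       mu = 0, k_scale = 1, centerline_to = NULL) {
  stopifnot(radius > 0, radius_to > 0)
  if (!is.null(centerline_to))
    stopifnot(nrow(centerline_to) == nrow(centerline))
  big <- 1e9
  window <- pmin(pmax(window, -big), big)
  window_to <- pmin(pmax(window_to, -big), big)
  list(kind = "tube", centerline = as.matrix(centerline),
       centerline_to = if (is.null(centerline_to)) NULL
                       else as.matrix(centerline_to),
       radius_from = radius, radius_to = radius_to,
       window_from = window, window_to = window_to,
       mu = mu, k_scale = k_scale)
}

#' Twelve-plane crimper
#'
#' Planes tangent to the commanded cylinder at 30 degree increments,
#' normals pointing to the device axis, translating radially from
#' `diameter_from` to `diameter_to` over a phase.
#'
#' @param diameter_from,diameter_to commanded crimper diameter (mm)
#' @param mu friction coefficient (0.3 stent-plane by default)
#' @param n_planes number of planes
#' @return list of [rigid_plane()] surfaces
#' @export
crimper_planes <- function(diameter_from, diameter_to = diameter_from,
                           mu = 0.3, n_planes = 12L) {
  th <- (seq_len(n_planes) - 1) * 2 * pi / n_planes
  lapply(th, function(a) {
    u <- c(cos(a), sin(a), 0)
    rigid_plane(point = u * diameter_from / 2, normal = -u,
                point_to = u * diameter_to / 2, mu = mu)
  })
}

#' Evaluate contact of nodes against one rigid surface
#'
#' Penalty normal force `k * penetration` along the surface normal
#' (frictionless single evaluation; the stick-slip tangential model
#' lives in the time stepper).
#'
#' @param nodes n x 3 coordinates
#' @param surface [rigid_plane()] or [rigid_tube()] (start position used)
#' @param k_pen penalty stiffness (N/mm)
#' @return list with nodal `forces` and a `record` data.frame (gap,
#'   normal force per node) plus the resultant normal force
#' @export
surface_contact <- function(nodes, surface, k_pen = 1000) {
  s <- if (surface$kind == "plane")
    list(kind = "plane", normal = surface$normal, point = surface$point_from)
  else
    list(kind = "tube", centerline = surface$centerline,
         radius = surface$radius_from)
  out <- contact_eval_cpp(as.matrix(nodes), s, k_pen)
  rec <- data.frame(node = seq_len(nrow(nodes)), gap = out$gap, fn = out$fn)
  list(forces = out$f, record = rec, resultant = sum(out$fn))
}

#' Total radial force from the twelve crimper planes
#'
#' @param plane_forces numeric vector of per-plane resultant normal
#'   forces (one per crimper plane)
#' @return sum of the twelve contributions (N)
#' @export
total_radial_force <- function(plane_forces) {
  if (length(plane_forces) != 12L)
    stop("the crimper radial force is defined as the sum over 12 planes")
  sum(plane_forces)
}

#' Minimum distance between non-adjacent stent wire segments
#'
#' @param nodes n x 3 current coordinates
#' @param elements m x 2 beam connectivity
#' @param skip how many neighbouring elements along the loop to ignore
#' @return minimum centerline-to-centerline distance (mm)
#' @export
min_strut_distance <- function(nodes, elements, skip = 2L) {
  min_strut_distance_cpp(as.matrix(nodes), as.matrix(elements), as.integer(skip))
}
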