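#' Extract the proximal apex set of a ring
#'
#' Finds the nodes at the local axial maxima of the ring wire (one per
#' peak) in the deployed configuration; for the thin circular ring a
#' uniform 16-point subsample of the wire is returned.
#'
#' @param devstate a `device_state` (or any list with `x` coordinates
#'   and a `beam` beam_mesh)
#' @param ring_id ring index
#' @return object of class `ring_apex_set`: list with `ring_id`,
#'   `points` (ordered by angle about the best-fit axis), `source`
#' @export
extract_apexes <- function(devstate, ring_id) {
  beam <- devstate$beam
  if (ring_id > length(beam$rings)) stop("no such ring")
  ring <- beam$rings[[ring_id]]
  pts <- devstate$x[ring$nodes, , drop = FALSE]
  m <- nrow(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  ax <- sv$v[, 3]
  # orient axis toward the device proximal direction (+z reference)
  if (sum(ax * c(0, 0, 1)) < 0) ax <- -ax
  z <- as.numeric(X %*% ax)
  n_pk <- ring$spec$n_peaks
  if (is.null(n_pk) || n_pk == 0) {
    idx <- round(seq(1, m + 1, length.out = 17))[-17]
    sel <- ((idx - 1) %% m) + 1
  } else {
    # local maxima of the axial coordinate along the closed wire
    prv <- c(m, 1:(m - 1)); nxt <- c(2:m, 1)
    is_max <- z >= z[prv] & z >= z[nxt]
    sel <- which(is_max)
    # suppress plateaus / duplicates: keep the highest point per cluster
    if (length(sel) != n_pk) {
      # fall back to the nearest-extrema selection: one apex per
      # angular sector of width 2*pi/n_peaks
      warning("expected ", n_pk, " apexes, found ", length(sel),
              "; using per-sector maxima")
      ang <- atan2(X %*% sv$v[, 2], X %*% sv$v[, 1])
      sector <- floor((ang + pi) / (2 * pi / n_pk))
      sector[sector >= n_pk] <- n_pk - 1
      sel <- vapply(split(seq_len(m), sector),
                    function(i) i[which.max(z[i])], integer(1))
    }
  }
  pts_sel <- pts[sel, , drop = FALSE]
  # order by angle in the best-fit plane
  Xs <- sweep(pts_sel, 2, ctr)
  ang <- atan2(as.numeric(Xs %*% sv$v[, 2]), as.numeric(Xs %*% sv$v[, 1]))
  o <- order(ang)
  structure(list(ring_id = ring_id, points = pts_sel[o, , drop = FALSE],
                 source = "simulation"),
            class = "ring_apex_set")
}

#' Opening area enclosed by a periodic spline through ring apexes
#'
#' Apex points are projected onto their best-fit plane (principal
#' components), a periodic cubic spline is fit through them
#' (chord-length parametrised), resampled at 1000 points, and the
#' enclosed area evaluated by the shoelace form of Green's theorem.
#'
#' @param apexes a `ring_apex_set` or an n x 3 point matrix (n >= 4)
#' @param n_resample spline resampling density
#' @return area (mm^2)
#' @export
opening_area <- function(apexes, n_resample = 1000) {
  pts <- if (inherits(apexes, "ring_apex_set")) apexes$points else as.matrix(apexes)
  if (nrow(pts) < 4) stop("need at least 4 apex points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  u <- as.numeric(X %*% sv$v[, 1])
  v <- as.numeric(X %*% sv$v[, 2])
  o <- order(atan2(v, u))
  u <- u[o]; v <- v[o]
  # closed chord-length parametrisation
  uu <- c(u, u[1]); vv <- c(v, v[1])
  tpar <- cumsum(c(0, sqrt(diff(uu)^2 + diff(vv)^2)))
  if (tpar[length(tpar)] <= 0) stop("degenerate apex set")
  tg <- seq(0, tpar[length(tpar)], length.out = n_resample + 1)
  us <- spline(tpar, uu, xout = tg, method = "periodic")$y
  vs <- spline(tpar, vv, xout = tg, method = "periodic")$y
  area <- 0.5 * abs(sum(us[-length(us)] * vs[-1] - us[-1] * vs[-length(vs)]))
  # reject self-intersecting contours: spline area should not collapse
  poly <- 0.5 * abs(sum(u * c(v[-1], v[1]) - c(u[-1], u[1]) * v))
  if (area < 0.2 * poly) stop("self-intersecting apex spline")
  area
}

#' Opening-area percentage error between simulation and reference
#'
#' @param sim,ref lists of `ring_apex_set`s (or n x 3 matrices), same
#'   ring order, or numeric vectors of precomputed areas
#' @return object of class `oa_result`: data.frame of per-ring areas
#'   and absolute percent errors, with summary statistics (mean, sd,
#'   min, max) in `attr(, "summary")`
#' @export
oa_percent_error <- function(sim, ref) {
  a_sim <- if (is.numeric(sim)) sim else vapply(sim, opening_area, numeric(1))
  a_ref <- if (is.numeric(ref)) ref else vapply(ref, opening_area, numeric(1))
  if (length(a_sim) != length(a_ref)) stop("ring sets do not match")
  err <- abs(a_sim - a_ref) / a_ref * 100
  out <- data.frame(ring = seq_along(a_sim), area_sim = a_sim,
                    area_ref = a_ref, percent_error = err)
  attr(out, "summary") <- c(mean = mean(err), sd = stats::sd(err),
                            min = min(err), max = max(err))
  class(out) <- c("oa_result", "data.frame")
  out
}

#' @export
print.oa_result <- function(x, ...) {
  s <- attr(x, "summary")
  NextMethod()
  cat(sprintf("OA error: %.2f%% +/- %.2f%% [%.2f%%; %.2f%%]\n",
              s["mean"], s["sd"], s["min"], s["max"]))
  invisible(x)
}

#' Maximum strut distance between two polylines
#'
#' One-sided Hausdorff distance: the maximum over vertices of the
#' simulated strut of the minimum distance to the reference polyline's
#' segments.
#'
#' @param sim n x 3 vertex matrix (simulated strut)
#' @param ref m x 3 vertex matrix (reference strut), treated as an open
#'   polyline
#' @return distance (mm)
#' @export
max_strut_distance <- function(sim, ref) {
  sim <- as.matrix(sim); ref <- as.matrix(ref)
  if (nrow(sim) == 0 || nrow(ref) == 0) stop("empty polyline")
  if (nrow(ref) == 1)
    return(max(sqrt(rowSums(sweep(sim, 2, ref[1, ])^2))))
  a <- ref[-nrow(ref), , drop = FALSE]
  b <- ref[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  dmin <- vapply(seq_len(nrow(sim)), function(i) {
    p <- sim[i, ]
    ap <- sweep(a, 2, p, "-")
    t <- pmin(1, pmax(0, -rowSums(ap * ab) / pmax(len2, 1e-30)))
    dx <- a + ab * t
    min(sqrt(rowSums(sweep(dx, 2, p)^2)))
  }, numeric(1))
  max(dmin)
}

#' Deployed stent length along the vessel centerline
#'
#' Projects every stent node onto the centerline and returns the
#' arc-length extent between the most proximal and most distal node.
#'
#' @param devstate `device_state` (or list with `x`, `beam`)
#' @param centerline k x 3 polyline; a straight axis through the device
#'   is used when missing
#' @return length (mm)
#' @export
deployed_length <- function(devstate, centerline = NULL) {
  x <- devstate$x[seq_len(nrow(devstate$beam$nodes)), , drop = FALSE]
  if (is.null(centerline)) {
    zr <- range(x[, 3])
    centerline <- cbind(0, 0, seq(zr[1] - 1, zr[2] + 1, length.out = 2))
  }
  centerline <- as.matrix(centerline)
  a <- centerline[-nrow(centerline), , drop = FALSE]
  b <- centerline[-1, , drop = FALSE]
  ab <- b - a
  len <- sqrt(rowSums(ab^2))
  scum <- c(0, cumsum(len))
  s_node <- vapply(seq_len(nrow(x)), function(i) {
    p <- x[i, ]
    ap <- sweep(a, 2, p, "-")
    t <- pmin(1, pmax(0, -rowSums(ap * ab) / pmax(len^2, 1e-30)))
    d2 <- rowSums((a + ab * t - matrix(p, nrow(a), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    scum[j] + t[j] * len[j]
  }, numeric(1))
  max(s_node) - min(s_node)
}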