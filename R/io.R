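#' Read and write force-diameter curves as CSV
#'
#' Columns `diameter_mm`, `force_N`, `phase`; values round-trip at full
#' double precision.
#'
#' @param curve `force_diameter_curve` data.frame
#' @param path file path
#' @return the curve (invisibly for the writer)
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(diameter_mm = format(curve$diameter, digits = 17),
                   force_N = format(curve$force, digits = 17),
                   phase = curve$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(curve)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(diameter = as.numeric(df$diameter_mm),
                    force = as.numeric(df$force_N), phase = df$phase)
  class(out) <- c("force_diameter_curve", "data.frame")
  out
}

#' Read and write centerline / point-set CSV files
#'
#' Plain `x_mm, y_mm, z_mm` columns.
#'
#' @param points n x 3 matrix
#' @param path file path
#' @export
write_points_csv <- function(points, path) {
  df <- data.frame(x_mm = format(points[, 1], digits = 17),
                   y_mm = format(points[, 2], digits = 17),
                   z_mm = format(points[, 3], digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(points)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(cbind(as.numeric(df$x_mm), as.numeric(df$y_mm),
                  as.numeric(df$z_mm)))
}

#' Export meshes as legacy ASCII VTK
#'
#' Beam meshes become polylines, membrane meshes triangle polydata.
#'
#' @param mesh `beam_mesh` or `membrane_mesh`
#' @param path output `.vtk` path
#' @param coords optional deformed coordinates overriding the mesh's
#' @export
write_vtk <- function(mesh, path, coords = NULL) {
  pts <- if (is.null(coords)) mesh$nodes else coords
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tevarsim mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(pts), "double")), con)
  utils::write.table(format(pts, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (inherits(mesh, "beam_mesh")) {
    m <- nrow(mesh$elements)
    writeLines(paste("LINES", m, 3 * m), con)
    utils::write.table(cbind(2L, mesh$elements - 1L), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    k <- nrow(mesh$triangles)
    writeLines(paste("POLYGONS", k, 4 * k), con)
    utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a membrane mesh as ASCII STL
#'
#' @param mesh `membrane_mesh`
#' @param path output `.stl` path
#' @param coords optional deformed coordinates
#' @export
write_stl <- function(mesh, path, coords = NULL) {
  stopifnot(inherits(mesh, "membrane_mesh"))
  pts <- if (is.null(coords)) mesh$nodes else coords
  tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid tevarsim", con)
  for (i in seq_len(nrow(tr))) {
    a <- pts[tr[i, 1], ]; b <- pts[tr[i, 2], ]; c2 <- pts[tr[i, 3], ]
    n <- c((b[2]-a[2])*(c2[3]-a[3]) - (b[3]-a[3])*(c2[2]-a[2]),
           (b[3]-a[3])*(c2[1]-a[1]) - (b[1]-a[1])*(c2[3]-a[3]),
           (b[1]-a[1])*(c2[2]-a[2]) - (b[2]-a[2])*(c2[1]-a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", c2[1], c2[2], c2[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid tevarsim", con)
  invisible(path)
}

#' Read a triangle surface from ASCII STL
#'
#' Provides the triangle-mesh vessel route; vertices are merged within
#' a tolerance.
#'
#' @param path `.stl` file
#' @param tol vertex merge tolerance (mm)
#' @return `membrane_mesh`-shaped list with `nodes` and `triangles`
#' @export
read_stl <- function(path, tol = 1e-6) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(round(v / tol) * tol, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  nodes <- v[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  structure(list(nodes = nodes, triangles = tris, thickness = 0,
                 suture_map = NULL), class = "membrane_mesh")
}

#' Serialize/deserialize configurations as JSON
#'
#' Covers material parameter sets, ring and device specs and crimp
#' protocols; objects are tagged by a `type` field.
#'
#' @param x object to write
#' @param path JSON file path
#' @export
write_config_json <- function(x, path) {
  type <- class(x)[1]
  payload <- unclass(x)
  if (type == "device_spec") {
    payload$rings <- lapply(payload$rings, function(r)
      list(spec = unclass(r$spec), position = r$position))
  }
  jsonlite::write_json(list(type = type, value = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$value
  switch(obj$type,
    nitinol_params = do.call(nitinol_params, v),
    fabric_params = do.call(fabric_params, v),
    ring_spec = do.call(ring_spec, v),
    crimp_protocol = do.call(crimp_protocol, v),
    synth_config = do.call(synth_config, v),
    device_spec = {
      rings <- lapply(seq_len(nrow(v$rings)), function(i) {
        sp <- as.list(v$rings$spec[i, ])
        list(spec = do.call(ring_spec, sp), position = v$rings$position[i])
      })
      device_spec(rings, graft_diameter = v$graft_diameter,
                  graft_length = v$graft_length,
                  graft_thickness = v$graft_thickness,
                  configuration = v$configuration,
                  prestress_ratio = v$prestress_ratio,
                  graft_element_size = v$graft_element_size)
    },
    stop("unknown config type: ", obj$type))
}
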