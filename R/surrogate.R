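#' Crimp/release protocol
#'
#' @param start_diameter crimper diameter at which the protocol starts
#'   (mm); defaults used by the presets start just above the ring's
#'   free diameter
#' @param min_diameter smallest commanded diameter (5 mm for single
#'   rings, 10 mm for full devices)
#' @param release_to diameter the crimper opens back to
#' @param d_step diameter increment of the surrogate sweep (mm)
#' @param n_steps_load,n_steps_unload explicit-dynamics steps per phase
#'   for the full FE route
#' @return object of class `crimp_protocol`
#' @export
crimp_protocol <- function(start_diameter, min_diameter = 5,
                           release_to = start_diameter, d_step = 0.05,
                           n_steps_load = 70000L, n_steps_unload = 70000L) {
  stopifnot(min_diameter < start_diameter, min_diameter > 0,
            release_to > min_diameter)
  structure(list(start_diameter = start_diameter, min_diameter = min_diameter,
                 release_to = release_to, d_step = d_step,
                 n_steps_load = as.integer(n_steps_load),
                 n_steps_unload = as.integer(n_steps_unload)),
            class = "crimp_protocol")
}

.path_cache <- new.env(parent = emptyenv())

#' Freeze the kinematic path of a ring crimp
#'
#' Runs one full explicit-FE crimp/release of the ring and records the
#' fibre strain histories. The frozen path is the kinematic backbone of
#' the fast calibration surrogate: candidate material parameters are
#' evaluated by re-driving every fibre through these strain histories.
#' The path is computed at fixed reference parameters (the literature
#' preset by default) so the surrogate is a well-defined model
#' independent of the candidate parameters.
#'
#' @param spec [ring_spec()]
#' @param proto [crimp_protocol()]
#' @param path_params material used for the one-off path computation
#' @param cfg [solver_config()]
#' @return object of class `ring_crimp_path` with `d` (commanded
#'   diameters), `phase`, `eps` (records x fibres strain matrix),
#'   `vol` (fibre volumes, mm^3) and `force_fe` (the FE radial force)
#' @export
ring_crimp_path <- function(spec, proto,
                            path_params = nitinol_preset("kleinstreuer2008"),
                            cfg = solver_config(damping_stent = 500)) {
  curve <- run_crimp_release(make_ring(spec), proto, material = path_params,
                             cfg = cfg, record_fibres = TRUE,
                             relax_after = FALSE)
  structure(list(d = curve$diameter, phase = curve$phase,
                 eps = attr(curve, "fib_eps"), vol = attr(curve, "fib_vol"),
                 force_fe = curve$force),
            class = "ring_crimp_path")
}

.cached_path <- function(spec, proto, path_params, cfg) {
  key <- paste(collapse = "|", c(
    vapply(spec, function(v) paste(format(v, digits = 10), collapse = ","), ""),
    format(c(proto$start_diameter, proto$min_diameter, proto$release_to,
             proto$n_steps_load, proto$n_steps_unload), digits = 10),
    format(unlist(path_params), digits = 10)))
  if (is.null(.path_cache[[key]]))
    .path_cache[[key]] <- ring_crimp_path(spec, proto, path_params, cfg)
  .path_cache[[key]]
}

#' Reduced ring crimp surrogate
#'
#' Fast quasi-static radial-force model used inside the calibration
#' loop: fibre strain histories are taken from a frozen explicit-FE
#' kinematic path ([ring_crimp_path()]), every fibre is re-driven
#' through the history-dependent superelastic law at the candidate
#' parameters, and the radial force is recovered from work conjugacy
#' with the commanded crimper diameter. Milliseconds per evaluation
#' after the one-off path computation.
#'
#' @param spec [ring_spec()]
#' @param params candidate [nitinol_params()]
#' @param proto [crimp_protocol()]
#' @param path optional [ring_crimp_path()]; computed (and cached) at
#'   the literature preset when missing
#' @return data.frame of class `force_diameter_curve`
#' @export
ring_crimp_surrogate <- function(spec, params, proto, path = NULL) {
  stopifnot(inherits(spec, "ring_spec"), spec$kind != "thin")
  if (is.null(path))
    path <- .cached_path(spec, proto, nitinol_preset("kleinstreuer2008"),
                         solver_config(damping_stent = 500))
  sig <- sma_sweep_multi_cpp(path$eps, sma_param_vec(params))$sig
  nk <- length(path$d)
  dW <- (0.5 * (sig[-1, , drop = FALSE] + sig[-nk, , drop = FALSE]) *
           (path$eps[-1, , drop = FALSE] - path$eps[-nk, , drop = FALSE])) %*%
    path$vol
  W <- cumsum(c(0, dW))
  dd <- c(0, diff(path$d))
  # crimper planes move by dd/2: radial force is -2 dW/dd on both branches
  F_raw <- ifelse(abs(dd) > 1e-6, -2 * c(0, diff(W)) / dd, NA_real_)
  F_raw[F_raw < 0] <- 0
  curve <- data.frame(diameter = path$d, force = F_raw, phase = path$phase)
  # fill the hold/approach records by interpolation inside each phase
  for (ph in unique(curve$phase)) {
    i <- curve$phase == ph
    if (any(is.na(curve$force[i])) && sum(!is.na(curve$force[i])) >= 2) {
      curve$force[i] <- approx(seq_len(sum(i))[!is.na(curve$force[i])],
                               curve$force[i][!is.na(curve$force[i])],
                               seq_len(sum(i)), rule = 2)$y
    }
  }
  curve$force[is.na(curve$force)] <- 0
  class(curve) <- c("force_diameter_curve", "data.frame")
  curve
}

#' @export
print.force_diameter_curve <- function(x, ...) {
  cat("Force-diameter curve:", nrow(x), "samples,",
      "diameter", round(min(x$diameter), 2), "-", round(max(x$diameter), 2),
      "mm, peak force", round(max(x$force), 2), "N\n")
  invisible(x)
}

#' Plot a force-diameter curve
#'
#' @param x `force_diameter_curve`
#' @param ... passed to [graphics::plot()]
#' @export
plot_force_diameter <- function(x, ...) {
  ld <- x[x$phase == "loading", ]
  ul <- x[x$phase == "unloading", ]
  graphics::plot(ld$diameter, ld$force, type = "l", col = "firebrick",
                 xlab = "crimper diameter [mm]", ylab = "radial force [N]", ...)
  graphics::lines(ul$diameter, ul$force, col = "steelblue")
  graphics::legend("topright", c("loading", "unloading"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
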