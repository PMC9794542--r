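#' Calibration configuration
#'
#' @param free parameter names allowed to vary (subset of `E_A`, `E_M`,
#'   `sig_SL`, `sig_EL`, `sig_SU`, `sig_EU`)
#' @param start starting parameter set (literature preset by default)
#' @param working_range diameter interval (mm) the fit is evaluated on
#' @param n_grid resampling points per phase inside the working range
#' @param loss `"sse"` or `"mae"`
#' @param lower_scale,upper_scale multiplicative bounds around the
#'   starting values (applied in the transformed parameter space)
#' @return object of class `calibration_config`
#' @export
calibration_config <- function(free = c("E_A", "E_M", "sig_SL", "sig_EL",
                                        "sig_SU", "sig_EU"),
                               start = nitinol_preset("kleinstreuer2008"),
                               working_range = c(6, 30), n_grid = 50,
                               loss = c("sse", "mae"),
                               lower_scale = 0.4, upper_scale = 2.5) {
  loss <- match.arg(loss)
  free <- match.arg(free, c("E_A", "E_M", "sig_SL", "sig_EL",
                            "sig_SU", "sig_EU"), several.ok = TRUE)
  stopifnot(working_range[1] < working_range[2], n_grid >= 5,
            lower_scale < 1, upper_scale > 1)
  structure(list(free = free, start = start, working_range = working_range,
                 n_grid = n_grid, loss = loss,
                 lower_scale = lower_scale, upper_scale = upper_scale),
            class = "calibration_config")
}

# ordering-preserving transform: moduli and the lowest plateau stress as
# logs, plateau stresses as log-gaps so sig_EU < sig_SU < sig_SL < sig_EL
# holds structurally for any parameter vector the optimizer proposes
.nitinol_to_theta <- function(p) {
  c(lE_A = log(p$E_A), lE_M = log(p$E_M), l_sEU = log(p$sig_EU),
    l_d1 = log(p$sig_SU - p$sig_EU), l_d2 = log(p$sig_SL - p$sig_SU),
    l_d3 = log(p$sig_EL - p$sig_SL))
}
.theta_to_nitinol <- function(th, template) {
  sEU <- exp(th[["l_sEU"]])
  sSU <- sEU + exp(th[["l_d1"]])
  sSL <- sSU + exp(th[["l_d2"]])
  sEL <- sSL + exp(th[["l_d3"]])
  nitinol_params(E_A = exp(th[["lE_A"]]), E_M = exp(th[["lE_M"]]),
                 nu = template$nu, sig_SL = sSL, sig_EL = sEL,
                 sig_SU = sSU, sig_EU = sEU, eps_L = template$eps_L,
                 alpha = template$alpha)
}
.free_theta_names <- function(free) {
  map <- c(E_A = "lE_A", E_M = "lE_M", sig_EU = "l_sEU", sig_SU = "l_d1",
           sig_SL = "l_d2", sig_EL = "l_d3")
  unname(map[free])
}

.resample_curve <- function(curve, d_grid, phase) {
  sub <- curve[curve$phase == phase, ]
  if (nrow(sub) < 2) stop("curve has no ", phase, " samples")
  o <- order(sub$diameter)
  approx(sub$diameter[o], sub$force[o], d_grid, rule = 2, ties = mean)$y
}

#' Percentage error between two force-diameter curves
#'
#' Per phase, both curves are resampled on a uniform diameter grid
#' inside the working range and the relative force deviation
#' `|F_sim - F_ref| / F_ref * 100` is summarised as mean and standard
#' deviation across the grid.
#'
#' @param sim,ref `force_diameter_curve` data.frames (columns
#'   `diameter`, `force`, `phase`)
#' @param working_range diameter interval (mm)
#' @param n_grid grid size
#' @return data.frame with one row per phase: `mean`, `sd` (percent)
#' @export
curve_percent_error <- function(sim, ref, working_range, n_grid = 50) {
  lo <- max(working_range[1], min(sim$diameter), min(ref$diameter))
  hi <- min(working_range[2], max(sim$diameter), max(ref$diameter))
  if (!(lo < hi)) stop("curves do not overlap inside the working range")
  d_grid <- seq(lo, hi, length.out = n_grid)
  out <- lapply(c("loading", "unloading"), function(ph) {
    fs <- .resample_curve(sim, d_grid, ph)
    fr <- .resample_curve(ref, d_grid, ph)
    ok <- fr != 0
    e <- abs(fs[ok] - fr[ok]) / fr[ok] * 100
    data.frame(phase = ph, mean = mean(e), sd = stats::sd(e))
  })
  do.call(rbind, out)
}

#' Calibrate Nitinol parameters against force-diameter curves
#'
#' Bounded least squares (Levenberg-Marquardt) on a log/log-gap
#' reparametrisation of the superelastic parameters, with the ring
#' model re-run at every iterate. The default ring model is the fast
#' unit-cell surrogate; the full explicit-FE crimp can be plugged in
#' through `ring_model` for final verification.
#'
#' @param ref_curves list of `force_diameter_curve` data.frames (or a
#'   single one); each entry needs a matching entry in `specs`
#' @param specs list of [ring_spec()] matching `ref_curves`
#' @param proto [crimp_protocol()]
#' @param cfg [calibration_config()]
#' @param ring_model function `(spec, params, proto) -> curve`; defaults
#'   to [ring_crimp_surrogate()]
#' @return list with `params` (fitted [nitinol_params()]), `loss`,
#'   `loss_trace`, `iterations`, `errors` (per-phase working-range
#'   percent errors per curve), `bound_warnings`
#' @export
calibrate_nitinol <- function(ref_curves, specs, proto,
                              cfg = calibration_config(),
                              ring_model = ring_crimp_surrogate) {
  if (inherits(ref_curves, "force_diameter_curve")) ref_curves <- list(ref_curves)
  if (inherits(specs, "ring_spec")) specs <- list(specs)
  stopifnot(length(ref_curves) == length(specs))
  th0_all <- .nitinol_to_theta(cfg$start)
  free_th <- .free_theta_names(cfg$free)
  th0 <- th0_all[free_th]
  # plateau *gaps* vary over an order of magnitude across the
  # literature; give them wider multiplicative bounds than the moduli
  is_gap <- grepl("^l_d", free_th)
  lower <- th0 + ifelse(is_gap, log(cfg$lower_scale / 4), log(cfg$lower_scale))
  upper <- th0 + ifelse(is_gap, log(cfg$upper_scale * 4), log(cfg$upper_scale))
  d_grid <- seq(cfg$working_range[1], cfg$working_range[2],
                length.out = cfg$n_grid)
  ref_F <- lapply(ref_curves, function(cv)
    c(.resample_curve(cv, d_grid, "loading"),
      .resample_curve(cv, d_grid, "unloading")))
  resid_fn <- function(th_free) {
    th <- th0_all
    th[free_th] <- th_free
    p <- .theta_to_nitinol(th, cfg$start)
    res <- unlist(lapply(seq_along(specs), function(i) {
      cv <- ring_model(specs[[i]], p, proto)
      sim <- c(.resample_curve(cv, d_grid, "loading"),
               .resample_curve(cv, d_grid, "unloading"))
      sim - ref_F[[i]]
    }))
    if (any(!is.finite(res))) stop("non-finite calibration loss")
    if (cfg$loss == "mae") res <- sqrt(abs(res) + 1e-12)
    res
  }
  fit <- minpack.lm::nls.lm(par = th0, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-10))
  th <- th0_all
  th[free_th] <- fit$par
  p_fit <- .theta_to_nitinol(th, cfg$start)
  at_bound <- names(fit$par)[fit$par <= lower + 1e-9 | fit$par >= upper - 1e-9]
  errors <- lapply(seq_along(specs), function(i)
    curve_percent_error(ring_model(specs[[i]], p_fit, proto),
                        ref_curves[[i]], cfg$working_range, cfg$n_grid))
  list(params = p_fit, loss = fit$deviance, loss_trace = fit$rsstrace,
       iterations = fit$niter, errors = errors,
       bound_warnings = at_bound, converged = fit$info %in% 1:4)
}
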