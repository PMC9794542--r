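#' Superelastic Nitinol material parameters
#'
#' Parameter set for the one-dimensional superelastic shape-memory-alloy
#' law used for the stent wire fibres: bilinear elastic branches
#' (austenite/martensite) joined by flat forward and reverse
#' transformation plateaus with linear kinetics in the driving stress.
#'
#' @param E_A austenite Young's modulus (MPa)
#' @param E_M martensite Young's modulus (MPa)
#' @param nu Poisson's ratio (both phases, used for the elastic shear modulus)
#' @param sig_SL,sig_EL start/end stress of the forward (loading)
#'   transformation plateau (MPa)
#' @param sig_SU,sig_EU start/end stress of the reverse (unloading)
#'   transformation plateau (MPa)
#' @param eps_L maximum transformation strain (dimensionless)
#' @param alpha tension-compression asymmetry; compression plateau
#'   stresses are scaled by `(1 + alpha)`
#' @return object of class `nitinol_params`
#' @export
nitinol_params <- function(E_A, E_M, nu = 0.3, sig_SL, sig_EL,
                           sig_SU, sig_EU, eps_L, alpha = 0) {
  stopifnot(E_A > 0, E_M > 0, nu > 0, nu < 0.5,
            sig_EL > sig_SL, sig_SL > sig_SU, sig_SU > sig_EU, sig_EU > 0,
            eps_L > 0, eps_L < 0.15, alpha >= 0)
  structure(list(E_A = E_A, E_M = E_M, nu = nu,
                 sig_SL = sig_SL, sig_EL = sig_EL,
                 sig_SU = sig_SU, sig_EU = sig_EU,
                 eps_L = eps_L, alpha = alpha),
            class = "nitinol_params")
}

#' @export
print.nitinol_params <- function(x, ...) {
  cat("Superelastic Nitinol parameters (MPa, -):\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

sma_param_vec <- function(p) {
  vapply(c("E_A", "E_M", "sig_SL", "sig_EL", "sig_SU", "sig_EU",
           "eps_L", "alpha"), function(k) p[[k]], numeric(1))
}

#' Named Nitinol parameter presets
#'
#' `"valiant_captivia_table2"` is the calibrated set for the Valiant
#' Captivia ring wire; `"kleinstreuer2008"` is the literature starting
#' point used by the calibration routines.
#'
#' @param name preset name
#' @return a [nitinol_params()] object
#' @export
nitinol_preset <- function(name = c("valiant_captivia_table2", "kleinstreuer2008")) {
  name <- match.arg(name)
  switch(name,
    valiant_captivia_table2 = nitinol_params(
      E_A = 57500, E_M = 47800, nu = 0.3,
      sig_SL = 550, sig_EL = 620, sig_SU = 450, sig_EU = 250,
      eps_L = 0.063, alpha = 0.0279),
    # Kleinstreuer et al. (2008), J Biomech 41:2370-2378, Nitinol set
    # for stent-graft wire; alpha kept at the device value (never fitted).
    kleinstreuer2008 = nitinol_params(
      E_A = 51700, E_M = 47800, nu = 0.3,
      sig_SL = 600, sig_EL = 670, sig_SU = 288, sig_EU = 254,
      eps_L = 0.063, alpha = 0.0279))
}

#' Fresh superelastic material state
#'
#' @return list with martensite fraction `xi`, transformation direction
#'   `dir`, last strain `eps` and stress `sig`, and the active `branch`
#' @export
sma_state <- function() {
  list(xi = 0, dir = 1, eps = 0, sig = 0, branch = "elastic")
}

#' Strain-driven update of the superelastic law
#'
#' Advances a single material point to a new total strain and returns the
#' stress together with the updated history state.
#'
#' @param eps_new new total strain
#' @param state state from [sma_state()] or a previous update
#' @param params [nitinol_params()]
#' @return list with `sig` (MPa) and `state`
#' @export
sma_update <- function(eps_new, state = sma_state(), params) {
  if (!is.finite(eps_new)) stop("strain must be finite")
  out <- sma_update_cpp(eps_new, state$xi, state$dir, sma_param_vec(params))
  branch <- if (out$xi > state$xi) "forward"
            else if (out$xi < state$xi) "reverse" else "elastic"
  list(sig = out$sig,
       state = list(xi = out$xi, dir = out$dir, eps = eps_new,
                    sig = out$sig, branch = branch))
}

#' Drive the superelastic law through a strain path
#'
#' @param eps numeric vector of total strains (visited in order)
#' @param params [nitinol_params()]
#' @param state optional starting state
#' @return data.frame with columns `eps`, `sig` (MPa), `xi`
#' @export
sma_path <- function(eps, params, state = sma_state()) {
  if (any(!is.finite(eps))) stop("strain path must be finite")
  out <- sma_sweep_cpp(eps, sma_param_vec(params), state$xi, state$dir)
  data.frame(eps = eps, sig = out$sig, xi = out$xi)
}

#' Graft fabric material parameters
#'
#' Isotropic plane-stress law for the polyester graft with the stiffness
#' against compressive principal stresses scaled down (zero by default,
#' which reproduces wrinkling-like zero-compression fabric behaviour).
#'
#' @param E_long longitudinal Young's modulus (MPa)
#' @param nu Poisson's ratio
#' @param thickness membrane thickness (mm)
#' @param compressive_stiffness_factor in `[0, 1]`; 0 = true fabric,
#'   1 = classical linear isotropic plane stress
#' @return object of class `fabric_params`
#' @export
fabric_params <- function(E_long = 1080, nu = 0.35, thickness = 0.1,
                          compressive_stiffness_factor = 0) {
  stopifnot(E_long > 0, thickness > 0,
            compressive_stiffness_factor >= 0, compressive_stiffness_factor <= 1)
  structure(list(E_long = E_long, nu = nu, thickness = thickness,
                 compressive_stiffness_factor = compressive_stiffness_factor),
            class = "fabric_params")
}

#' Plane-stress fabric update
#'
#' Maps an in-plane membrane strain to Cauchy stress and stress
#' resultants. The isotropic plane-stress stress is rotated to the
#' principal frame, compressive principal components are scaled by the
#' compressive stiffness factor, and the result is rotated back.
#'
#' @param strain either a 2x2 strain tensor or a vector
#'   `c(e11, e22, gamma12)` with engineering shear
#' @param p [fabric_params()]
#' @return list with `stress` (`c(s11, s22, s12)`, MPa), principal
#'   stresses `principal`, principal angle `theta` (rad) and
#'   `resultant` (stress times thickness, N/mm)
#' @export
fabric_update <- function(strain, p) {
  if (is.matrix(strain)) {
    e <- c(strain[1, 1], strain[2, 2], strain[1, 2] + strain[2, 1])
  } else {
    e <- as.numeric(strain)
  }
  if (any(!is.finite(e))) stop("strain must be finite")
  E <- p$E_long; nu <- p$nu
  c1 <- E / (1 - nu^2)
  s11 <- c1 * (e[1] + nu * e[2])
  s22 <- c1 * (e[2] + nu * e[1])
  s12 <- c1 * (1 - nu) / 2 * e[3]
  # principal frame
  m <- (s11 + s22) / 2; d <- (s11 - s22) / 2
  r <- sqrt(d^2 + s12^2)
  p1 <- m + r; p2 <- m - r
  theta <- 0.5 * atan2(2 * s12, s11 - s22)
  f <- p$compressive_stiffness_factor
  q1 <- if (p1 < 0) f * p1 else p1
  q2 <- if (p2 < 0) f * p2 else p2
  ct <- cos(theta); st <- sin(theta)
  s11n <- q1 * ct^2 + q2 * st^2
  s22n <- q1 * st^2 + q2 * ct^2
  s12n <- (q1 - q2) * st * ct
  stress <- c(s11n, s22n, s12n)
  list(stress = stress, principal = c(q1, q2), theta = theta,
       resultant = stress * p$thickness)
}

#' Uniaxial plane-stress response of the fabric law
#'
#' Applies an axial strain with free lateral contraction
#' (`e22 = -nu * e11` for tensile loading), the standard uniaxial-stress
#' test on a membrane coupon; returns the axial Cauchy stress.
#'
#' @param eps axial strain (vectorised)
#' @param p [fabric_params()]
#' @return axial stress (MPa)
#' @export
fabric_uniaxial <- function(eps, p) {
  vapply(eps, function(e) {
    fabric_update(c(e, -p$nu * e, 0), p)$stress[1]
  }, numeric(1))
}

#' Linear elastic uniaxial update
#'
#' @param eps strain (vectorised)
#' @param E Young's modulus (MPa)
#' @return stress `E * eps` (MPa)
#' @export
linear_elastic_update <- function(eps, E) {
  stopifnot(E > 0)
  E * eps
}
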