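#' Explicit solver configuration
#'
#' @param dt_target timestep (s); nodal masses are inflated so the
#'   element-wise critical step stays above it when `mass_scaling` is on
#' @param damping_stent,damping_graft mass-proportional damping (1/s)
#' @param ke_tol relative kinetic-energy threshold for dynamic
#'   relaxation (fraction of the in-phase peak)
#' @param max_steps step budget for [relax_to_equilibrium()]
#' @param mass_scaling enable mass scaling
#' @param rho_stent,rho_graft densities (tonne/mm^3)
#' @param fatal_eps fibre / membrane strain beyond which a run is
#'   declared fatally deformed
#' @param fatal_jmin in-plane area ratio below which a stress-bearing
#'   membrane element counts as collapsed (three consecutive checks)
#' @param fatal_tens membrane tensile principal strain beyond which an
#'   element counts as destroyed
#' @param visc stiffness-proportional bulk viscosity (fraction of the
#'   elastic stress increment per step) damping element-local modes
#' @return object of class `solver_config`
#' @export
solver_config <- function(dt_target = 1e-6, damping_stent = 1,
                          damping_graft = 0.1, ke_tol = 1e-3,
                          max_steps = 200000L, mass_scaling = TRUE,
                          rho_stent = 6.45e-9, rho_graft = 1.4e-9,
                          fatal_eps = 0.4, fatal_jmin = 0.05,
                          fatal_tens = 1.0, visc = 0.05) {
  stopifnot(dt_target > 0, damping_stent >= 0, damping_graft >= 0, ke_tol > 0,
            visc >= 0)
  structure(list(dt_target = dt_target, damping_stent = damping_stent,
                 damping_graft = damping_graft, ke_tol = ke_tol,
                 max_steps = as.integer(max_steps), mass_scaling = mass_scaling,
                 rho_stent = rho_stent, rho_graft = rho_graft,
                 fatal_eps = fatal_eps, fatal_jmin = fatal_jmin,
                 fatal_tens = fatal_tens, visc = visc),
            class = "solver_config")
}

#' Assemble an explicit FE model from meshes and materials
#'
#' Stent nodes come first in the global numbering, then graft nodes.
#'
#' @param beam a `beam_mesh` (or NULL)
#' @param membrane a `membrane_mesh` (or NULL)
#' @param stent_material [nitinol_params()] or `list(type = "linear", E = ...)`
#' @param fabric [fabric_params()] (`compressive_stiffness_factor = 1`
#'   recovers a classical linear membrane)
#' @param cfg [solver_config()]
#' @param ties optional override of the suture map (pairs of global
#'   stent node, global graft node); by default taken from
#'   `membrane$suture_map`
#' @return object of class `fe_model`
#' @export
fe_model <- function(beam = NULL, membrane = NULL,
                     stent_material = nitinol_preset(), fabric = fabric_params(),
                     cfg = solver_config(), ties = NULL) {
  nb <- if (is.null(beam)) 0L else nrow(beam$nodes)
  nm <- if (is.null(membrane)) 0L else nrow(membrane$nodes)
  if (nb + nm == 0) stop("empty model")
  x0 <- rbind(if (nb) beam$nodes else NULL,
              if (nm) membrane$nodes else NULL)
  lin <- is.list(stent_material) && !inherits(stent_material, "nitinol_params")
  smap <- if (lin) nitinol_preset() else stent_material
  m <- if (nb) nrow(beam$elements) else 0L
  model <- list(
    x0 = x0,
    n_beam_nodes = nb,
    beam_conn = if (nb) beam$elements else matrix(integer(0), 0, 2),
    beam_r = if (nb) beam$section_radius else numeric(0),
    beam_mat = if (nb) rep(if (lin) 1L else 0L, m) else integer(0),
    beam_E = if (nb) rep(if (lin) stent_material$E else smap$E_A, m) else numeric(0),
    sma_params = sma_param_vec(smap),
    beam_nu = smap$nu,
    beam_rho = cfg$rho_stent,
    mem_tris = if (nm) membrane$triangles + nb else NULL,
    mem_thick = if (nm) membrane$thickness else 0.1,
    fabric = c(E_long = fabric$E_long, nu = fabric$nu,
               factor = fabric$compressive_stiffness_factor),
    mem_rho = cfg$rho_graft,
    visc = cfg$visc,
    ties = NULL,
    part = c(rep(1L, nb), rep(2L, nm)),
    beam_mesh = beam, membrane_mesh = membrane)
  if (is.null(ties) && nm && !is.null(membrane$suture_map)) {
    ties <- cbind(membrane$suture_map[, "stent_node"],
                  membrane$suture_map[, "graft_node"] + nb)
  } else if (!is.null(ties)) {
    ties <- cbind(ties[, 1], ties[, 2] + nb)
  }
  model["ties"] <- list(ties)   # keep the element even when NULL
  structure(model, class = "fe_model")
}

#' Initialise the dynamic state of a model
#'
#' Computes reference geometry, lumped (possibly scaled) masses and
#' zeroed velocities, rotations and material history.
#'
#' @param model [fe_model()]
#' @param cfg [solver_config()]
#' @return object of class `fe_state`; the added-mass fraction from mass
#'   scaling is in `$added_mass_fraction`
#' @export
fe_state <- function(model, cfg = solver_config()) {
  st <- fe_init_state_cpp(model, cfg$dt_target, cfg$mass_scaling)
  class(st) <- "fe_state"
  st
}

# full phase list with every key the kernel expects
fe_phase <- function(model, cfg, n_steps,
                     surfaces = list(), bc = NULL, f_ext = NULL,
                     ramp_frac = 0.9, stop_on_ke = FALSE,
                     ties_active = FALSE, self_contact = FALSE,
                     fatal_check = FALSE, record_stride = 50L,
                     damping = NULL, record_fibres = FALSE) {
  if (is.null(damping))
    damping <- ifelse(model$part == 1L, cfg$damping_stent, cfg$damping_graft)
  list(n_steps = as.integer(n_steps), record_stride = as.integer(record_stride),
       ramp_frac = ramp_frac, stop_on_ke = stop_on_ke, ke_tol = cfg$ke_tol,
       damping = damping, ties_active = ties_active, self_contact = self_contact,
       fatal_check = fatal_check, fatal_eps = cfg$fatal_eps,
       fatal_jmin = cfg$fatal_jmin, fatal_tens = cfg$fatal_tens,
       record_fibres = record_fibres,
       bc_idx = if (is.null(bc)) NULL else as.integer(bc$idx),
       bc_from = if (is.null(bc)) NULL else bc$from,
       bc_to = if (is.null(bc)) NULL else bc$to,
       bc_mask = if (is.null(bc)) NULL else bc$mask,
       bc_rotfix = if (is.null(bc)) NULL else as.integer(bc$rotfix),
       f_ext = f_ext,
       surfaces = surfaces)
}

bc_spec <- function(idx, from, to, mask = NULL, rotfix = NULL) {
  idx <- as.integer(idx)
  if (is.null(mask)) mask <- matrix(1, length(idx), 3)
  if (is.null(rotfix)) rotfix <- rep(0L, length(idx))
  list(idx = idx, from = from, to = to, mask = mask, rotfix = rotfix)
}

#' Advance the explicit solution
#'
#' Runs one phase of central-difference time stepping with the given
#' surfaces, boundary conditions and external loads.
#'
#' @param model [fe_model()]
#' @param state [fe_state()]
#' @param cfg [solver_config()]
#' @param n_steps number of steps
#' @param ... passed to the internal phase constructor (surfaces, bc,
#'   f_ext, ramp_frac, stop_on_ke, ties_active, self_contact,
#'   fatal_check, record_stride, damping)
#' @return list with `state`, `records` (data.frame time series:
#'   energies, per-surface forces and commanded parameters, max fibre
#'   strain), `outcome` (`"ok"`, `"divergence"`, or a `"fatal_..."` bad-deformation code)
#'   and `steps_done`
#' @export
fe_step <- function(model, state, cfg = solver_config(), n_steps = 1L, ...) {
  ph <- fe_phase(model, cfg, n_steps, ...)
  # the kernel updates state arrays in place; keep the caller's copy intact
  state <- lapply(state, function(el) if (is.numeric(el)) el + 0 else el)
  out <- fe_run_phase_cpp(model, state, ph)
  rec <- out$records
  ns <- ncol(rec$surf_force)
  df <- data.frame(time = rec$time, ke = rec$ke, ie = rec$ie,
                   wext = rec$wext, d_damp = rec$d_damp, d_fric = rec$d_fric,
                   e_contact = rec$e_contact, max_fib_eps = rec$max_fib_eps,
                   max_mem_tens = rec$max_mem_tens, min_mem_J = rec$min_mem_J)
  if (length(ph$surfaces)) {
    sf <- rec$surf_force; sp <- rec$surf_param
    colnames(sf) <- paste0("F_surf", seq_len(ns))
    colnames(sp) <- paste0("par_surf", seq_len(ns))
    df <- cbind(df, sf, sp)
  }
  st <- out$state
  class(st) <- "fe_state"
  list(state = st, records = df, fib_eps = rec$fib_eps,
       outcome = c("ok", "fatal_fibre_strain", "divergence",
                   "fatal_membrane_strain",
                   "fatal_membrane_collapse")[out$outcome + 1],
       steps_done = out$steps_done, ke_peak = out$ke_peak)
}

#' Dynamic relaxation to quasi-static equilibrium
#'
#' Steps with prescribed motions held fixed until the kinetic energy
#' falls below `cfg$ke_tol` times its in-phase peak.
#'
#' @inheritParams fe_step
#' @param max_steps step budget; exceeding it raises a non-convergence
#'   error unless `error_on_fail = FALSE`
#' @param error_on_fail raise an error on non-convergence
#' @return as [fe_step()]
#' @export
relax_to_equilibrium <- function(model, state, cfg = solver_config(),
                                 max_steps = cfg$max_steps,
                                 error_on_fail = TRUE, ...) {
  out <- fe_step(model, state, cfg, n_steps = max_steps,
                 ramp_frac = 0, stop_on_ke = TRUE, ...)
  if (out$steps_done >= max_steps && error_on_fail) {
    ke_end <- utils::tail(out$records$ke, 1)
    if (is.finite(ke_end) && out$ke_peak > 0 &&
        ke_end > cfg$ke_tol * out$ke_peak)
      stop("dynamic relaxation did not converge within max_steps")
  }
  out
}

#' Beam internal forces for a displaced configuration
#'
#' Corotational fibre-beam force evaluation (no time stepping): axial
#' strain plus two bending curvatures sampled at two Gauss stations,
#' four section fibres each, every fibre through the active material
#' law; elastic torsion.
#'
#' @param mesh a `beam_mesh`
#' @param displacements n x 3 nodal displacement matrix
#' @param material [nitinol_params()] or `list(type="linear", E=)`
#' @param rotations optional n x 4 quaternion matrix (identity default)
#' @return list with nodal `f` (N), `mom` (N mm) and `max_eps`
#' @export
beam_internal_forces <- function(mesh, displacements, material = nitinol_preset(),
                                 rotations = NULL) {
  model <- fe_model(beam = mesh, stent_material = material)
  n <- nrow(mesh$nodes)
  x <- mesh$nodes + displacements
  q <- rotations
  if (is.null(q)) {
    q <- matrix(0, n, 4); q[, 1] <- 1
  }
  beam_forces_cpp(model, x, q, mesh$nodes)
}

#' Membrane internal forces for a displaced configuration
#'
#' Constant-strain triangles through the fabric plane-stress law; no
#' bending stiffness.
#'
#' @param mesh a `membrane_mesh`
#' @param displacements n x 3 displacement matrix
#' @param fabric [fabric_params()]
#' @return list with nodal `f` (N), minimum area ratio `min_J` and the
#'   maximum tensile principal strain
#' @export
membrane_internal_forces <- function(mesh, displacements, fabric = fabric_params()) {
  model <- fe_model(membrane = mesh, fabric = fabric)
  x <- mesh$nodes + displacements
  membrane_forces_cpp(model, x, mesh$nodes)
}

#' Energy balance of a protocol's records
#'
#' @param records row-bound records of the phases of a protocol
#' @return list with terms (mJ) and the relative closure error
#' @export
energy_balance <- function(records) {
  last <- records[nrow(records), ]
  # external work is measured on the node side of every interface, so
  # the ledger closes over kinetic + internal + damping-dissipated
  # energy; friction dissipation and penalty storage live on the
  # surface side and are reported as diagnostics only
  lhs <- last$ke + last$ie + last$d_damp
  rhs <- last$wext
  scale <- max(abs(rhs), abs(last$ie), 1e-9)
  list(ke = last$ke, ie = last$ie, d_damp = last$d_damp, d_fric = last$d_fric,
       e_contact = last$e_contact, wext = rhs,
       rel_error = abs(lhs - rhs) / scale)
}
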