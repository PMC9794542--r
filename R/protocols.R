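#' Crimp/release simulation of a ring or device
#'
#' Reproduces the radial-force bench test: twelve rigid planes tangent
#' to the commanded cylinder close from `start_diameter` to
#' `min_diameter` and open back to `release_to`; the radial force is
#' the sum of the twelve plane contact forces. The returned curve is
#' phase-labelled; per-step surface forces are averaged between records.
#'
#' @param object a `beam_mesh` (single ring), a [ring_spec()], or a
#'   `device_state` from [apply_prestress()]
#' @param proto [crimp_protocol()]
#' @param material stent material ([nitinol_params()] or
#'   `list(type = "linear", E = )`); ignored for `device_state` input
#' @param cfg [solver_config()]
#' @param mu plane friction coefficient (0.3 stent-plane)
#' @param record_fibres keep fibre strain histories in the result
#'   (needed to freeze a kinematic path for the calibration surrogate)
#' @param relax_after dynamic relaxation after release
#' @return a `force_diameter_curve` data.frame with attributes
#'   `records` (energy/force time series), `state` (final [fe_state()]),
#'   `model`, `outcome`, and `fib_eps`/`fib_vol` when requested
#' @export
run_crimp_release <- function(object, proto, material = nitinol_preset(),
                              cfg = solver_config(), mu = 0.3,
                              record_fibres = FALSE, relax_after = TRUE) {
  if (inherits(object, "ring_spec")) object <- make_ring(object)
  if (inherits(object, "device_state")) {
    model <- object$model
    st <- object$state
    ties_on <- TRUE
  } else {
    stopifnot(inherits(object, "beam_mesh"))
    model <- fe_model(beam = object, stent_material = material, cfg = cfg)
    st <- fe_state(model, cfg)
    ties_on <- FALSE
  }
  stride_l <- max(1L, proto$n_steps_load %/% 400L)
  stride_u <- max(1L, proto$n_steps_unload %/% 400L)
  # the crimper must close from outside the device envelope even when
  # the protocol's nominal start diameter is smaller (the bench iris
  # sweeps through it on the way down)
  d_env <- 2 * max(sqrt(rowSums(st$x[, 1:2]^2)))
  d_start <- max(proto$start_diameter, 1.03 * d_env)
  ph1 <- fe_step(model, st, cfg, n_steps = proto$n_steps_load,
                 surfaces = crimper_planes(d_start,
                                           proto$min_diameter, mu = mu),
                 self_contact = TRUE, ties_active = ties_on,
                 record_stride = stride_l, ramp_frac = 0.97,
                 record_fibres = record_fibres, fatal_check = TRUE)
  if (ph1$outcome != "ok")
    stop("crimp diverged (", ph1$outcome, ") at step ", ph1$steps_done)
  ph2 <- fe_step(model, ph1$state, cfg, n_steps = proto$n_steps_unload,
                 surfaces = crimper_planes(proto$min_diameter,
                                           proto$release_to, mu = mu),
                 self_contact = TRUE, ties_active = ties_on,
                 record_stride = stride_u, ramp_frac = 0.97,
                 record_fibres = record_fibres, fatal_check = TRUE)
  if (ph2$outcome != "ok")
    stop("release diverged (", ph2$outcome, ") at step ", ph2$steps_done)
  final <- ph2
  if (relax_after)
    final <- relax_to_equilibrium(model, ph2$state, cfg,
                                  max_steps = min(cfg$max_steps, 60000L),
                                  ties_active = ties_on,
                                  error_on_fail = FALSE)
  Fc <- paste0("F_surf", 1:12)
  r1 <- ph1$records; r2 <- ph2$records
  curve <- rbind(
    data.frame(diameter = r1$par_surf1, force = rowSums(r1[, Fc]),
               phase = "loading"),
    data.frame(diameter = r2$par_surf1, force = rowSums(r2[, Fc]),
               phase = "unloading"))
  class(curve) <- c("force_diameter_curve", "data.frame")
  attr(curve, "records") <- list(load = r1, unload = r2,
                                 relax = final$records)
  attr(curve, "state") <- final$state
  attr(curve, "model") <- model
  attr(curve, "outcome") <- final$outcome
  if (record_fibres) {
    attr(curve, "fib_eps") <- rbind(ph1$fib_eps, ph2$fib_eps)
    L0 <- final$state$L0
    A <- pi * model$beam_r^2
    # fibre volume: (A/4) * L0 * Gauss weight 1/2, 8 fibres per element
    attr(curve, "fib_vol") <- rep(A * L0 / 8, each = 8)
  }
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_device_state <- function(model, state, spec) {
  structure(list(model = model, state = state, x = state$x,
                 beam = model$beam_mesh, membrane = model$membrane_mesh,
                 spec = spec), class = "device_state")
}

#' Apply the stent pre-stress procedure to an assembled device
#'
#' Rings are moved from their stress-free diameter to the sutured one
#' by a radial displacement boundary condition (axial motion left
#' free), accumulating superelastic material history; the suture ties
#' are then activated and the assembly relaxed to equilibrium, leaving
#' a residual stress field in the stent.
#'
#' @param device output of [make_device()]
#' @param cfg [solver_config()]
#' @param stent_material [nitinol_params()] or linear spec
#' @param fabric [fabric_params()]
#' @param n_steps displacement-ramp steps
#' @return a `device_state` (model + dynamic state + meshes)
#' @export
apply_prestress <- function(device, cfg = solver_config(damping_stent = 20000,
                                                        damping_graft = 2000,
                                                        visc = 0.2),
                            stent_material = nitinol_preset(),
                            fabric = fabric_params(), n_steps = 8000L) {
  model <- fe_model(beam = device$beam, membrane = device$membrane,
                    stent_material = stent_material, fabric = fabric,
                    cfg = cfg)
  st <- fe_state(model, cfg)
  pr <- device$spec$prestress_ratio
  nb <- model$n_beam_nodes
  x0 <- model$x0[seq_len(nb), , drop = FALSE]
  # length-preserving fold of every ring onto the sutured diameter
  tgt <- x0
  for (r in device$beam$rings)
    tgt[r$nodes, ] <- fold_ring_nodes(x0[r$nodes, , drop = FALSE],
                                      1 / (1 + pr))
  bc <- bc_spec(seq_len(nb), from = x0, to = tgt)
  if (pr > 0) {
    ph1 <- fe_step(model, st, cfg, n_steps = n_steps, bc = bc,
                   ramp_frac = 0.9, record_stride = max(1L, n_steps %/% 50L))
    st <- ph1$state
  }
  # heavily damped release: the assembly is practically static within
  # a few damping time constants; the budget caps the fabric's
  # persistent low-level wrinkling jitter
  ph2 <- relax_to_equilibrium(model, st, cfg,
                              max_steps = min(cfg$max_steps, 12000L),
                              ties_active = TRUE, error_on_fail = FALSE)
  as_device_state(model, ph2$state, device$spec)
}

#' Arch-like vessel centerline for desk-scale deployments
#'
#' Straight entry segment along the device axis, a circular bend in the
#' x-z plane, and a straight landing segment. The entry segment
#' contains the device's initial position so that zero advance maps the
#' device onto itself.
#'
#' @param z_start start of the centerline (mm, below the device)
#' @param straight entry length (mm)
#' @param bend_radius,bend_angle circular bend parameters (mm, rad)
#' @param out_straight landing segment length (mm)
#' @param step sampling step (mm)
#' @return k x 3 polyline matrix
#' @export
make_arch_centerline <- function(z_start = -20, straight = 100,
                                 bend_radius = 45, bend_angle = pi / 3,
                                 out_straight = 60, step = 3) {
  z1 <- seq(0, straight, by = step)
  P <- cbind(0, 0, z_start + z1)
  cz <- z_start + straight
  th <- seq(step / bend_radius, bend_angle, by = step / bend_radius)
  P <- rbind(P, cbind(bend_radius * (1 - cos(th)), 0, cz + bend_radius * sin(th)))
  tang <- c(sin(bend_angle), 0, cos(bend_angle))
  pend <- P[nrow(P), ]
  tt <- seq(step, out_straight, by = step)
  P <- rbind(P, cbind(pend[1] + tang[1] * tt, 0, pend[3] + tang[3] * tt))
  P
}

approx_frame <- function(frames, M, s) {
  vapply(1:3, function(c) approx(frames$s, M[, c], s)$y, numeric(1))
}

# rigidly rotate + translate a dynamic state (positions, velocities and
# node triads) so the device z-axis maps onto a new direction
place_state <- function(st, Rp, centre, target) {
  st <- lapply(st, function(el) if (is.numeric(el)) el + 0 else el)
  x <- st$x
  st$x[] <- sweep(sweep(x, 2, centre) %*% t(Rp), 2, target, "+")
  st$v[] <- st$v %*% t(Rp)
  st$w[] <- st$w %*% t(Rp)
  # quaternion of Rp (w, x, y, z), robust trace branch
  tr <- sum(diag(Rp))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    qp <- c(0.25 * s, (Rp[3, 2] - Rp[2, 3]) / s,
            (Rp[1, 3] - Rp[3, 1]) / s, (Rp[2, 1] - Rp[1, 2]) / s)
  } else {
    i <- which.max(diag(Rp))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(Rp[i, i] - Rp[j, j] - Rp[k, k] + 1) * 2
    qp <- numeric(4)
    qp[1] <- (Rp[k, j] - Rp[j, k]) / s
    qp[i + 1] <- 0.25 * s
    qp[j + 1] <- (Rp[j, i] + Rp[i, j]) / s
    qp[k + 1] <- (Rp[k, i] + Rp[i, k]) / s
  }
  q <- st$q
  st$q[, 1] <- qp[1] * q[, 1] - qp[2] * q[, 2] - qp[3] * q[, 3] - qp[4] * q[, 4]
  st$q[, 2] <- qp[1] * q[, 2] + qp[2] * q[, 1] + qp[3] * q[, 4] - qp[4] * q[, 3]
  st$q[, 3] <- qp[1] * q[, 3] - qp[2] * q[, 4] + qp[3] * q[, 1] + qp[4] * q[, 2]
  st$q[, 4] <- qp[1] * q[, 4] + qp[2] * q[, 3] - qp[3] * q[, 2] + qp[4] * q[, 1]
  class(st) <- "fe_state"
  st
}

# parallel-transported frames along a polyline
centerline_frames <- function(P) {
  P <- as.matrix(P)
  k <- nrow(P)
  seg <- diff(P)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  Tt <- rbind(seg / len, seg[k - 1, ] / len[k - 1])
  N1 <- matrix(0, k, 3)
  n <- c(1, 0, 0)
  n <- n - sum(n * Tt[1, ]) * Tt[1, ]; n <- n / sqrt(sum(n^2))
  N1[1, ] <- n
  for (i in 2:k) {
    n <- N1[i - 1, ]
    n <- n - sum(n * Tt[i, ]) * Tt[i, ]
    N1[i, ] <- n / sqrt(sum(n^2))
  }
  N2 <- cbind(Tt[, 2] * N1[, 3] - Tt[, 3] * N1[, 2],
              Tt[, 3] * N1[, 1] - Tt[, 1] * N1[, 3],
              Tt[, 1] * N1[, 2] - Tt[, 2] * N1[, 1])
  list(P = P, s = s, T = Tt, N1 = N1, N2 = N2, z_start = P[1, 3])
}

# map device cross-sections onto the centerline at a given advance
track_map <- function(x, frames, advance, radial_scale = 1) {
  s_node <- x[, 3] - frames$z_start + advance
  s_node <- pmin(pmax(s_node, 0), max(frames$s))
  fi <- function(M) apply(M, 2, function(cc) approx(frames$s, cc, s_node)$y)
  C <- fi(frames$P); Tt <- fi(frames$T); N1 <- fi(frames$N1)
  Tt <- Tt / sqrt(rowSums(Tt^2))
  N1 <- N1 - rowSums(N1 * Tt) * Tt
  N1 <- N1 / sqrt(rowSums(N1^2))
  N2 <- cbind(Tt[, 2] * N1[, 3] - Tt[, 3] * N1[, 2],
              Tt[, 3] * N1[, 1] - Tt[, 1] * N1[, 3],
              Tt[, 1] * N1[, 2] - Tt[, 2] * N1[, 1])
  C + x[, 1] * radial_scale * N1 + x[, 2] * radial_scale * N2
}

#' Deployment protocol
#'
#' @param method `"tracking"` (crimp into the catheter, advance along
#'   the centerline, gradual unsheathing with tip capture),
#'   `"virtual_catheter"` (prescribed crimp-and-morph onto the
#'   centerline, instantaneous release) or
#'   `"virtual_catheter_modified"` (morph, then gradual sheath
#'   retraction)
#' @param centerline k x 3 polyline (see [make_arch_centerline()])
#' @param catheter_radius inner sheath radius (mm; 3.75 by default, a
#'   configurable stand-in for the delivery-system profile)
#' @param vessel_radius rigid vessel tube radius (mm)
#' @param advance tracking arc length (mm)
#' @param tip_capture hold the bare-ring proximal apexes until last
#'   (tracking only; on by default for Free-Flo devices)
#' @param n_steps list of step counts per phase
#' @param track_segments piecewise-linear subdivisions of the tracking
#'   motion
#' @return object of class `deployment_protocol`
#' @export
deployment_protocol <- function(method = c("tracking", "virtual_catheter",
                                           "virtual_catheter_modified"),
                                centerline = make_arch_centerline(),
                                catheter_radius = 3.75, vessel_radius = 10.5,
                                advance = 60, tip_capture = NULL,
                                n_steps = list(crimp = 10000L, track = 12000L,
                                               deploy = 14000L, release = 8000L),
                                track_segments = 6L) {
  method <- match.arg(method)
  structure(list(method = method, centerline = as.matrix(centerline),
                 catheter_radius = catheter_radius,
                 vessel_radius = vessel_radius, advance = advance,
                 tip_capture = tip_capture, n_steps = n_steps,
                 track_segments = as.integer(track_segments)),
            class = "deployment_protocol")
}

#' Run a deployment simulation
#'
#' Executes the protocol on a pre-stressed device and returns the
#' inspection-stage states. Runs that trip the bad-deformation checks
#' (wire fibre strain beyond 40%, stress-bearing membrane element
#' collapse, energy divergence) are reported as `"Negative"` with the
#' failing phase, mirroring how a production explicit solver terminates
#' on distorted elements.
#'
#' @param devstate `device_state` from [apply_prestress()]
#' @param proto [deployment_protocol()]
#' @param cfg [solver_config()]
#' @return list with `outcome` ("Positive"/"Negative"), `failed_phase`,
#'   `stages` (named list of `device_state`s), `records`
#' @export
run_deployment <- function(devstate, proto,
                           cfg = solver_config(damping_stent = 5000,
                                               damping_graft = 2000,
                                               visc = 0.2)) {
  model <- devstate$model
  st <- devstate$state
  spec <- devstate$spec
  frames <- centerline_frames(proto$centerline)
  nb <- model$n_beam_nodes
  n_all <- nrow(model$x0)
  stages <- list()
  records <- list()
  fail <- function(phase, out) {
    list(outcome = "Negative", failed_phase = phase, phase_outcome = out,
         stages = stages, records = records, protocol = proto)
  }
  dev_R <- max(sqrt(rowSums(st$x[, 1:2]^2)))
  tip_capture <- proto$tip_capture
  if (is.null(tip_capture))
    tip_capture <- spec$configuration == "FreeFlo" && proto$method == "tracking"

  if (proto$method == "tracking") {
    ## phase I: contact-driven crimp into the catheter (straight tube)
    zr <- range(model$x0[, 3])
    ax <- cbind(0, 0, seq(zr[1] - 30, zr[2] + 30, length.out = 2))
    ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$crimp,
                  surfaces = list(rigid_tube(ax, radius = dev_R + 1,
                                             radius_to = proto$catheter_radius,
                                             mu = 0.1)),
                  ties_active = TRUE, fatal_check = TRUE,
                  record_stride = 200L, ramp_frac = 0.95)
    records$crimp <- ph$records
    if (ph$outcome != "ok") return(fail("crimp", ph$outcome))
    st <- ph$state
    # the commanded crimp envelope must actually be enforced: a device
    # that resists contact beyond tolerance means the penalty contact
    # lost, and the protocol cannot proceed (runs of this kind abort as
    # contact failures in production solvers)
    if (max(sqrt(rowSums(st$x[, 1:2]^2))) >
        1.25 * proto$catheter_radius)
      return(fail("crimp", "contact_enforcement"))
    stages$crimped <- as_device_state(model, st, spec)
    ## phase II: tracking along the centerline (prescribed, piecewise)
    x_crimped <- st$x + 0
    K <- proto$track_segments
    for (k in seq_len(K)) {
      a0 <- proto$advance * (k - 1) / K
      a1 <- proto$advance * k / K
      bc <- bc_spec(seq_len(n_all),
                    from = track_map(x_crimped, frames, a0),
                    to = track_map(x_crimped, frames, a1))
      ph <- fe_step(model, st, cfg, n_steps = max(500L, proto$n_steps$track %/% K),
                    bc = bc, ties_active = TRUE, fatal_check = TRUE,
                    ramp_frac = 1, record_stride = 200L)
      records[[paste0("track", k)]] <- ph$records
      if (ph$outcome != "ok") return(fail("tracking", ph$outcome))
      st <- ph$state
    }
    stages$tracked <- as_device_state(model, st, spec)
    ## phase III: gradual unsheathing proximal -> distal
    sheath <- function(w_from, w_to)
      rigid_tube(proto$centerline, radius = proto$catheter_radius,
                 window = c(-1e9, w_from), window_to = c(-1e9, w_to), mu = 0)
    vessel <- rigid_tube(proto$centerline, radius = proto$vessel_radius,
                         mu = 0.1)
    s_max <- max(model$x0[, 3]) - frames$z_start + proto$advance + 5
    s_min <- min(model$x0[, 3]) - frames$z_start + proto$advance - 5
    pin_idx <- integer(0)
    if (tip_capture) {
      bare <- which(vapply(model$beam_mesh$rings,
                           function(r) r$spec$kind != "thin", logical(1)))[1]
      pin_idx <- model$beam_mesh$rings[[bare]]$apex_prox
    }
    pin_bc <- if (length(pin_idx))
      bc_spec(pin_idx, from = st$x[pin_idx, , drop = FALSE],
              to = st$x[pin_idx, , drop = FALSE]) else NULL
    w_steps <- c(0.35, 0.65, 1)
    stage_names <- c("first_ring", "half_body", "full_body")
    w_prev <- s_max
    for (j in seq_along(w_steps)) {
      w_now <- s_max - (s_max - s_min) * w_steps[j]
      ph <- fe_step(model, st, cfg,
                    n_steps = max(1000L, round(proto$n_steps$deploy *
                                               (w_steps[j] - c(0, w_steps)[j]))),
                    surfaces = list(sheath(w_prev, w_now), vessel),
                    bc = pin_bc, ties_active = TRUE, fatal_check = TRUE,
                    self_contact = FALSE, ramp_frac = 0.9,
                    record_stride = 200L)
      records[[paste0("deploy_", stage_names[j])]] <- ph$records
      if (ph$outcome != "ok") return(fail("deployment", ph$outcome))
      st <- ph$state
      stages[[stage_names[j]]] <- as_device_state(model, st, spec)
      w_prev <- w_now
    }
    ## phase IV: tip release and final relaxation
    ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$release,
                  surfaces = list(vessel), ties_active = TRUE,
                  fatal_check = TRUE, ramp_frac = 0, stop_on_ke = TRUE,
                  record_stride = 200L)
    records$release <- ph$records
    if (ph$outcome != "ok") return(fail("release", ph$outcome))
    st <- ph$state
    stages$final <- as_device_state(model, st, spec)
  } else {
    ## virtual catheter: the device is rigidly placed on the tangent
    ## line of the landing zone (a tube cannot push it axially), then a
    ## contact tube morphs from that line onto the curved centerline
    ## section while its radius shrinks, crimping and bending at once
    zr <- range(model$x0[, 3])
    z_mid <- mean(zr)
    s_mid <- z_mid - frames$z_start + proto$advance
    fi <- function(M) approx_frame(frames, M, s_mid)
    Pm <- fi(frames$P); Tm <- fi(frames$T); N1m <- fi(frames$N1)
    Tm <- Tm / sqrt(sum(Tm^2))
    N1m <- N1m - sum(N1m * Tm) * Tm
    N1m <- N1m / sqrt(sum(N1m^2))
    N2m <- c(Tm[2] * N1m[3] - Tm[3] * N1m[2],
             Tm[3] * N1m[1] - Tm[1] * N1m[3],
             Tm[1] * N1m[2] - Tm[2] * N1m[1])
    Rp <- cbind(N1m, N2m, Tm)    # placement rotation (device z -> tangent)
    st <- place_state(st, Rp, centre = c(0, 0, z_mid), target = Pm)
    z_samp <- seq(zr[1] - 25, zr[2] + 25, by = 3)
    cl_from <- t(Pm + Rp %*% rbind(0, 0, z_samp - z_mid))
    s_tgt <- z_samp - frames$z_start + proto$advance
    s_tgt <- pmin(pmax(s_tgt, 0), max(frames$s))
    cl_to <- apply(frames$P, 2, function(cc) approx(frames$s, cc, s_tgt)$y)
    vc_tube <- rigid_tube(cl_from, radius = dev_R + 1,
                          radius_to = proto$catheter_radius,
                          centerline_to = cl_to, mu = 0.1)
    x0 <- st$x + 0
    ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$crimp +
                    proto$n_steps$track,
                  surfaces = list(vc_tube), ties_active = TRUE,
                  fatal_check = TRUE, ramp_frac = 0.95,
                  record_stride = 200L)
    records$morph <- ph$records
    if (ph$outcome != "ok") return(fail("morph", ph$outcome))
    st <- ph$state
    # enforcement check against the morphed tube centerline
    dmax <- max(vapply(seq_len(nrow(st$x)), function(i) {
      d2 <- rowSums((cl_to - matrix(st$x[i, ], nrow(cl_to), 3,
                                    byrow = TRUE))^2)
      sqrt(min(d2))
    }, numeric(1)))
    if (dmax > 1.25 * proto$catheter_radius + 3)
      return(fail("morph", "contact_enforcement"))
    stages$crimped <- as_device_state(model, st, spec)
    vessel <- rigid_tube(proto$centerline, radius = proto$vessel_radius,
                         mu = 0.1)
    if (proto$method == "virtual_catheter") {
      ## instantaneous release: remove the morphing constraint at once
      ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$deploy +
                      proto$n_steps$release,
                    surfaces = list(vessel), ties_active = TRUE,
                    fatal_check = TRUE, ramp_frac = 0, stop_on_ke = TRUE,
                    record_stride = 200L)
      records$release <- ph$records
      if (ph$outcome != "ok") return(fail("release", ph$outcome))
      st <- ph$state
    } else {
      ## modified: gradual sheath retraction, proximal -> distal
      s_max <- max(model$x0[, 3]) - frames$z_start + proto$advance + 5
      s_min <- min(model$x0[, 3]) - frames$z_start + proto$advance - 5
      sheath <- rigid_tube(proto$centerline, radius = proto$catheter_radius,
                           window = c(-1e9, s_max),
                           window_to = c(-1e9, s_min), mu = 0)
      ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$deploy,
                    surfaces = list(sheath, vessel), ties_active = TRUE,
                    fatal_check = TRUE, ramp_frac = 0.9, record_stride = 200L)
      records$deploy <- ph$records
      if (ph$outcome != "ok") return(fail("deployment", ph$outcome))
      st <- ph$state
      ph <- fe_step(model, st, cfg, n_steps = proto$n_steps$release,
                    surfaces = list(vessel), ties_active = TRUE,
                    fatal_check = TRUE, ramp_frac = 0, stop_on_ke = TRUE,
                    record_stride = 200L)
      records$release <- ph$records
      if (ph$outcome != "ok") return(fail("release", ph$outcome))
      st <- ph$state
    }
    stages$final <- as_device_state(model, st, spec)
  }
  list(outcome = "Positive", failed_phase = NA_character_,
       stages = stages, records = records, protocol = proto)
}

#' Verification-matrix configurations
#'
#' The eight modelling variants compared against the reference tracking
#' model: linear-elastic stent wire, linear-elastic graft at two
#' stiffnesses, no pre-stress, and the virtual-catheter deployment
#' family.
#'
#' @return data.frame with columns `id`, `label`, `method`, `nitinol`,
#'   `prestress`, `pet`
#' @export
table3_configs <- function() {
  data.frame(
    id = sprintf("%02d", 1:8),
    label = c("Nitinol linear elastic", "PET linear elastic - 1.84 MPa",
              "PET linear elastic - 1.84 GPa", "Without stent pre-stress",
              "Virtual catheter method - fabric",
              "Virtual catheter method - linear elastic 1.84 MPa",
              "Virtual catheter method - linear elastic 1.84 GPa",
              "Virtual catheter method modified"),
    method = c("tracking", "tracking", "tracking", "tracking",
               "virtual_catheter", "virtual_catheter", "virtual_catheter",
               "virtual_catheter_modified"),
    nitinol = c("linear", rep("superelastic", 7)),
    prestress = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    pet = c("fabric", "linear_1.84MPa", "linear_1.84GPa", "fabric",
            "fabric", "linear_1.84MPa", "linear_1.84GPa", "fabric"),
    stringsAsFactors = FALSE)
}

.pet_variant <- function(pet) {
  switch(pet,
         fabric = fabric_params(),
         linear_1.84MPa = fabric_params(E_long = 1.84,
                                        compressive_stiffness_factor = 1),
         linear_1.84GPa = fabric_params(E_long = 1840,
                                        compressive_stiffness_factor = 1))
}

#' Run the verification matrix
#'
#' Runs every configuration of [table3_configs()] on the same device
#' and vessel, labels each run Positive/Negative, and for completed
#' runs computes opening-area statistics against a reference apex set
#' (typically a pseudo-segmentation of the baseline tracking run) and
#' the deployed length.
#'
#' @param device output of [make_device()]; the no-pre-stress variant
#'   rebuilds it with `prestress_ratio = 0`
#' @param proto_tracking baseline [deployment_protocol()] (tracking);
#'   virtual-catheter variants reuse its geometry
#' @param reference list of per-ring apex point sets (reference
#'   configuration); when NULL, OA statistics are skipped
#' @param configs subset of [table3_configs()] rows
#' @param cfg [solver_config()]
#' @param stent_params superelastic parameter set
#' @return data.frame mirroring the verification table: outcome, OA
#'   mean/sd/min/max, OA percent-error statistics, deployed length;
#'   per-run results in `attr(, "runs")`
#' @export
run_verification_matrix <- function(device, proto_tracking,
                                    reference = NULL,
                                    configs = table3_configs(),
                                    cfg = solver_config(damping_stent = 5000,
                                                        damping_graft = 2000,
                                                        visc = 0.2),
                                    stent_params = nitinol_preset()) {
  spec0 <- device$spec
  runs <- list()
  rows <- list()
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    dev_i <- device
    if (!cf$prestress) {
      spec_i <- spec0
      spec_i$prestress_ratio <- 0
      dev_i <- make_device(spec_i)
    }
    mat <- if (cf$nitinol == "linear")
      list(type = "linear", E = stent_params$E_A) else stent_params
    ds <- apply_prestress(dev_i, stent_material = mat,
                          fabric = .pet_variant(cf$pet))
    proto_i <- proto_tracking
    proto_i$method <- cf$method
    run <- tryCatch(run_deployment(ds, proto_i, cfg),
                    error = function(e) list(outcome = "Negative",
                                             failed_phase = conditionMessage(e),
                                             stages = list()))
    runs[[cf$id]] <- run
    row <- data.frame(id = cf$id, label = cf$label, outcome = run$outcome,
                      failed_phase = if (is.na(run$failed_phase %||% NA))
                        NA_character_ else as.character(run$failed_phase),
                      oa_mean = NA, oa_sd = NA, oa_min = NA, oa_max = NA,
                      err_mean = NA, err_sd = NA, err_min = NA, err_max = NA,
                      deployed_length = NA)
    if (run$outcome == "Positive") {
      fin <- run$stages$final
      apx <- lapply(seq_along(fin$beam$rings), function(k)
        suppressWarnings(extract_apexes(fin, k)))
      areas <- vapply(apx, opening_area, numeric(1))
      row$oa_mean <- mean(areas); row$oa_sd <- stats::sd(areas)
      row$oa_min <- min(areas); row$oa_max <- max(areas)
      if (!is.null(reference)) {
        oa <- oa_percent_error(areas,
                               vapply(reference, function(r)
                                 opening_area(r$apexes), numeric(1)))
        s <- attr(oa, "summary")
        row$err_mean <- s["mean"]; row$err_sd <- s["sd"]
        row$err_min <- s["min"]; row$err_max <- s["max"]
      }
      row$deployed_length <- deployed_length(fin, proto_tracking$centerline)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}
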