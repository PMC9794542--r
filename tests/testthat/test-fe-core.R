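test_that("corotational beam matches the cantilever closed form within 2 percent", {
  n_el <- 20; L <- 20; r <- 0.25; E <- 57500
  mesh <- straight_beam_mesh(n_el, L, r)
  cfg <- solver_config(damping_stent = 3000, ke_tol = 1e-8)
  model <- fe_model(beam = mesh, stent_material = list(type = "linear", E = E),
                    cfg = cfg)
  st <- fe_state(model, cfg)
  P <- 0.02
  fext <- matrix(0, n_el + 1, 3); fext[n_el + 1, 3] <- P
  bc <- tevarsim:::bc_spec(1L, from = mesh$nodes[1, , drop = FALSE],
                           to = mesh$nodes[1, , drop = FALSE], rotfix = 1L)
  out <- relax_to_equilibrium(model, st, cfg, max_steps = 120000,
                              f_ext = fext, bc = bc,
                              record_stride = 2000, error_on_fail = FALSE)
  I <- pi * r^4 / 4
  expect_rel_equal(out$state$x[n_el + 1, 3], P * L^3 / (3 * E * I), 0.02)
})

test_that("beam discretisation error drops by at least 3x on refinement", {
  # uniform transverse load: the quartic solution is outside the cubic
  # element space, so the error converges at finite order
  L <- 20; r <- 0.25; E <- 57500; w_tot <- 0.02
  I <- pi * r^4 / 4
  delta_exact <- (w_tot / L) * L^4 / (8 * E * I)
  tip_for <- function(n_el) {
    mesh <- straight_beam_mesh(n_el, L, r)
    cfg <- solver_config(damping_stent = 3000, ke_tol = 1e-9)
    model <- fe_model(beam = mesh, stent_material = list(type = "linear", E = E),
                      cfg = cfg)
    st <- fe_state(model, cfg)
    fext <- matrix(0, n_el + 1, 3)
    fext[, 3] <- w_tot / n_el
    fext[c(1, n_el + 1), 3] <- w_tot / n_el / 2
    bc <- tevarsim:::bc_spec(1L, from = mesh$nodes[1, , drop = FALSE],
                             to = mesh$nodes[1, , drop = FALSE], rotfix = 1L)
    out <- relax_to_equilibrium(model, st, cfg, max_steps = 150000,
                                f_ext = fext, bc = bc,
                                record_stride = 2000, error_on_fail = FALSE)
    out$state$x[n_el + 1, 3]
  }
  e1 <- abs(tip_for(5) - delta_exact)
  e2 <- abs(tip_for(10) - delta_exact)
  expect_gt(e1 / e2, 3)
})

test_that("rigid-body motion produces no internal force", {
  mesh <- straight_beam_mesh(10, 10, 0.25)
  f_t <- beam_internal_forces(mesh, matrix(1.23, 11, 3))
  expect_lt(max(abs(f_t$f)), 1e-9)
  expect_lt(max(abs(f_t$mom)), 1e-9)
  # membrane rigid rotation
  mem <- unit_square_membrane()
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  disp <- mem$nodes %*% t(R) - mem$nodes
  expect_lt(max(abs(membrane_internal_forces(mem, disp)$f)), 1e-9)
})

test_that("axial stretch of a single element integrates the fibre law", {
  m1 <- straight_beam_mesh(1, 1, 0.25)
  d <- rbind(c(0, 0, 0), c(0.02, 0, 0))
  f <- beam_internal_forces(m1, d, nitinol_preset())
  sig <- sma_update(0.02, params = nitinol_preset())$sig
  expect_rel_equal(abs(f$f[2, 1]), pi * 0.25^2 * sig, 1e-9)
})

test_that("membrane patch test transfers the uniaxial stress resultant", {
  mem <- unit_square_membrane()
  e <- 0.01; nu <- 0.35
  disp <- cbind(e * mem$nodes[, 1], -nu * e * mem$nodes[, 2], 0)
  out <- membrane_internal_forces(mem, disp)
  expect_rel_equal(abs(sum(out$f[c(2, 3), 1])), 10.8 * 0.1, 0.01)
  # uniform compression with factor 0 is force free
  disp_c <- cbind(-0.3 * mem$nodes[, 1], -0.3 * mem$nodes[, 2], 0)
  expect_equal(max(abs(membrane_internal_forces(mem, disp_c)$f)), 0)
})

test_that("central difference reproduces the oscillator frequency", {
  m1 <- straight_beam_mesh(1, 10, 0.5)
  cfg <- solver_config(damping_stent = 0, mass_scaling = FALSE,
                       dt_target = 2e-8, visc = 0)
  model <- fe_model(beam = m1, stent_material = list(type = "linear", E = 1000),
                    cfg = cfg)
  st <- fe_state(model, cfg)
  st$x[2, 1] <- 10.01
  bc <- tevarsim:::bc_spec(1L, from = m1$nodes[1, , drop = FALSE],
                           to = m1$nodes[1, , drop = FALSE], rotfix = 1L)
  out <- fe_step(model, st, cfg, n_steps = 60000, bc = bc, ramp_frac = 0,
                 record_stride = 10)
  ke <- out$records$ke; t <- out$records$time
  pk <- which(diff(sign(diff(ke))) < 0) + 1
  # kinetic energy oscillates at twice the natural frequency
  omega <- pi / mean(diff(t[pk]))
  k <- 1000 * pi * 0.25 / 10
  m <- 6.45e-9 * pi * 0.25 * 10 / 2
  expect_rel_equal(omega, sqrt(k / m), 1e-3)
})

test_that("stepping is inert without forces and dissipative with damping", {
  m1 <- straight_beam_mesh(4, 4, 0.25)
  cfg <- solver_config(damping_stent = 0)
  model <- fe_model(beam = m1, cfg = cfg)
  st <- fe_state(model, cfg)
  out <- fe_step(model, st, cfg, n_steps = 100, ramp_frac = 0)
  expect_equal(out$state$x, st$x)
  expect_equal(utils::tail(out$records$ke, 1), 0)
  # heavy damping: monotonic kinetic-energy decay of a free vibration
  cfg2 <- solver_config(damping_stent = 5e4, visc = 0)
  model2 <- fe_model(beam = m1, cfg = cfg2)
  st2 <- fe_state(model2, cfg2)
  set.seed(5)
  st2$v[] <- stats::rnorm(length(st2$v), 0, 10)
  out2 <- fe_step(model2, st2, cfg2, n_steps = 4000, ramp_frac = 0,
                  record_stride = 400)
  expect_true(all(diff(out2$records$ke) <= 1e-12))
})

test_that("dynamic relaxation terminates on the kinetic-energy criterion", {
  m1 <- straight_beam_mesh(10, 10, 0.25)
  cfg <- solver_config(damping_stent = 5000)
  model <- fe_model(beam = m1, cfg = cfg)
  st <- fe_state(model, cfg)
  # pre-equilibrated state returns almost immediately
  out <- relax_to_equilibrium(model, st, cfg, max_steps = 5000,
                              error_on_fail = FALSE)
  expect_equal(utils::tail(out$records$ke, 1), 0)
  # a disturbed state relaxes below the tolerance before the budget
  st$v[6, 3] <- 100
  out2 <- relax_to_equilibrium(model, st, cfg, max_steps = 150000)
  expect_lt(out2$steps_done, 150000)
  expect_lt(utils::tail(out2$records$ke, 1), cfg$ke_tol * out2$ke_peak * 1.01)
})
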