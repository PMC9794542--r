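test_that("pre-stress maps rings from stress-free to sutured diameter", {
  dev <- tiny_device()
  # meshed (stress-free) diameter is nominal x 1.17
  expect_rel_equal(measure_diameter(dev$beam, 1), 20 * 1.17, 1e-3)
  ds <- apply_prestress(dev, n_steps = 8000L)
  # rings bow outward between suture points; at this very coarse suture
  # grid (4 mm graft elements on a 20 mm device) the mean diameter sits
  # within ten percent of the sutured target
  for (k in seq_along(ds$beam$rings)) {
    d_k <- measure_diameter(ds$x[ds$beam$rings[[k]]$nodes, , drop = FALSE],
                            axis = c(0, 0, 1))
    expect_rel_equal(d_k, 20, 0.10)
  }
  # residual stress is retained in the wire
  expect_gt(max(abs(ds$state$fib_sig)), 100)
})

test_that("zero pre-stress ratio produces a stress-free assembly", {
  ds0 <- apply_prestress(tiny_device(prestress_ratio = 0), n_steps = 2000L)
  expect_lt(max(abs(ds0$state$fib_sig)), 1e-6)
  expect_lt(abs(ds0$state$ie), 1e-6)
})

ring5 <- ring_spec("peaks5", nominal_diameter = 30 * 1.17,
                   target_element_size = 2)
proto5 <- crimp_protocol(start_diameter = 36, min_diameter = 8,
                         n_steps_load = 25000L, n_steps_unload = 25000L)

test_that("superelastic crimp/release shows hysteresis and full recovery", {
  cfg <- solver_config(damping_stent = 500)
  cv <- run_crimp_release(ring5, proto5, cfg = cfg)
  expect_s3_class(cv, "force_diameter_curve")
  expect_setequal(unique(cv$phase), c("loading", "unloading"))
  ld <- cv[cv$phase == "loading", ]; ul <- cv[cv$phase == "unloading", ]
  d_grid <- seq(12, 30, length.out = 12)
  f_l <- approx(ld$diameter, ld$force, d_grid, ties = mean)$y
  f_u <- approx(ul$diameter, ul$force, d_grid, ties = mean)$y
  # material hysteresis: unloading force below loading force throughout
  expect_true(all(f_u < f_l))
  # fully open crimper exerts no force
  expect_equal(ld$force[1], 0)
  # superelastic ring recovers its free diameter after release
  st <- attr(cv, "state")
  d_rec <- measure_diameter(st$x[seq_len(nrow(attr(cv, "model")$beam_mesh$nodes)), ])
  expect_rel_equal(d_rec, 35.1, 0.005)
  # energy ledger closes over the whole protocol
  eb <- energy_balance(attr(cv, "records")$relax)
  expect_lt(eb$rel_error, 0.02)
})

test_that("a linear-elastic ring loads and unloads along the same path", {
  cfg <- solver_config(damping_stent = 500)
  cv <- run_crimp_release(ring5, proto5,
                          material = list(type = "linear", E = 57500),
                          cfg = cfg, mu = 0)
  ld <- cv[cv$phase == "loading", ]; ul <- cv[cv$phase == "unloading", ]
  d_grid <- seq(12, 30, length.out = 12)
  f_l <- approx(ld$diameter, ld$force, d_grid, ties = mean)$y
  f_u <- approx(ul$diameter, ul$force, d_grid, ties = mean)$y
  # no material hysteresis: residual gap is solver (damping) tolerance
  expect_lt(mean(abs(f_l - f_u)) / mean(f_l), 0.2)
  # and far smaller than the superelastic material hysteresis
  cv_se <- run_crimp_release(ring5, proto5, cfg = cfg, mu = 0)
  ld2 <- cv_se[cv_se$phase == "loading", ]; ul2 <- cv_se[cv_se$phase == "unloading", ]
  gap_se <- mean(abs(approx(ld2$diameter, ld2$force, d_grid, ties = mean)$y -
                     approx(ul2$diameter, ul2$force, d_grid, ties = mean)$y)) /
    mean(approx(ld2$diameter, ld2$force, d_grid, ties = mean)$y)
  expect_gt(gap_se, mean(abs(f_l - f_u)) / mean(f_l))
})

test_that("whole-device crimp to 10 mm runs with ties engaged", {
  ds <- apply_prestress(tiny_device(), n_steps = 8000L)
  proto <- crimp_protocol(start_diameter = 22, min_diameter = 10,
                          release_to = 22,
                          n_steps_load = 12000L, n_steps_unload = 12000L)
  cv <- run_crimp_release(ds, proto,
                          cfg = solver_config(damping_stent = 5000,
                                              damping_graft = 2000,
                                              visc = 0.2))
  expect_equal(attr(cv, "outcome"), "ok")
  expect_gt(max(cv$force), 0)
})

test_that("tracking deployment stages arrive in order with tip capture", {
  ds <- apply_prestress(tiny_device(), n_steps = 8000L)
  proto <- deployment_protocol(
    "tracking", catheter_radius = 4.5, vessel_radius = 9,
    advance = 40,
    n_steps = list(crimp = 6000L, track = 6000L, deploy = 8000L,
                   release = 6000L), track_segments = 4L)
  run <- run_deployment(ds, proto)
  expect_equal(run$outcome, "Positive")
  expect_named(run$stages, c("crimped", "tracked", "first_ring", "half_body",
                             "full_body", "final"))
  # the bare-ring proximal apexes stay captured until the final phase:
  # identical positions in every unsheathing stage, then released
  pin <- run$stages$full_body$beam$rings[[1]]$apex_prox
  expect_equal(run$stages$full_body$x[pin, ],
               run$stages$first_ring$x[pin, ], tolerance = 1e-9)
  expect_gt(max(abs(run$stages$final$x[pin, ] -
                    run$stages$full_body$x[pin, ])), 0.05)
  # rings expand toward the vessel after release
  d_final <- measure_diameter(
    run$stages$final$x[run$stages$final$beam$rings[[3]]$nodes, , drop = FALSE])
  expect_gt(d_final, 2 * proto$catheter_radius)
})

test_that("deployment trajectories are bit-reproducible", {
  ds <- apply_prestress(tiny_device(), n_steps = 4000L)
  proto <- deployment_protocol(
    "tracking", catheter_radius = 4.5, vessel_radius = 9, advance = 30,
    n_steps = list(crimp = 2000L, track = 2000L, deploy = 3000L,
                   release = 2000L), track_segments = 2L)
  r1 <- run_deployment(ds, proto)
  r2 <- run_deployment(ds, proto)
  expect_identical(r1$stages$final$x, r2$stages$final$x)
})
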