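spec_a8 <- ring_preset("deviceA_8peaks")
proto_a <- crimp_protocol(start_diameter = 36, min_diameter = 5)
p2 <- nitinol_preset("valiant_captivia_table2")

toy_curve <- function(f_load, f_unload, d = c(10, 15, 20, 25, 30)) {
  out <- rbind(data.frame(diameter = d, force = f_load, phase = "loading"),
               data.frame(diameter = d, force = f_unload, phase = "unloading"))
  class(out) <- c("force_diameter_curve", "data.frame")
  out
}

test_that("curve percent error matches hand-computed cases", {
  ref <- toy_curve(c(10, 8, 6, 4, 2), c(5, 4, 3, 2, 1))
  expect_equal(curve_percent_error(ref, ref, c(10, 30))$mean, c(0, 0))
  expect_equal(curve_percent_error(ref, ref, c(10, 30))$sd, c(0, 0))
  scaled <- ref; scaled$force <- 1.05 * scaled$force
  e <- curve_percent_error(scaled, ref, c(10, 30))
  expect_equal(e$mean, c(5, 5), tolerance = 1e-9)
  expect_equal(e$sd, c(0, 0), tolerance = 1e-9)
  # piecewise toy with known offsets: +10 percent on loading only
  sim <- ref
  sim$force[sim$phase == "loading"] <- sim$force[sim$phase == "loading"] * 1.1
  e2 <- curve_percent_error(sim, ref, c(10, 30))
  expect_equal(e2$mean, c(10, 0), tolerance = 1e-9)
  # scale symmetry: multiplying both curves leaves errors unchanged
  sim3 <- sim; ref3 <- ref
  sim3$force <- sim3$force * 7; ref3$force <- ref3$force * 7
  expect_equal(curve_percent_error(sim3, ref3, c(10, 30))$mean,
               e2$mean, tolerance = 1e-12)
  expect_error(curve_percent_error(ref, toy_curve(1:5, 1:5, d = 50:54),
                                   c(10, 30)))
})

test_that("noiseless synthetic curves are recovered exactly", {
  syn0 <- gen_synthetic_curve(p2, spec_a8, proto_a,
                              synth_config(seed = 1, noise_sd_rel = 0))
  fit <- calibrate_nitinol(syn0, spec_a8, proto_a,
                           calibration_config(working_range = c(5.5, 30)))
  expect_rel_equal(fit$params$E_A, 57500, 0.01)
  expect_rel_equal(fit$params$E_M, 47800, 0.01)
  expect_rel_equal(fit$params$sig_SL, 550, 0.01)
  expect_rel_equal(fit$params$sig_EL, 620, 0.01)
  expect_rel_equal(fit$params$sig_SU, 450, 0.01)
  expect_rel_equal(fit$params$sig_EU, 250, 0.01)
  expect_length(fit$bound_warnings, 0)
  # accepted iterations never increase the loss
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
})

test_that("a two-parameter fit identifies the loading plateau", {
  truth <- nitinol_preset("kleinstreuer2008")
  truth$sig_SL <- 520; truth$sig_EL <- 700
  syn <- gen_synthetic_curve(truth, spec_a8, proto_a,
                             synth_config(seed = 2, noise_sd_rel = 0))
  fit <- calibrate_nitinol(syn, spec_a8, proto_a,
                           calibration_config(free = c("sig_SL", "sig_EL"),
                                              working_range = c(5.5, 30)))
  expect_rel_equal(fit$params$sig_SL, 520, 0.01)
  expect_rel_equal(fit$params$sig_EL, 700, 0.01)
})

test_that("starting at the truth converges immediately", {
  start <- nitinol_preset("kleinstreuer2008")
  syn <- gen_synthetic_curve(start, spec_a8, proto_a,
                             synth_config(seed = 3, noise_sd_rel = 0))
  fit <- calibrate_nitinol(syn, spec_a8, proto_a,
                           calibration_config(start = start,
                                              working_range = c(5.5, 30)))
  expect_lt(fit$loss, 1e-10)
  expect_lte(fit$iterations, 2)
})

test_that("the surrogate force tracks the explicit-FE internal energy", {
  # work-conjugate validation: the surrogate's radial force should
  # integrate to the FE model's internal-energy curve on loading
  path <- ring_crimp_path(spec_a8, proto_a, path_params = p2)
  cv <- ring_crimp_surrogate(spec_a8, p2, proto_a, path = path)
  ld <- cv$phase == "loading"
  # compare hysteresis ordering: unloading force below loading force
  d_grid <- seq(8, 28, length.out = 20)
  f_l <- approx(cv$diameter[ld], cv$force[ld], d_grid, ties = mean)$y
  f_u <- approx(cv$diameter[!ld], cv$force[!ld], d_grid, ties = mean)$y
  expect_true(all(f_u <= f_l + 1e-6))
  # and the loading force sits within about a third of the FE plane
  # force over the working range: the FE signal additionally carries
  # damping and friction work, which biases it high on loading
  fe_l <- approx(path$d[ld], path$force_fe[ld], d_grid, ties = mean)$y
  expect_lt(stats::median(abs(f_l - fe_l) / fe_l), 0.4)
  expect_true(stats::median(f_l) < stats::median(fe_l))
})

test_that("surrogate evaluations are deterministic", {
  path <- ring_crimp_path(spec_a8, proto_a, path_params = p2)
  c1 <- ring_crimp_surrogate(spec_a8, p2, proto_a, path = path)
  c2 <- ring_crimp_surrogate(spec_a8, p2, proto_a, path = path)
  expect_identical(c1, c2)
})
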