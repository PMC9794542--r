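p2 <- nitinol_preset("valiant_captivia_table2")

test_that("superelastic plateaus reproduce the calibrated anchor stresses", {
  eps_up <- seq(0, 0.12, by = 1e-5)
  eps_dn <- seq(0.12, 0, by = -1e-5)
  r <- sma_path(c(eps_up, eps_dn[-1]), p2)
  up <- r[seq_along(eps_up), ]
  # forward transformation starts at sig_SL = 550 MPa
  i_on <- which(up$xi > 0)[1]
  expect_equal(up$sig[i_on], 550, tolerance = 1e-3)
  expect_equal(up$eps[i_on], 550 / p2$E_A, tolerance = 1e-2)
  # forward transformation completes at sig_EL = 620 MPa, at the strain
  # sig_EL / E_M + eps_L
  i_full <- which(up$xi >= 1)[1]
  expect_equal(up$sig[i_full], 620, tolerance = 1e-2)
  expect_equal(up$eps[i_full], 620 / p2$E_M + p2$eps_L, tolerance = 1e-3)
  # transformation strain between plateau ends, elastic part removed
  inel <- (up$eps[i_full] - up$eps[i_on]) -
    (up$sig[i_full] / p2$E_M - up$sig[i_on] / p2$E_A)
  expect_equal(inel, 0.063, tolerance = 1e-3)
  # reverse plateau spans sig_SU = 450 down to sig_EU = 250
  dn <- r[-seq_along(eps_up), ]
  i_rs <- which(dn$xi < 1)[1]
  expect_equal(dn$sig[i_rs], 450, tolerance = 1e-2)
  i_re <- utils::tail(which(dn$xi > 0), 1)
  expect_equal(dn$sig[i_re], 250, tolerance = 1e-2)
  # full recovery: zero stress, zero strain, zero martensite at the end
  expect_equal(utils::tail(dn$sig, 1), 0, tolerance = 1e-6)
  expect_equal(utils::tail(dn$xi, 1), 0, tolerance = 1e-9)
})

test_that("loading/unloading loop closes with non-negative hysteresis area", {
  eps <- c(seq(0, 0.1, by = 1e-4), seq(0.1, 0, by = -1e-4))
  r <- sma_path(eps, p2)
  area <- -sum(diff(r$eps) * (utils::head(r$sig, -1) + utils::tail(r$sig, -1)) / 2) * -1
  # signed loop integral: load work minus unload work
  w <- sum(diff(r$eps) * (utils::head(r$sig, -1) + utils::tail(r$sig, -1)) / 2)
  expect_gt(w, 0)
  expect_equal(utils::tail(r$sig, 1), 0, tolerance = 1e-6)
})

test_that("the update is rate-independent and monotone on loading", {
  eps_c <- seq(0, 0.09, by = 3e-4)
  eps_f <- seq(0, 0.09, by = 3e-5)
  rc <- sma_path(eps_c, p2)
  rf <- sma_path(eps_f, p2)
  expect_lt(max(abs(rc$sig - rf$sig[seq(1, nrow(rf), by = 10)])), 1e-9)
  expect_true(all(diff(rc$sig) >= -1e-9))
})

test_that("compression onset scales with (1 + alpha)", {
  r <- sma_path(seq(0, -0.05, by = -1e-5), p2)
  i_on <- which(r$xi > 0)[1]
  expect_equal(r$sig[i_on], -550 * (1 + p2$alpha), tolerance = 1e-3)
})

test_that("inner unload/reload cycles between the plateaus are elastic", {
  # load to plateau midpoint, unload a little, reload: the excursion
  # must ride an elastic branch (dense-increment oracle = same path at
  # 10x resolution)
  eps <- c(seq(0, 0.04, by = 1e-4), seq(0.04, 0.035, by = -1e-4),
           seq(0.035, 0.045, by = 1e-4))
  r1 <- sma_path(eps, p2)
  eps10 <- c(seq(0, 0.04, by = 1e-5), seq(0.04, 0.035, by = -1e-5),
             seq(0.035, 0.045, by = 1e-5))
  r10 <- sma_path(eps10, p2)
  expect_equal(utils::tail(r1$sig, 1), utils::tail(r10$sig, 1),
               tolerance = 1e-9)
  # the small unload drops stress at a modulus between E_M and E_A
  i0 <- length(seq(0, 0.04, by = 1e-4))
  drop <- (r1$sig[i0] - r1$sig[i0 + 10]) / (r1$eps[i0] - r1$eps[i0 + 10])
  expect_gt(drop, p2$E_M * 0.9)
  expect_lt(drop, p2$E_A * 1.1)
})

test_that("fabric law is plane-stress in tension and dead in compression", {
  fp <- fabric_params()
  expect_equal(fabric_uniaxial(0.01, fp), 10.8, tolerance = 1e-9)
  # equibiaxial compression carries nothing at factor 0
  out <- fabric_update(c(-0.02, -0.02, 0), fp)
  expect_equal(out$stress, c(0, 0, 0))
  # factor 1 recovers the classical isotropic plane-stress answer
  fp1 <- fabric_params(compressive_stiffness_factor = 1)
  e <- c(-0.01, 0.004, 0.003)
  out1 <- fabric_update(e, fp1)
  c1 <- fp1$E_long / (1 - fp1$nu^2)
  expect_equal(out1$stress,
               c(c1 * (e[1] + fp1$nu * e[2]), c1 * (e[2] + fp1$nu * e[1]),
                 c1 * (1 - fp1$nu) / 2 * e[3]), tolerance = 1e-9)
  # principal stresses never negative at factor 0 (random strain states)
  set.seed(42)
  for (i in 1:50) {
    e <- stats::rnorm(3, 0, 0.05)
    pr <- fabric_update(e, fp)$principal
    expect_true(all(pr >= -1e-12))
  }
})

test_that("linear elastic update is exactly E * eps", {
  expect_equal(linear_elastic_update(0.01, 57500), 575)
  expect_equal(linear_elastic_update(0.1, 1.84), 0.184)
  expect_equal(linear_elastic_update(0, 1000), 0)
  expect_error(linear_elastic_update(0.1, -1))
})

test_that("parameter validation catches impossible sets", {
  expect_error(nitinol_params(E_A = 57500, E_M = 47800, sig_SL = 550,
                              sig_EL = 500, sig_SU = 450, sig_EU = 250,
                              eps_L = 0.063))
  expect_error(sma_update(NaN, params = p2))
  expect_error(fabric_update(c(NA, 0, 0), fabric_params()))
})
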