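spec_a8 <- ring_preset("deviceA_8peaks")
proto_a <- crimp_protocol(start_diameter = 36, min_diameter = 5)
p2 <- nitinol_preset("valiant_captivia_table2")

test_that("synthetic curves are seeded and noise-calibrated", {
  c0 <- gen_synthetic_curve(p2, spec_a8, proto_a,
                            synth_config(seed = 1, noise_sd_rel = 0))
  base <- ring_crimp_surrogate(spec_a8, p2, proto_a)
  expect_equal(c0$force, base$force)
  c1 <- gen_synthetic_curve(p2, spec_a8, proto_a, synth_config(seed = 9))
  c2 <- gen_synthetic_curve(p2, spec_a8, proto_a, synth_config(seed = 9))
  expect_identical(c1, c2)
  c3 <- gen_synthetic_curve(p2, spec_a8, proto_a, synth_config(seed = 10))
  expect_false(identical(c1$force, c3$force))
  # 1 percent multiplicative noise: mean |relative deviation| is the
  # half-normal expectation sigma * sqrt(2/pi)
  ok <- base$force > 1
  rel <- abs(c1$force[ok] - base$force[ok]) / base$force[ok]
  expect_rel_equal(mean(rel), 0.01 * sqrt(2 / pi), 0.25)
})

test_that("pseudo-segmentation is seeded and area-stable", {
  r8 <- make_ring(ring_preset("deviceA_8peaks"))
  st <- list(x = r8$nodes, beam = r8)
  s0 <- gen_pseudo_segmentation(st, synth_config(seed = 4, perturbation_sd = 0))
  expect_equal(s0[[1]]$polyline, r8$nodes)
  a0 <- opening_area(s0[[1]]$apexes)
  s1 <- gen_pseudo_segmentation(st, synth_config(seed = 4, perturbation_sd = 0.2))
  s2 <- gen_pseudo_segmentation(st, synth_config(seed = 4, perturbation_sd = 0.2))
  expect_identical(s1, s2)
  # 0.2 mm noise on a 35 mm ring moves the enclosed area by well under
  # 3 percent (area is first-order insensitive to zero-mean noise)
  errs <- vapply(1:20, function(s) {
    sg <- gen_pseudo_segmentation(st, synth_config(seed = s,
                                                   perturbation_sd = 0.2))
    abs(opening_area(sg[[1]]$apexes) - a0) / a0 * 100
  }, numeric(1))
  expect_lt(stats::quantile(errs, 0.9), 3)
})

test_that("curve and point CSV files round-trip losslessly", {
  cv <- ring_crimp_surrogate(spec_a8, p2, proto_a)
  f <- tempfile(fileext = ".csv")
  write_curve_csv(cv, f)
  back <- read_curve_csv(f)
  expect_equal(back$diameter, cv$diameter, tolerance = 1e-12)
  expect_equal(back$force, cv$force, tolerance = 1e-12)
  expect_equal(back$phase, cv$phase)
  pts <- matrix(stats::rnorm(30), 10, 3)
  f2 <- tempfile(fileext = ".csv")
  write_points_csv(pts, f2)
  expect_equal(read_points_csv(f2), pts, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("configuration JSON round-trips typed objects", {
  f <- tempfile(fileext = ".json")
  write_config_json(p2, f)
  expect_equal(read_config_json(f), p2)
  write_config_json(spec_a8, f)
  expect_equal(read_config_json(f), spec_a8)
  write_config_json(proto_a, f)
  expect_equal(read_config_json(f), proto_a)
  write_config_json(device_preset("desk"), f)
  dev2 <- read_config_json(f)
  expect_equal(make_device(dev2)$beam$nodes,
               make_device(device_preset("desk"))$beam$nodes)
})

test_that("VTK and STL exports are well formed and STL reads back", {
  dev <- make_device(device_preset("desk"))
  fv <- tempfile(fileext = ".vtk")
  write_vtk(dev$beam, fv)
  lines <- readLines(fv)
  expect_equal(lines[4], "DATASET POLYDATA")
  expect_match(lines[5], sprintf("POINTS %d", nrow(dev$beam$nodes)))
  fs <- tempfile(fileext = ".stl")
  write_stl(dev$membrane, fs)
  back <- read_stl(fs)
  expect_equal(nrow(back$triangles), nrow(dev$membrane$triangles))
  expect_equal(nrow(back$nodes), nrow(dev$membrane$nodes))
})

test_that("the command-line interface runs its light commands", {
  out <- tempfile()
  expect_equal(suppressMessages(
    tevar_cli(c("synth", "--out", out, "--seed", "3"))), 0L)
  expect_true(file.exists(file.path(out, "synthetic_curve.csv")))
  # metrics on identical point sets reports zero error
  pts <- file.path(out, "ring.csv")
  write_points_csv(cbind(17 * cos(seq(0, 2 * pi, length.out = 17)[-17]),
                         17 * sin(seq(0, 2 * pi, length.out = 17)[-17]), 0),
                   pts)
  expect_equal(suppressMessages(
    tevar_cli(c("metrics", "--sim", pts, "--ref", pts, "--out", out))), 0L)
  met <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(met$oa_percent_error, 0)
  expect_equal(met$max_strut_distance, 0)
  # device meshing export
  expect_equal(suppressMessages(
    tevar_cli(c("generate", "--device", "desk", "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "graft.stl")))
  # unknown command exits non-zero
  expect_equal(suppressMessages(tevar_cli("frobnicate")), 1L)
})
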