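circle_points <- function(n, r, jitter = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th), 0) + jitter
}

test_that("spline opening area recovers a circle to 0.1 percent", {
  pts <- circle_points(16, 17)
  expect_rel_equal(opening_area(pts), pi * 17^2, 1e-3)
  # rigid-body motion invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pts %*% t(R) + matrix(c(5, -3, 11), 16, 3, byrow = TRUE)
  expect_rel_equal(opening_area(moved), opening_area(pts), 1e-9)
})

test_that("opening area scales quadratically and is deterministic", {
  pts <- circle_points(12, 10, jitter = 0)
  a1 <- opening_area(pts)
  expect_rel_equal(opening_area(pts * 2), 4 * a1, 1e-9)
  # 4-point square: the periodic spline overshoots the polygon
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  a_sq <- opening_area(sq)
  expect_gt(a_sq, 100)
  expect_equal(opening_area(sq), a_sq, tolerance = 1e-9)
})

test_that("spline area agrees with the shoelace polygon for convex sets", {
  # a smooth convex contour sampled at n points exceeds its inscribed
  # polygon by about 2 pi^2 / (3 n^2); the two agree to 2 percent once
  # n >= 24, and the spline always lies outside the polygon
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(24:40, 1)
    th0 <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    th <- sort(th0 + stats::runif(n, -0.1, 0.1) * 2 * pi / n)
    r <- stats::runif(1, 5, 20) * (1 + stats::runif(n, -0.03, 0.03))
    pts <- cbind(r * cos(th), r * sin(th), 0)
    poly <- 0.5 * abs(sum(pts[, 1] * c(pts[-1, 2], pts[1, 2]) -
                          c(pts[-1, 1], pts[1, 1]) * pts[, 2]))
    a <- opening_area(pts)
    expect_rel_equal(a, poly, 0.02)
    expect_gte(a, poly * 0.999)
  }
  # at the 8-apex sampling of a peaks ring the overshoot is the
  # documented ~10 percent of the inscribed octagon
  th8 <- seq(0, 2 * pi, length.out = 9)[-9]
  pts8 <- cbind(10 * cos(th8), 10 * sin(th8), 0)
  poly8 <- 0.5 * abs(sum(pts8[, 1] * c(pts8[-1, 2], pts8[1, 2]) -
                         c(pts8[-1, 1], pts8[1, 1]) * pts8[, 2]))
  expect_rel_equal(opening_area(pts8) / poly8, pi * 100 / poly8, 0.02)
})

test_that("OA percent errors and their summary are consistent", {
  oa <- oa_percent_error(c(100, 110, 90), c(100, 100, 100))
  expect_equal(oa$percent_error, c(0, 10, 10))
  s <- attr(oa, "summary")
  expect_equal(unname(s["mean"]), 20 / 3, tolerance = 1e-12)
  expect_equal(unname(s["sd"]), stats::sd(oa$percent_error))
  expect_equal(unname(s["min"]), 0)
  expect_equal(unname(s["max"]), 10)
  # identical inputs give all zeros; uniform scaling gives constant error
  expect_equal(oa_percent_error(c(50, 60), c(50, 60))$percent_error, c(0, 0))
  oa2 <- oa_percent_error(1.02 * c(50, 60), c(50, 60))
  expect_equal(oa2$percent_error, c(2, 2), tolerance = 1e-9)
  expect_error(oa_percent_error(c(1, 2), c(1, 2, 3)))
})

test_that("maximum strut distance matches a brute-force scan", {
  th <- seq(0, 2 * pi, length.out = 40)
  zig <- cbind(10 * cos(th), 10 * sin(th), 2 * sign(sin(8 * th)))
  smooth <- cbind(10 * cos(th), 10 * sin(th), 2 * sin(8 * th))
  expect_equal(max_strut_distance(zig, zig), 0)
  moved <- sweep(zig, 2, c(1, 0, 0), "+")
  expect_equal(max_strut_distance(moved, zig), 1, tolerance = 1e-9)
  # O(n^2) point-to-segment oracle
  brute <- max(vapply(seq_len(nrow(zig)), function(i) {
    p <- zig[i, ]
    min(vapply(seq_len(nrow(smooth) - 1), function(j) {
      a <- smooth[j, ]; b <- smooth[j + 1, ]
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((a + t * ab - p)^2))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(max_strut_distance(zig, smooth), brute, tolerance = 1e-12)
})

test_that("deployed length follows the centerline arc", {
  devC <- make_device(device_preset("C"))
  st <- list(x = devC$beam$nodes, beam = devC$beam)
  expect_equal(deployed_length(st), 200, tolerance = 1e-6)
  # 5 percent axial compression shortens accordingly
  x2 <- devC$beam$nodes
  x2[, 3] <- x2[, 3] * 0.95
  expect_equal(deployed_length(list(x = x2, beam = devC$beam)), 190,
               tolerance = 1e-6)
  # along a curved centerline the arc extent is at least the chord
  cl <- make_arch_centerline()
  fr <- tevarsim:::centerline_frames(cl)
  xb <- tevarsim:::track_map(devC$beam$nodes * 0.2, fr, advance = 60)
  arc <- deployed_length(list(x = xb, beam = devC$beam), cl)
  chord <- sqrt(sum((xb[which.max(devC$beam$nodes[, 3]), ] -
                     xb[which.min(devC$beam$nodes[, 3]), ])^2))
  expect_gte(arc, chord * 0.99)
})

test_that("apex extraction finds one proximal apex per peak", {
  r8 <- make_ring(ring_preset("deviceA_8peaks"))
  st <- list(x = r8$nodes, beam = r8)
  ap <- extract_apexes(st, 1)
  expect_equal(nrow(ap$points), 8)
  expect_true(all(abs(ap$points[, 3] - max(r8$nodes[, 3])) < 1e-9))
  # thin ring: sixteen uniform samples
  rt <- make_ring(ring_preset("thin34"))
  ap_t <- extract_apexes(list(x = rt$nodes, beam = rt), 1)
  expect_equal(nrow(ap_t$points), 16)
  # small perturbations do not change the apex set by more than a node
  set.seed(3)
  xp <- r8$nodes + matrix(stats::rnorm(length(r8$nodes), 0, 0.05),
                          ncol = 3)
  ap_p <- suppressWarnings(extract_apexes(list(x = xp, beam = r8), 1))
  expect_equal(nrow(ap_p$points), 8)
  d <- vapply(seq_len(8), function(i)
    min(sqrt(rowSums(sweep(ap$points, 2, ap_p$points[i, ])^2))),
    numeric(1))
  expect_lt(max(d), 2)  # within one 1 mm element of the unperturbed apex
})
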