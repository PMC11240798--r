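test_that("polygon centroid matches closed forms and is orientation/start invariant", {
  sq <- contour_slice(0, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(polygon_centroid(sq)), c(0.5, 0.5))

  circ <- circle_contour(0, r = 10, center = c(3, -2), n = 360)
  expect_equal(unname(polygon_centroid(circ)), c(3, -2), tolerance = 1e-9)

  tri <- contour_slice(0, rbind(c(0, 0), c(6, 0), c(0, 3)))
  expect_equal(unname(polygon_centroid(tri)), c(2, 1))

  # invariant to ordering direction and starting vertex
  v <- star_polygon(25)
  c0 <- polygon_centroid(v)
  expect_equal(polygon_centroid(v[nrow(v):1, ]), c0)
  expect_equal(polygon_centroid(v[c(7:nrow(v), 1:6), ]), c0)
})

test_that("degenerate polygons are rejected", {
  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "zero-area")
  expect_error(contour_slice(0, rbind(c(0, 0), c(1, 1))), "3 distinct")
})

test_that("axis fit recovers collinear centroids exactly and has closed-form OLS", {
  z <- 0:9
  cents <- cbind(1 + 0.5 * z, rep(-2, 10))
  ax <- fit_axis(cents, z)
  expect_equal(ax$x_intercept, 1, tolerance = 1e-12)
  expect_equal(ax$x_slope, 0.5, tolerance = 1e-12)
  expect_equal(ax$y_intercept, -2, tolerance = 1e-12)
  expect_equal(ax$y_slope, 0, tolerance = 1e-12)

  # symmetric +/- delta x-perturbations at paired z leave the slope alone
  zp <- c(0, 0, 4, 4); delta <- 0.7
  axp <- fit_axis(cbind(c(1 - delta, 1 + delta, 3 - delta, 3 + delta),
                        rep(0, 4)), zp)
  expect_equal(axp$x_slope, 0.5, tolerance = 1e-12)

  # three points (z, x) = (0,0), (1,1), (2,1): slope 1/2, intercept 1/6
  ax3 <- fit_axis(cbind(c(0, 1, 1), c(0, 0, 0)), c(0, 1, 2))
  expect_equal(ax3$x_slope, 0.5, tolerance = 1e-12)
  expect_equal(ax3$x_intercept, 1 / 6, tolerance = 1e-12)
})

test_that("axis fit is invariant to slice ordering and rejects a single z", {
  set.seed(42)
  z <- 0:7
  cents <- cbind(rnorm(8), rnorm(8))
  ax <- fit_axis(cents, z)
  perm <- sample(8)
  axp <- fit_axis(cents[perm, ], z[perm])
  expect_equal(unclass(ax), unclass(axp), tolerance = 1e-12)
  expect_error(fit_axis(cents, rep(3, 8)), "distinct")
})

test_that("beam casting matches ray-circle closed forms", {
  circ <- circle_contour(0, r = 10, n = 7200)  # fine enough for 1e-4 mm
  for (a in c(0, 37, 90, 135, 179))
    expect_equal(cast_beam(c(0, 0), a, circ), 10, tolerance = 1e-4)
  # origin (3, 0): exit along (-1, 0) at (-10, 0) -> length 13
  expect_equal(cast_beam(c(3, 0), 0, circ), 13, tolerance = 1e-4)
  # origin (3, 0), direction (0, 1): chord length sqrt(100 - 9)
  expect_equal(cast_beam(c(3, 0), 90, circ), sqrt(91), tolerance = 1e-4)
})

test_that("beam casting flags an outside origin and takes the outermost crossing", {
  circ <- circle_contour(0, r = 10)
  out <- cast_beam(c(20, 0), 90, circ)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "outside")

  # non-convex: a radial notch makes the ray cross three times; the skin
  # surface seen from outside is the outermost crossing
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- rep(10, 360)
  notch <- abs(th - pi / 2) < 0.15
  r[notch] <- 4
  poly <- contour_slice(0, cbind(r * cos(th), r * sin(th)))
  # beam at 90 deg has direction (0, 1): hits the notch floor at ~4 mm
  expect_equal(cast_beam(c(0, 0), 90, poly), 4, tolerance = 0.05)
  # a beam near the notch edge keeps the outer radius
  expect_equal(cast_beam(c(0, 0), 70, poly), 10, tolerance = 0.05)
})

test_that("beam casting agrees with the fine point-in-polygon bisection oracle", {
  set.seed(7)
  for (i in 1:25) {
    v <- star_polygon(n = sample(10:60, 1))
    cs <- contour_slice(0, v)
    for (a in runif(3, 0, 180)) {
      got <- cast_beam(c(0, 0), a, cs)
      expect_equal(got, oracle_beam_length(c(0, 0), a, cs$vertices),
                   tolerance = 1e-6)
    }
  }
})

test_that("beam-length field has the contract shape and is constant for a rigid torso", {
  cfg <- phantom_config(slice_zs = c(0, 5, 10),
                        amplitude_field = function(theta, z)
                          rep_len(0, length(theta)))
  torso <- generate_torso(cfg)
  fld <- build_beam_length_field(torso$phases,
                                 fit_axis(matrix(0, 3, 2), c(0, 5, 10)))
  expect_identical(dim(fld$lengths), c(10L, 3L, 180L))
  expect_true(all(fld$valid))
  for (p in 2:10)
    expect_equal(fld$lengths[p, , ], fld$lengths[1, , ], tolerance = 1e-12)
})

test_that("TS centroid trajectory is the area-weighted slice mean", {
  one <- lapply(1:10, function(p) list(circle_contour(100, r = 5)))
  expect_equal(ts_centroid_z(one)$z_per_phase, rep(100, 10))

  two <- lapply(1:4, function(p)
    list(circle_contour(100, r = 5), circle_contour(102, r = 5)))
  expect_equal(ts_centroid_z(two)$z_per_phase, rep(101, 4))

  # areas 1 and 3 at z = 100 and 104 -> weighted mean 103
  r1 <- sqrt(1 / pi); r3 <- sqrt(3 / pi)
  aw <- lapply(1:3, function(p)
    list(circle_contour(100, r = r1, n = 5000),
         circle_contour(104, r = r3, n = 5000)))
  expect_equal(ts_centroid_z(aw)$z_per_phase, rep(103, 3), tolerance = 1e-4)

  expect_error(ts_centroid_z(list(list(circle_contour(1, 2)), list())),
               "empty")
})
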