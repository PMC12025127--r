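test_that("plane_from_points contains its points and has a deterministic normal", {
  p <- plane_from_points(c(0, 0, -398.3), c(1, 0, -398.3), c(0, 1, -398.3))
  expect_equal(p$normal, c(0, 0, 1))
  expect_equal(sum((c(0, 1, -398.3) - p$point) * p$normal), 0, tolerance = 1e-12)

  p0 <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(p0$normal, c(0, 0, 1))

  set.seed(1)
  for (i in 1:50) {
    pts <- matrix(rnorm(9, sd = 10), 3, 3)
    pl <- plane_from_points(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(vapply(1:3, function(k) sum((pts[k, ] - pl$point) * pl$normal), numeric(1)),
                 rep(0, 3), tolerance = 1e-9)
    expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
    expect_gte(pl$normal[3], 0)
  }
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "rgbdgaze_degenerate")
  expect_error(plane_from_points(c(1, 2, 3), c(1, 2, 3), c(0, 0, 1)),
               class = "rgbdgaze_degenerate")
})

test_that("ray_plane_intersection hits forward, misses parallel and backward", {
  board <- plane_from_points(c(0, 0, -398.3), c(1, 0, -398.3), c(0, 1, -398.3))
  expect_equal(ray_plane_intersection(gaze_ray(c(0, 0, 0), c(0, 0, -1)), board),
               c(0, 0, -398.3))
  expect_null(ray_plane_intersection(gaze_ray(c(0, 0, 0), c(1, 0, 0)), board))
  expect_null(ray_plane_intersection(gaze_ray(c(0, 0, 0), c(0, 0, 1)), board))
  oblique <- ray_plane_intersection(
    gaze_ray(c(0, 0, 0), c(1, 0, -1)),
    plane_from_points(c(0, 0, -2), c(1, 0, -2), c(0, 1, -2))
  )
  expect_equal(oblique, c(2, 0, -2), tolerance = 1e-12)

  # residual property: the returned point satisfies the plane equation
  set.seed(2)
  for (i in 1:100) {
    pl <- plane_from_points(rnorm(3, sd = 5), rnorm(3, sd = 5), rnorm(3, sd = 5))
    r <- gaze_ray(rnorm(3, sd = 5), rnorm(3))
    hit <- ray_plane_intersection(r, pl)
    if (!is.null(hit)) {
      expect_lt(abs(sum((hit - pl$point) * pl$normal)), 1e-9)
    }
  }
})

test_that("ray_sphere_hit returns the nearest forward intersection, tangent included", {
  r <- gaze_ray(c(0, 0, 0), c(0, 0, -1))
  expect_equal(ray_sphere_hit(r, c(0, 0, -100), 12), list(hit = TRUE, point = c(0, 0, -88)))
  expect_false(ray_sphere_hit(r, c(13, 0, -100), 12)$hit)
  tangent <- ray_sphere_hit(r, c(12, 0, -100), 12)
  expect_true(tangent$hit)
  expect_equal(tangent$point, c(0, 0, -100), tolerance = 1e-6)
})

test_that("ray_sphere_hit agrees with a brute-force grid oracle on random pairs", {
  set.seed(3)
  for (i in 1:1000) {
    o <- rnorm(3, sd = 20)
    d <- random_unit()
    ctr <- rnorm(3, sd = 60)
    rad <- runif(1, 2, 30)
    got <- ray_sphere_hit(gaze_ray(o, d), ctr, rad)$hit
    want <- ray_sphere_brute(o, d, ctr, rad)
    # the grid oracle can only miss razor-thin grazes; tolerate those
    if (got != want) {
      oc <- o - ctr
      b <- sum(d * oc)
      disc <- b^2 - sum(oc * oc) + rad^2
      expect_lt(abs(disc), 1e-2)
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("angular_error matches canonical pairs and is symmetric, scale-free, bounded", {
  expect_equal(angular_error(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_error(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_error(angular_error(c(0, 0, 0), c(1, 0, 0)), class = "rgbdgaze_invalid_input")
  set.seed(4)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3)
    th <- angular_error(a, b)
    expect_gte(th, 0); expect_lte(th, 180)
    expect_equal(th, angular_error(b, a))
    expect_equal(th, angular_error(5.5 * a, 0.02 * b), tolerance = 1e-9)
  }
})

test_that("backproject inverts projection for points with positive depth", {
  cam <- camera_model(fx = 500, fy = 500, cx = 320, cy = 240)
  expect_equal(backproject(320, 240, 100, cam), c(0, 0, 100))
  cam0 <- camera_model(500, 500, 0, 0)
  expect_equal(backproject(50, 0, 100, cam0), c(10, 0, 100))
  expect_error(backproject(0, 0, -1, cam), class = "rgbdgaze_invalid_input")
  set.seed(5)
  pts <- cbind(rnorm(200, sd = 50), rnorm(200, sd = 50), runif(200, 10, 400))
  uvd <- project_point(pts, cam)
  back <- backproject(uvd$u, uvd$v, uvd$depth, cam)
  expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
})
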