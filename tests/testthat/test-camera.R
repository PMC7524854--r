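test_that("project: principal point, projective invariance, hand-computed", {
  cam <- pinhole_camera(800, 900, 960, 540, c(1920L, 1080L))
  # any point on the optical axis lands on the principal point
  for (z in c(10, 100, 1000)) {
    expect_equal(project(cam, c(0, 0, z)), c(960, 540))
  }
  # scaling a camera-frame point leaves the pixel unchanged
  p <- c(20, -14, 130)
  expect_equal(project(cam, p), project(cam, 3.7 * p), tolerance = 1e-9)
  # pinhole formula by hand: fx = fy = 1000, principal point at 0
  cam0 <- pinhole_camera(1000, 1000, 0, 0, c(4000L, 4000L))
  expect_equal(project(cam0, c(10, -5, 200)), c(50, -25))
  expect_error(project(cam, c(0, 0, -5)), class = "liverreg_behind_camera")
  expect_error(project(cam, c(0, 0, 0)), class = "liverreg_behind_camera")
})

test_that("triangulate: noiseless round trip over random points", {
  rig <- default_rig()
  set.seed(3)
  for (i in 1:50) {
    p <- c(runif(1, -40, 40), runif(1, -30, 30), runif(1, 80, 300))
    uv_l <- project(rig$left, p)
    uv_r <- project(rig$right, p)
    q <- triangulate(rig, uv_l, uv_r)
    expect_lt(sqrt(sum((q - p)^2)), 1e-6)
  }
})

test_that("triangulate: rectified-rig depth matches z = f b / d", {
  rig <- rectified_rig(fx = 1000, baseline_mm = 4)
  # disparity 20 px at the principal row
  p <- triangulate(rig, c(960 + 20, 540), c(960, 540))
  expect_equal(p[3], 1000 * 4 / 20, tolerance = 1e-9)  # 200 mm
  # and the closed form holds for other disparities
  for (d in c(5, 10, 40)) {
    p <- triangulate(rig, c(960 + d, 540), c(960, 540))
    expect_equal(p[3], 1000 * 4 / d, tolerance = 1e-9)
  }
})

test_that("triangulate: degenerate and out-of-bounds input", {
  rig <- rectified_rig()
  # zero disparity -> parallel rays
  expect_error(triangulate(rig, c(960, 540), c(960, 540)),
               class = "liverreg_degenerate_geometry")
  expect_error(triangulate(rig, c(-5, 540), c(960, 540)),
               class = "liverreg_invalid_geometry")
})

test_that("baseline doubling reduces median triangulation error under noise", {
  # Monte-Carlo with a fixed seed: same points and pixel noise, two rigs
  err_for_baseline <- function(b) {
    rig <- rectified_rig(fx = 1000, baseline_mm = b)
    set.seed(42)
    errs <- replicate(500, {
      p <- c(runif(1, -30, 30), runif(1, -20, 20), runif(1, 100, 250))
      uv_l <- project(rig$left, p) + rnorm(2, 0, 0.5)
      uv_r <- project(rig$right, p) + rnorm(2, 0, 0.5)
      q <- tryCatch(triangulate(rig, uv_l, uv_r), error = function(e) NULL)
      if (is.null(q)) NA_real_ else sqrt(sum((q - p)^2))
    })
    median(errs, na.rm = TRUE)
  }
  expect_lt(err_for_baseline(8), err_for_baseline(4))
})

test_that("triangulation residual is zero without noise, positive with", {
  rig <- default_rig()
  p <- c(12, -8, 150)
  uv_l <- project(rig$left, p)
  uv_r <- project(rig$right, p)
  q0 <- triangulate(rig, uv_l, uv_r)
  expect_lt(sqrt(sum((q0 - p)^2)), 1e-6)
  set.seed(1)
  q1 <- triangulate(rig, uv_l + rnorm(2, 0, 1), uv_r + rnorm(2, 0, 1))
  expect_gt(sqrt(sum((q1 - p)^2)), 0)
})

test_that("reconstruct_patch: labels conserved, degenerates counted", {
  rig <- rectified_rig()
  set.seed(9)
  pts <- cbind(runif(100, -30, 30), runif(100, -20, 20), runif(100, 100, 250))
  labels <- rep(c(0L, 1L), 50)
  uv_l <- t(apply(pts, 1, function(p) project(rig$left, p)))
  uv_r <- t(apply(pts, 1, function(p) project(rig$right, p)))
  corr <- data.frame(ul = uv_l[, 1], vl = uv_l[, 2],
                     ur = uv_r[, 1], vr = uv_r[, 2], label = labels)
  cloud <- reconstruct_patch(rig, corr)
  expect_equal(n_points(cloud), 100)
  expect_equal(attr(cloud, "dropped"), 0)
  # label histogram carried through
  expect_equal(as.vector(table(cloud$labels)), as.vector(table(labels)))
  expect_lt(max(abs(cloud$points - pts)), 1e-6)
  # force 10 degenerate pairs (zero disparity = parallel rays)
  bad <- data.frame(ul = rep(960, 10), vl = rep(540, 10),
                    ur = rep(960, 10), vr = rep(540, 10), label = 0L)
  cloud2 <- reconstruct_patch(rig, rbind(corr, bad))
  expect_equal(n_points(cloud2), 100)
  expect_equal(attr(cloud2, "dropped"), 10)
  # all degenerate -> error
  expect_error(reconstruct_patch(rig, bad),
               class = "liverreg_empty_reconstruction")
})

test_that("rig JSON and correspondence CSV round trips", {
  rig <- default_rig(fx = 1100, baseline_mm = 5.5, verge_deg = 2)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  rig_to_json(rig, f)
  rig2 <- rig_from_json(f)
  expect_equal(rig2$baseline_mm, rig$baseline_mm, tolerance = 1e-12)
  expect_equal(rig2$left$pose$rotation, rig$left$pose$rotation,
               tolerance = 1e-12)
  p <- c(7, 3, 180)
  expect_equal(project(rig2$right, p), project(rig$right, p),
               tolerance = 1e-9)
  corr <- data.frame(ul = c(1.5, 2), vl = c(3, 4), ur = c(5, 6),
                     vr = c(7, 8), label = c(0L, 2L))
  g <- tempfile(fileext = ".csv")
  on.exit(unlink(g), add = TRUE)
  write_correspondences(corr, g)
  expect_equal(read_correspondences(g), corr)
  expect_error(read_correspondences({
    h <- tempfile(fileext = ".csv"); writeLines("a,b\n1,2", h); h
  }), class = "liverreg_schema")
})
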