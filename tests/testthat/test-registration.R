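test_that("kabsch_fit: identity, construct-and-recover, degeneracy", {
  set.seed(1)
  S <- matrix(rnorm(60), ncol = 3) * 30
  T0 <- kabsch_fit(S, S)
  expect_lt(max(abs(T0$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(T0$translation)), 1e-9)
  # recovers random rigid transforms on noiseless correspondences to 1e-9
  for (s in 1:20) {
    T1 <- random_transform(s)
    Tr <- kabsch_fit(S, apply_transform(T1, S))
    expect_lt(max(abs(Tr$rotation - T1$rotation)), 1e-9)
    expect_lt(max(abs(Tr$translation - T1$translation)), 1e-9)
  }
  # collinear source is rank-deficient
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_fit(line, line + 1), class = "liverreg_degenerate_fit")
  expect_error(kabsch_fit(S[1:2, ], S[1:2, ]),
               class = "liverreg_degenerate_fit")
  # never returns a reflection, even for adversarial targets
  Sm <- S; Sm[, 3] <- -Sm[, 3]
  Tf <- kabsch_fit(S, Sm)
  expect_gt(det(Tf$rotation), 0)
})

test_that("kabsch_fit honours weights", {
  set.seed(2)
  S <- matrix(rnorm(45), ncol = 3) * 20
  T1 <- random_transform(5)
  Tgt <- apply_transform(T1, S)
  # corrupt one target point but give it zero weight
  Tgt[1, ] <- Tgt[1, ] + c(50, -30, 20)
  w <- c(0, rep(1, nrow(S) - 1))
  Tr <- kabsch_fit(S, Tgt, weights = w)
  expect_lt(max(abs(Tr$rotation - T1$rotation)), 1e-9)
})

test_that("nearest_correspondences matches the brute-force oracle", {
  set.seed(3)
  src <- matrix(rnorm(300), ncol = 3) * 40
  ref <- matrix(rnorm(3000), ncol = 3) * 40
  got <- nearest_correspondences(src, ref)
  oracle <- liverreg:::nn_bruteforce_r(src, ref)
  expect_equal(got$model_idx, oracle$index, ignore_attr = TRUE)
  expect_equal(got$distance, oracle$distance, tolerance = 1e-12,
               ignore_attr = TRUE)
  # self-pairing at distance zero
  self <- nearest_correspondences(ref[1:50, ], ref, max_dist_mm = 1)
  expect_equal(self$model_idx, 1:50)
  expect_true(all(self$distance == 0))
  # max_dist 0 on disjoint sets -> no correspondences
  expect_error(nearest_correspondences(src + 1000, ref, max_dist_mm = 0),
               class = "liverreg_no_correspondence")
})

test_that("manual_init packages coarse poses and is exact in manual mode", {
  expect_equal(manual_init()$rotation, diag(3))
  expect_equal(manual_init()$translation, c(0, 0, 0))
  # manual mode passthrough contract: the returned pose IS the input pose
  T1 <- manual_init(c(10, -5, 3), c(10, 20, 30))
  expect_equal(T1$translation, c(10, -5, 3))
  expect_equal(T1$rotation,
               rot_z(30 * pi / 180) %*% rot_y(20 * pi / 180) %*%
                 rot_x(10 * pi / 180), tolerance = 1e-12)
  T2 <- manual_init(c(1, 2, 3), random_transform(7))
  expect_equal(T2$rotation, random_transform(7)$rotation)
  expect_error(manual_init(c(0, 0, 0), diag(c(1, 1, -1))),
               class = "liverreg_invalid_pose")
  expect_error(manual_init(c(0, 0, 0), c(1, 2)),
               class = "liverreg_invalid_pose")
})

test_that("icp_register: fixed point on self-sampled cloud", {
  mesh <- make_liver_mesh(seed = 8)
  smp <- sample_mesh_points(mesh, 400, seed = 21)
  cloud <- labeled_point_cloud(smp$points, rep(0L, 400))
  res <- icp_register(cloud, mesh, init = identity_transform(),
                      icp_params(model_sample_count = 5000L))
  expect_lt(res$inlier_rms_mm, 1e-6)
  expect_lte(res$iterations_used, 2)
  expect_true(res$converged)
  expect_equal(res$n_correspondences, 400)
})

test_that("icp_register recovers a noiseless scene pose", {
  sc <- make_scene(seed = 31, n_landmarks = 4)
  cloud <- gate_points(observe_cloud(sc, n_patches = 3, n_points = 300,
                                     seed_base = 310), 0)
  init <- compose(rigid_transform(rot_y(5 * pi / 180), c(10, 0, 0)),
                  sc$true_pose)
  # sub-0.1 mm recovery needs the tangential creep to run its course, so
  # give ICP an offline iteration budget
  res <- icp_register(cloud, sc$liver_mesh, init = init,
                      icp_params(max_iterations = 1000L))
  ctr <- colMeans(sc$liver_mesh$vertices)
  pe <- pose_error(res$transform, sc$true_pose, at = ctr)
  expect_lt(pe$translation_mm, 0.1)
  expect_lt(pe$rotation_deg, 0.1)
  # inlier RMS history is non-increasing
  expect_true(all(diff(res$history) <= 1e-9))
})

test_that("icp_register signals failure far outside the capture range", {
  sc <- make_scene(seed = 32, n_landmarks = 4)
  cloud <- gate_points(observe_cloud(sc, n_patches = 2, n_points = 200,
                                     seed_base = 320), 0)
  init <- compose(rigid_transform(diag(3), c(200, 0, 0)), sc$true_pose)
  err <- tryCatch(
    icp_register(cloud, sc$liver_mesh, init = init,
                 icp_params(failure_rms_mm = 20)),
    liverreg_registration_failure = function(e) e)
  expect_s3_class(err, "liverreg_registration_failure")
  # the condition carries the partial result
  expect_s3_class(err$result, "registration_result")
  expect_error(icp_register(labeled_point_cloud(matrix(numeric(0), ncol = 3),
                                                integer(0)),
                            sc$liver_mesh, identity_transform(),
                            icp_params()),
               class = "liverreg_no_correspondence")
})

test_that("registration result JSON round trips", {
  sc <- make_scene(seed = 33, n_landmarks = 4)
  cloud <- gate_points(observe_cloud(sc, n_patches = 2, n_points = 150,
                                     seed_base = 330), 0)
  res <- icp_register(cloud, sc$liver_mesh, init = sc$true_pose, icp_params())
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  registration_to_json(res, f)
  res2 <- registration_from_json(f)
  expect_equal(res2$transform$rotation, res$transform$rotation,
               tolerance = 1e-12)
  expect_equal(res2$history, res$history, tolerance = 1e-12)
  expect_equal(res2$converged, res$converged)
})
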