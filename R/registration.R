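#' ICP parameters
#'
#' All defaults are engineering choices, surfaced here because the source
#' method names iterative closest point matching but fixes no parameters.
#'
#' @param max_iterations iteration cap (>= 1). The default of 100 mirrors a
#'   bounded intraoperative time budget; exceeding it without meeting the
#'   convergence tolerance is a registration failure. Offline use aiming
#'   for sub-0.1 mm pose recovery should raise it (point-to-point ICP
#'   removes residual tangential error slowly, typically needing a few
#'   hundred iterations on smooth organ surfaces).
#' @param convergence_tol_mm stop when the change in inlier RMS between
#'   iterations falls below this (mm).
#' @param max_correspondence_dist_mm pairs farther than this are discarded.
#' @param model_sample_count number of points sampled uniformly by area
#'   from the model mesh surface.
#' @param failure_rms_mm final inlier RMS above this raises a
#'   registration-failure error (the intraoperative "error message").
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, convergence_tol_mm = 1e-4,
                       max_correspondence_dist_mm = 25,
                       model_sample_count = 20000L, failure_rms_mm = 20) {
  if (max_iterations < 1L || convergence_tol_mm <= 0 ||
      max_correspondence_dist_mm <= 0 || model_sample_count < 3L ||
      failure_rms_mm <= 0) {
    stop_liverreg("schema", "invalid ICP parameters")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol_mm = convergence_tol_mm,
                 max_correspondence_dist_mm = max_correspondence_dist_mm,
                 model_sample_count = as.integer(model_sample_count),
                 failure_rms_mm = failure_rms_mm),
            class = "icp_params")
}

#' Least-squares rigid fit (Kabsch / orthogonal Procrustes)
#'
#' Finds the rigid transform minimising
#' `sum_i w_i || R s_i + t - t_i ||^2` via SVD of the weighted cross
#' covariance, with the sign of the smallest singular vector corrected so
#' the solution is a proper rotation (no reflection).
#'
#' @param source,target N x 3 matrices (or `point_set`s), N >= 3, in
#'   one-to-one correspondence.
#' @param weights optional non-negative per-pair weights.
#' @return A `rigid_transform` mapping source onto target. Degenerate
#'   input (N < 3, collinear source) raises a degenerate-fit error.
#' @export
kabsch_fit <- function(source, target, weights = NULL) {
  S <- as_points_matrix(source)
  T0 <- as_points_matrix(target)
  if (is.null(weights)) weights <- attr(source, "weights")
  if (nrow(S) != nrow(T0)) {
    stop_liverreg("degenerate_fit", "source and target sizes differ")
  }
  n <- nrow(S)
  if (n < 3L) {
    stop_liverreg("degenerate_fit", "need at least 3 point pairs")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  cs <- colSums(S * w)
  ct <- colSums(T0 * w)
  Sc <- sweep(S, 2, cs)
  Tc <- sweep(T0, 2, ct)
  H <- t(Sc * w) %*% Tc
  sv <- svd(H)
  # collinear (or coincident) source points leave the rotation about the
  # line undetermined: two near-zero singular values
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) {
    stop_liverreg("degenerate_fit", "source points are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Nearest-neighbour correspondences
#'
#' For every source point, its nearest model sample (Euclidean); pairs
#' farther apart than `max_dist_mm` are discarded. Ties broken by lowest
#' model-point index.
#'
#' @param source N x 3 matrix of reconstructed surface points (mm).
#' @param model_samples M x 3 matrix of model surface samples (mm).
#' @param max_dist_mm rejection distance (mm).
#' @return list with `source_idx`, `model_idx`, `distance` for surviving
#'   pairs. Zero survivors raise a no-correspondence error.
#' @export
nearest_correspondences <- function(source, model_samples, max_dist_mm = Inf) {
  S <- as_points_matrix(source)
  M <- as_points_matrix(model_samples)
  if (nrow(S) == 0L || nrow(M) == 0L) {
    stop_liverreg("no_correspondence", "empty point set")
  }
  nn <- nn_grid_cpp(S, M)
  keep <- nn$distance <= max_dist_mm
  if (!any(keep)) {
    stop_liverreg("no_correspondence",
                  "no pair within the correspondence distance")
  }
  list(source_idx = which(keep), model_idx = nn$index[keep],
       distance = nn$distance[keep])
}

#' Coarse manual initial pose
#'
#' Packages a user-supplied coarse pose as the ICP starting transform;
#' in manual registration mode this pose IS the final registration.
#' Rotation may be given as a `rigid_transform`, a 3x3 matrix, a
#' length-3 vector of extrinsic x/y/z Euler angles in degrees, or a
#' length-4 quaternion `(w, x, y, z)`.
#'
#' @param approx_translation_mm length-3 translation (mm).
#' @param approx_rotation rotation in any accepted form (default identity).
#' @return A `rigid_transform`.
#' @export
manual_init <- function(approx_translation_mm = c(0, 0, 0),
                        approx_rotation = NULL) {
  R <- if (is.null(approx_rotation)) {
    diag(3)
  } else if (is_rigid_transform(approx_rotation)) {
    approx_rotation$rotation
  } else if (is.matrix(approx_rotation)) {
    approx_rotation
  } else if (length(approx_rotation) == 3L) {
    ang <- as.numeric(approx_rotation) * pi / 180
    rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1])
  } else if (length(approx_rotation) == 4L) {
    quat_to_rotation(approx_rotation)
  } else {
    stop_liverreg("invalid_pose", "unrecognised rotation input")
  }
  tryCatch(rigid_transform(R, approx_translation_mm),
           liverreg_invalid_geometry = function(e) {
             stop_liverreg("invalid_pose", conditionMessage(e))
           })
}

#' Rigid registration by iterative closest point matching
#'
#' Aligns the preoperative liver model to a (gated) reconstructed surface
#' cloud. The model surface is represented by `model_sample_count` points
#' sampled uniformly by area; each iteration assigns every cloud point to
#' its nearest transformed model sample, discards pairs beyond the
#' correspondence distance, and updates the pose by an unweighted Kabsch
#' fit. Iteration stops when the inlier RMS changes by less than
#' `convergence_tol_mm` or the iteration cap is reached.
#'
#' A final inlier RMS above `failure_rms_mm`, or failure to converge,
#' raises a classed registration-failure error mirroring the system's
#' intraoperative error message; the partial result is attached to the
#' condition as `$result`.
#'
#' @param source_cloud a `labeled_point_cloud` (typically gated); all its
#'   points are used regardless of label.
#' @param liver_mesh the model `tri_mesh` (model space).
#' @param init `rigid_transform` initial model -> patient pose (coarse
#'   manual placement "in proximity" to the liver).
#' @param params an [icp_params()].
#' @param sample_seed seed for the model surface sampling.
#' @return A `registration_result`: `transform` (model -> patient),
#'   `inlier_rms_mm`, `n_correspondences`, `iterations_used`, `converged`,
#'   and `history` (inlier RMS per iteration, non-increasing).
#' @export
icp_register <- function(source_cloud, liver_mesh, init = identity_transform(),
                         params = icp_params(), sample_seed = 20211L) {
  stopifnot(inherits(source_cloud, "labeled_point_cloud"),
            inherits(liver_mesh, "tri_mesh"), is_rigid_transform(init),
            inherits(params, "icp_params"))
  if (n_points(source_cloud) == 0L) {
    stop_liverreg("no_correspondence", "empty source cloud")
  }
  cloud <- source_cloud$points
  smp <- sample_mesh_points(liver_mesh, params$model_sample_count, sample_seed)
  model0 <- smp$points
  fc <- face_corners(liver_mesh)
  ring <- face_ring(liver_mesh)
  T_cur <- init
  history <- numeric(0)
  converged <- FALSE
  n_corr <- 0L
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    # correspondence in the model frame (distances are rigid-invariant, so
    # the pairing equals nearest-neighbour search against the moved model)
    q <- apply_transform(invert(T_cur), cloud)
    corr <- tryCatch(
      nearest_correspondences(q, model0, params$max_correspondence_dist_mm),
      liverreg_no_correspondence = function(e) NULL)
    if (is.null(corr)) {
      res <- registration_result(T_cur, Inf, 0L, it, FALSE, history)
      stop_liverreg("registration_failure",
                    "no correspondences within distance threshold",
                    result = res)
    }
    n_corr <- length(corr$source_idx)
    # snap each matched sample to the closest surface point on its source
    # triangle's 1-ring neighbourhood: the pairing stays the point-to-point
    # nearest-sample match, but the fitted target lies on the continuous
    # surface, removing the sample-spacing noise floor that a finite sample
    # set would impose on the converged pose
    fi <- smp$face[corr$model_idx]
    qs <- q[corr$source_idx, , drop = FALSE]
    matched <- NULL
    best_d2 <- NULL
    for (r in seq_len(ncol(ring))) {
      fr <- ring[fi, r]
      ok <- !is.na(fr)
      if (!any(ok)) next
      cand <- qs
      cand[ok, ] <- closest_point_on_triangles(
        qs[ok, , drop = FALSE],
        fc$v0[fr[ok], , drop = FALSE], fc$v1[fr[ok], , drop = FALSE],
        fc$v2[fr[ok], , drop = FALSE])
      d2 <- rowSums((cand - qs)^2)
      d2[!ok] <- Inf
      if (is.null(matched)) {
        matched <- cand; best_d2 <- d2
      } else {
        sw <- d2 < best_d2
        matched[sw, ] <- cand[sw, , drop = FALSE]
        best_d2[sw] <- d2[sw]
      }
    }
    T_new <- tryCatch(
      kabsch_fit(matched, cloud[corr$source_idx, , drop = FALSE]),
      liverreg_degenerate_fit = function(e) NULL)
    if (is.null(T_new)) {
      res <- registration_result(T_cur, Inf, n_corr, it, FALSE, history)
      stop_liverreg("registration_failure", "degenerate correspondence set",
                    result = res)
    }
    moved_new <- apply_transform(T_new, matched)
    rms <- sqrt(mean(rowSums(
      (moved_new - cloud[corr$source_idx, , drop = FALSE])^2)))
    prev <- if (length(history)) history[length(history)] else Inf
    history <- c(history, rms)
    T_cur <- T_new
    if (is.finite(prev) && abs(prev - rms) < params$convergence_tol_mm) {
      converged <- TRUE
      break
    }
  }
  rms_final <- history[length(history)]
  # runtime self-check: classical point-to-point ICP guarantees a
  # non-increasing residual; a violation indicates a correspondence bug
  # (or a pathological inlier-set flip worth knowing about)
  if (length(history) > 1L && any(diff(history) > 1e-9)) {
    warning("ICP inlier RMS history is not non-increasing", call. = FALSE)
  }
  res <- registration_result(T_cur, rms_final, n_corr, it, converged, history)
  if (!converged || rms_final > params$failure_rms_mm) {
    stop_liverreg("registration_failure",
                  sprintf(paste0("registration failed (converged: %s, ",
                                 "inlier RMS %.2f mm, threshold %.2f mm)"),
                          converged, rms_final, params$failure_rms_mm),
                  result = res)
  }
  res
}

registration_result <- function(transform, inlier_rms_mm, n_correspondences,
                                iterations_used, converged, history) {
  structure(list(transform = transform, inlier_rms_mm = inlier_rms_mm,
                 n_correspondences = as.integer(n_correspondences),
                 iterations_used = as.integer(iterations_used),
                 converged = converged, history = history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: inlier RMS %.4f mm, %d correspondences, %d iterations, converged: %s\n",
    x$inlier_rms_mm, x$n_correspondences, x$iterations_used, x$converged))
  invisible(x)
}

#' Serialise a registration result to JSON
#'
#' @param result a `registration_result`.
#' @param path file path.
#' @return `registration_from_json` returns a `registration_result`.
#' @export
registration_to_json <- function(result, path) {
  jsonlite::write_json(
    list(transform = transform_to_list(result$transform),
         inlier_rms_mm = result$inlier_rms_mm,
         n_correspondences = result$n_correspondences,
         iterations_used = result$iterations_used,
         converged = result$converged,
         history = as.numeric(result$history)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname registration_to_json
#' @export
registration_from_json <- function(path) {
  x <- jsonlite::read_json(path)
  registration_result(transform_from_list(x$transform), x$inlier_rms_mm,
                      x$n_correspondences, x$iterations_used, x$converged,
                      unlist(x$history) %||% numeric(0))
}

# brute-force O(N*M) nearest neighbour in R; the independent oracle the
# tests compare the C++ path against
nn_bruteforce_r <- function(query, ref) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) +
    outer(rep(1, nrow(query)), rowSums(ref^2)) - 2 * query %*% t(ref)
  idx <- apply(d2, 1L, which.min)
  list(index = idx, distance = sqrt(pmax(d2[cbind(seq_len(nrow(query)), idx)], 0)))
}
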