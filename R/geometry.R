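#' Rigid 3D transforms and point sets
#'
#' All coordinates are millimetres in a right-handed coordinate system.
#' A `rigid_transform` carries a proper rotation (3x3 orthonormal matrix,
#' det = +1) and a translation 3-vector; it maps model space into
#' patient/tracker space as `p' = R p + t`.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' T1 <- rigid_transform(rot_z(pi / 2), c(0, 0, 10))
#' apply_transform(T1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop_liverreg("invalid_geometry", "rotation must be a finite 3x3 matrix")
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop_liverreg("invalid_geometry", "translation must be a finite 3-vector")
  }
  drift <- max(abs(crossprod(rotation) - diag(3)))
  if (drift > 1e-9) {
    # tolerate numerical drift from I/O round trips: project to the nearest
    # rotation; anything grossly non-orthonormal is a user error
    if (drift > 1e-3) {
      stop_liverreg("invalid_geometry", "rotation is not orthonormal")
    }
    rotation <- nearest_rotation(rotation)
  }
  if (det(rotation) < 0) {
    stop_liverreg("invalid_geometry",
                  "rotation has det -1 (reflection, not a proper rotation)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (mm)\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform()

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Project a near-rotation matrix to the nearest proper rotation
#'
#' Orthogonal Procrustes projection via SVD, with sign correction so the
#' result has determinant +1.
#'
#' @param M a 3x3 matrix close to a rotation.
#' @return The nearest (Frobenius) proper rotation matrix.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Elementary rotations about coordinate axes
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(theta) {
  c0 <- cos(theta); s0 <- sin(theta)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}

#' Rotation matrix from a unit quaternion
#'
#' Accepted at I/O boundaries; internally rotations are stored as matrices.
#'
#' @param q numeric length-4 quaternion `(w, x, y, z)`; normalised first.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || !all(is.finite(q)) || sum(q^2) == 0) {
    stop_liverreg("invalid_geometry", "quaternion must be a finite nonzero 4-vector")
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Point sets
#'
#' A point set is an N x 3 numeric matrix of coordinates in mm with an
#' optional non-negative per-point weight vector (attribute `weights`).
#'
#' @param points N x 3 matrix or length-3 vector (mm).
#' @param weights optional non-negative weights, length N, sum > 0.
#' @return N x 3 matrix of class `point_set`.
#' @export
point_set <- function(points, weights = NULL) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop_liverreg("invalid_geometry", "points must be N x 3")
  }
  if (!all(is.finite(points))) {
    stop_liverreg("invalid_geometry", "non-finite coordinates in point set")
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(points) || any(weights < 0) ||
        !all(is.finite(weights)) || sum(weights) <= 0) {
      stop_liverreg("invalid_geometry",
                    "weights must be non-negative, length N, sum > 0")
    }
    attr(points, "weights") <- weights
  }
  class(points) <- c("point_set", class(points))
  points
}

as_points_matrix <- function(P) {
  if (is.null(dim(P))) P <- matrix(as.numeric(P), ncol = 3)
  P <- unclass(P)
  attr(P, "weights") <- NULL
  P
}

#' Apply a rigid transform to points
#'
#' @param T a `rigid_transform`.
#' @param P an N x 3 matrix / `point_set`, or a length-3 vector.
#' @return Transformed points, same shape as the input (`R p + t` per row).
#' @export
apply_transform <- function(T, P) {
  stopifnot(is_rigid_transform(T))
  vec <- is.null(dim(P)) && length(P) == 3L
  M <- as_points_matrix(P)
  if (nrow(M) == 0L) {
    stop_liverreg("invalid_geometry", "empty point set")
  }
  if (!all(is.finite(M))) {
    stop_liverreg("invalid_geometry", "non-finite coordinates")
  }
  out <- M %*% t(T$rotation)
  out <- sweep(out, 2L, T$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' `compose(T2, T1)` applies `T1` first: `compose(T2, T1) p = T2 (T1 p)`.
#'
#' @param T2,T1 `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(T2, T1) {
  stopifnot(is_rigid_transform(T2), is_rigid_transform(T1))
  rigid_transform(T2$rotation %*% T1$rotation,
                  as.numeric(T2$rotation %*% T1$translation) + T2$translation)
}

#' Invert a rigid transform
#'
#' @param T a `rigid_transform`.
#' @return The inverse transform: `R' = R^T`, `t' = -R^T t`.
#' @export
invert <- function(T) {
  stopifnot(is_rigid_transform(T))
  Rt <- t(T$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% T$translation))
}

#' Rotation angle and centroid displacement between two poses
#'
#' Used to score a registration against a known ground-truth pose: the
#' angle (degrees) of the residual rotation, and the displacement (mm) the
#' pose mismatch induces at a reference point (typically the model
#' centroid, where the liver actually is).
#'
#' @param T_est,T_true `rigid_transform` objects.
#' @param at reference point (mm) at which translation error is evaluated.
#' @return list with `rotation_deg` and `translation_mm`.
#' @export
pose_error <- function(T_est, T_true, at = c(0, 0, 0)) {
  dR <- T_est$rotation %*% t(T_true$rotation)
  ctr <- pmin(pmax((sum(diag(dR)) - 1) / 2, -1), 1)
  list(rotation_deg = acos(ctr) * 180 / pi,
       translation_mm = sqrt(sum((apply_transform(T_est, at) -
                                    apply_transform(T_true, at))^2)))
}

#' JSON serialisation of rigid transforms
#'
#' The on-disk schema is
#' `{"rotation": [[..3x3..]], "translation_mm": [x, y, z]}`.
#'
#' @param T a `rigid_transform`.
#' @param path file path.
#' @return `transform_from_json` returns a `rigid_transform`.
#' @export
transform_to_json <- function(T, path) {
  stopifnot(is_rigid_transform(T))
  jsonlite::write_json(transform_to_list(T), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(T) {
  list(rotation = unname(apply(T$rotation, 1L, as.numeric, simplify = FALSE)),
       translation_mm = as.numeric(T$translation))
}

transform_from_list <- function(x) {
  if (!is.null(x$quaternion)) {
    R <- quat_to_rotation(unlist(x$quaternion))
  } else {
    R <- do.call(rbind, lapply(x$rotation, as.numeric))
  }
  rigid_transform(R, unlist(x$translation_mm))
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  transform_from_list(jsonlite::read_json(path))
}

# package condition helper: every domain error is a classed condition so
# callers (and the CLI) can map error kinds to exit codes
stop_liverreg <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("liverreg_", class), "liverreg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
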