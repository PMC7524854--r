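#' Pinhole camera model
#'
#' Distortion-free pinhole camera. Image origin is at the top-left corner,
#' `u` increases rightward and `v` downward; pixel centres sit at integer
#' coordinates. `pose` maps world coordinates (mm) into the camera frame,
#' whose +z axis points along the optical axis.
#'
#' @param fx,fy focal lengths (pixels), > 0.
#' @param cx,cy principal point (pixels), inside the image.
#' @param image_size integer `c(width, height)` in pixels.
#' @param pose `rigid_transform` mapping world -> camera coordinates.
#' @return An object of class `pinhole_camera`.
#' @export
pinhole_camera <- function(fx, fy, cx, cy, image_size = c(1920L, 1080L),
                           pose = identity_transform()) {
  if (fx <= 0 || fy <= 0) {
    stop_liverreg("invalid_geometry", "focal lengths must be positive")
  }
  if (cx < 0 || cx >= image_size[1] || cy < 0 || cy >= image_size[2]) {
    stop_liverreg("invalid_geometry", "principal point outside image")
  }
  stopifnot(is_rigid_transform(pose))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_size = as.numeric(image_size), pose = pose),
            class = "pinhole_camera")
}

#' Stereo rig
#'
#' Two pinhole cameras with a known relative pose. The baseline is derived
#' from the relative pose and must be nonzero.
#'
#' @param left,right `pinhole_camera` objects (poses in a common world frame).
#' @return An object of class `stereo_rig` with a `baseline_mm` element.
#' @export
stereo_rig <- function(left, right) {
  stopifnot(inherits(left, "pinhole_camera"), inherits(right, "pinhole_camera"))
  rel <- compose(right$pose, invert(left$pose))
  b <- sqrt(sum(rel$translation^2))
  if (b <= 0) {
    stop_liverreg("invalid_geometry", "stereo baseline is zero")
  }
  structure(list(left = left, right = right, baseline_mm = b),
            class = "stereo_rig")
}

#' Default stereo laparoscope rig
#'
#' Plausible but invented intrinsics resembling a 3D laparoscope (the source
#' system's calibration is not published): fx = fy = 1000 px, 1920 x 1080,
#' baseline 4 mm along +x, cameras verged by 1 degree.
#'
#' @param fx,fy,baseline_mm,verge_deg,image_size rig parameters.
#' @param pose world -> left-camera transform (rig mounting pose).
#' @return A `stereo_rig`.
#' @export
default_rig <- function(fx = 1000, fy = 1000, baseline_mm = 4, verge_deg = 1,
                        image_size = c(1920L, 1080L),
                        pose = identity_transform()) {
  cx <- image_size[1] / 2; cy <- image_size[2] / 2
  half_verge <- verge_deg / 2 * pi / 180
  # each camera toes inward about its own y axis
  left_pose <- compose(rigid_transform(rot_y(half_verge)), pose)
  right_pose <- compose(
    rigid_transform(rot_y(-half_verge), c(-baseline_mm, 0, 0)), pose)
  stereo_rig(pinhole_camera(fx, fy, cx, cy, image_size, left_pose),
             pinhole_camera(fx, fy, cx, cy, image_size, right_pose))
}

#' Project world points through a pinhole camera
#'
#' @param cam a `pinhole_camera`.
#' @param p_world N x 3 matrix or length-3 vector of world points (mm).
#' @return N x 2 matrix (or length-2 vector) of pixel coordinates `(u, v)`.
#'   Points at or behind the camera plane (camera-frame z <= 0) raise a
#'   behind-camera error.
#' @export
project <- function(cam, p_world) {
  vec <- is.null(dim(p_world)) && length(p_world) == 3L
  pc <- apply_transform(cam$pose, as_points_matrix(p_world))
  if (any(pc[, 3] <= 0)) {
    stop_liverreg("behind_camera", "point at or behind the camera (z <= 0)")
  }
  uv <- cbind(cam$fx * pc[, 1] / pc[, 3] + cam$cx,
              cam$fy * pc[, 2] / pc[, 3] + cam$cy)
  if (vec) as.numeric(uv) else uv
}

# back-project a pixel to a world-space ray (origin = camera centre,
# direction = unit vector)
pixel_ray <- function(cam, uv) {
  dir_cam <- c((uv[1] - cam$cx) / cam$fx, (uv[2] - cam$cy) / cam$fy, 1)
  inv <- invert(cam$pose)
  origin <- inv$translation
  d <- as.numeric(inv$rotation %*% dir_cam)
  list(origin = origin, dir = d / sqrt(sum(d^2)))
}

in_bounds <- function(cam, uv) {
  uv[1] >= 0 && uv[1] <= cam$image_size[1] - 1 &&
    uv[2] >= 0 && uv[2] <= cam$image_size[2] - 1
}

#' Triangulate a stereo correspondence
#'
#' Back-projects the two pixels to rays and returns the 3D point minimising
#' the summed squared distance to both rays (the midpoint of the common
#' perpendicular for two rays).
#'
#' @param rig a `stereo_rig`.
#' @param pixel_left,pixel_right `(u, v)` pixel coordinates.
#' @return length-3 world point (mm). Rays parallel within 1e-8 rad raise a
#'   degenerate-geometry error; out-of-bounds pixels raise an
#'   invalid-geometry error.
#' @export
triangulate <- function(rig, pixel_left, pixel_right) {
  if (!in_bounds(rig$left, pixel_left) || !in_bounds(rig$right, pixel_right)) {
    stop_liverreg("invalid_geometry", "correspondence pixel outside image bounds")
  }
  r1 <- pixel_ray(rig$left, pixel_left)
  r2 <- pixel_ray(rig$right, pixel_right)
  triangulate_rays(r1, r2)
}

triangulate_rays <- function(r1, r2) {
  d1 <- r1$dir; d2 <- r2$dir
  cross_n2 <- 1 - sum(d1 * d2)^2          # |d1 x d2|^2 for unit vectors
  if (cross_n2 < (1e-8)^2) {
    stop_liverreg("degenerate_geometry", "triangulation rays are parallel")
  }
  # closest points: solve [1 -d1.d2; d1.d2 -1] [s; t] = [(o2-o1).d1; (o2-o1).d2]
  w <- r2$origin - r1$origin
  a <- sum(d1 * d2)
  s <- (sum(w * d1) - a * sum(w * d2)) / cross_n2
  t0 <- (a * sum(w * d1) - sum(w * d2)) / cross_n2
  p1 <- r1$origin + s * d1
  p2 <- r2$origin + t0 * d2
  (p1 + p2) / 2
}

#' Reconstruct a labeled point cloud from stereo correspondences
#'
#' One 3D point per valid correspondence; labels are carried through.
#' Correspondences whose triangulation is degenerate (parallel rays,
#' out-of-bounds pixels) are dropped and counted in the `dropped` attribute.
#'
#' @param rig a `stereo_rig`.
#' @param correspondences data frame with columns `ul, vl, ur, vr, label`
#'   (label 0 = liver, >= 1 = distractor class).
#' @return A [labeled_point_cloud()] with attribute `dropped` (count of
#'   discarded correspondences). All correspondences degenerate raises an
#'   empty-reconstruction error.
#' @export
reconstruct_patch <- function(rig, correspondences) {
  cs <- as.data.frame(correspondences)
  need <- c("ul", "vl", "ur", "vr", "label")
  if (!all(need %in% names(cs))) {
    stop_liverreg("schema", paste("correspondences need columns:",
                                  paste(need, collapse = ", ")))
  }
  if (nrow(cs) < 1L) {
    stop_liverreg("empty_reconstruction", "no correspondences supplied")
  }
  pts <- matrix(NA_real_, nrow(cs), 3)
  ok <- logical(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    p <- tryCatch(triangulate(rig, c(cs$ul[i], cs$vl[i]), c(cs$ur[i], cs$vr[i])),
                  liverreg_error = function(e) NULL)
    if (!is.null(p)) {
      pts[i, ] <- p
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) {
    stop_liverreg("empty_reconstruction", "all correspondences degenerate")
  }
  cloud <- labeled_point_cloud(pts[ok, , drop = FALSE], cs$label[ok],
                               if (!is.null(cs$patch_id)) cs$patch_id[ok] else 0L)
  attr(cloud, "dropped") <- sum(!ok)
  cloud
}

#' Stereo rig JSON configuration
#'
#' Schema: per-camera intrinsics in pixels plus world -> camera poses in the
#' transform JSON schema of [transform_to_json()].
#'
#' @param rig a `stereo_rig`.
#' @param path file path.
#' @return `rig_from_json` returns a `stereo_rig`.
#' @export
rig_to_json <- function(rig, path) {
  cam_list <- function(cam) {
    list(fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
         image_size = as.numeric(cam$image_size),
         pose = transform_to_list(cam$pose))
  }
  jsonlite::write_json(list(left = cam_list(rig$left),
                            right = cam_list(rig$right),
                            baseline_mm = rig$baseline_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rig_to_json
#' @export
rig_from_json <- function(path) {
  x <- jsonlite::read_json(path)
  cam_of <- function(c0) {
    pinhole_camera(c0$fx, c0$fy, c0$cx, c0$cy, unlist(c0$image_size),
                   transform_from_list(c0$pose))
  }
  stereo_rig(cam_of(x$left), cam_of(x$right))
}

#' Read / write stereo correspondence CSVs
#'
#' Columns `ul, vl, ur, vr, label` (pixels; integer label).
#'
#' @param path CSV path.
#' @param correspondences data frame in the same schema.
#' @export
read_correspondences <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ul", "vl", "ur", "vr", "label")
  if (!all(need %in% names(df))) {
    stop_liverreg("schema", paste("missing correspondence columns:",
                                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df
}

#' @rdname read_correspondences
#' @export
write_correspondences <- function(correspondences, path) {
  utils::write.csv(as.data.frame(correspondences), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
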