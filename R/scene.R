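#' Synthetic liver-like mesh
#'
#' Deterministic liver stand-in: an icosphere scaled to a ~250 x 150 x 100 mm
#' ellipsoid envelope (semi-axes `radii_mm`), deformed by `n_bumps` smooth
#' radial Gaussian bumps whose centres and widths are drawn from `seed`.
#' Bumps emulate surface feature richness (a lobulated liver has more
#' features for surface matching than a smooth one); `bump_amp_mm = 0`
#' yields the pure ellipsoid.
#'
#' @param seed integer seed for bump placement.
#' @param n_bumps number of radial bumps (>= 0).
#' @param bump_amp_mm maximum bump amplitude in mm (>= 0).
#' @param radii_mm ellipsoid semi-axes (a, b, c) in mm.
#' @param subdivisions icosphere subdivision level; level `k` gives
#'   `20 * 4^k` faces (3 -> 1280, 4 -> 5120).
#' @return A watertight `tri_mesh`.
#' @export
make_liver_mesh <- function(seed = 1L, n_bumps = 12L, bump_amp_mm = 8,
                            radii_mm = c(125, 75, 50), subdivisions = 3L) {
  if (n_bumps < 0 || bump_amp_mm < 0) {
    stop_liverreg("generation", "n_bumps and bump_amp_mm must be non-negative")
  }
  ico <- icosphere(subdivisions)
  dirs <- ico$vertices                      # unit sphere
  verts <- sweep(dirs, 2L, radii_mm, "*")
  if (n_bumps > 0L && bump_amp_mm > 0) {
    bumps <- with_seed(seed, {
      u <- matrix(stats::rnorm(3 * n_bumps), n_bumps, 3)
      u <- u / sqrt(rowSums(u^2))
      list(centers = u,
           amps = stats::runif(n_bumps, 0.4, 1) * bump_amp_mm,
           widths = stats::runif(n_bumps, 0.25, 0.6))   # radians on the sphere
    })
    # radial displacement: sum of Gaussian bumps in angular distance
    disp <- numeric(nrow(dirs))
    for (k in seq_len(n_bumps)) {
      ang <- acos(pmin(pmax(as.numeric(dirs %*% bumps$centers[k, ]), -1), 1))
      disp <- disp + bumps$amps[k] * exp(-(ang / bumps$widths[k])^2 / 2)
    }
    if (any(disp >= min(radii_mm))) {
      stop_liverreg("generation", "bump amplitude causes self-intersection")
    }
    # displace along the local radial direction of the ellipsoid point
    rad <- sqrt(rowSums(verts^2))
    verts <- verts * (1 + disp / rad)
  }
  mesh <- tri_mesh(verts, ico$faces)
  stopifnot(is_watertight(mesh))
  mesh
}

# unit icosphere by repeated 4-way subdivision of an icosahedron;
# deterministic vertex order
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                          cbind(f[, 3], f[, 1])))
    keys <- edge_key(edges[, 1], edges[, 2])
    keep <- !duplicated(keys)
    edges <- edges[keep, , drop = FALSE]
    keys <- keys[keep]
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- stats::setNames(nv + seq_len(nrow(mid)), keys)
    v <- rbind(v, mid)
    a <- f[, 1]; b <- f[, 2]; c0 <- f[, 3]
    ab <- midx[edge_key(a, b)]; bc <- midx[edge_key(b, c0)]
    ca <- midx[edge_key(c0, a)]
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab), cbind(c0, ca, bc),
               cbind(ab, bc, ca))
    dimnames(f) <- NULL
  }
  list(vertices = v, faces = f)
}

#' Distractor sheet mesh
#'
#' An open rectangular sheet (two-triangle grid cells), mildly rippled,
#' standing in for the diaphragm: a smooth surface lying close above the
#' liver that a matcher without segmentation confuses with liver surface.
#'
#' @param width_mm,depth_mm sheet extent (mm).
#' @param n_grid grid resolution per side.
#' @param ripple_amp_mm sinusoidal ripple amplitude (mm).
#' @return An open `tri_mesh` in a local frame (sheet in the x-y plane,
#'   normal along -z so the underside faces the liver below).
#' @export
make_sheet_mesh <- function(width_mm = 300, depth_mm = 200, n_grid = 20L,
                            ripple_amp_mm = 2) {
  xs <- seq(-width_mm / 2, width_mm / 2, length.out = n_grid + 1L)
  ys <- seq(-depth_mm / 2, depth_mm / 2, length.out = n_grid + 1L)
  g <- expand.grid(x = xs, y = ys)
  z <- ripple_amp_mm * sin(2 * pi * g$x / width_mm) *
    cos(2 * pi * g$y / depth_mm)
  verts <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1L) * (n_grid + 1L) + i
  fs <- vector("list", n_grid * n_grid * 2L)
  k <- 1L
  for (j in seq_len(n_grid)) {
    for (i in seq_len(n_grid)) {
      # wound so normals point along -z (towards the liver below the sheet)
      fs[[k]] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)); k <- k + 1L
      fs[[k]] <- c(idx(i + 1L, j), idx(i, j + 1L), idx(i + 1L, j + 1L)); k <- k + 1L
    }
  }
  tri_mesh(verts, do.call(rbind, fs))
}

#' Synthetic surgical scene
#'
#' Assembles a patient stand-in: a liver mesh posed in patient space by a
#' ground-truth rigid transform, optional distractor surfaces (diaphragm
#' sheet) at a configurable clearance above the liver, and named landmarks
#' on the liver surface placed at curvature extrema (ridge/notch-like
#' features, the kind used clinically: lateral margin, lower margin,
#' falciform ligament, umbilical notch).
#'
#' All meshes and landmarks are stored in model space together with
#' `true_pose` (model -> patient); patient-space geometry is obtained by
#' applying `true_pose`.
#'
#' @param seed integer seed.
#' @param distractor_spec `NULL` for a liver-only scene, or a list with
#'   elements `clearance_mm` (gap between liver and sheet, default 5) and
#'   optionally `width_mm`, `depth_mm`, `ripple_amp_mm` passed to
#'   [make_sheet_mesh()].
#' @param n_landmarks number of landmarks (>= 3).
#' @param true_pose `rigid_transform`, model -> patient space.
#' @param mesh_args list of overrides for [make_liver_mesh()].
#' @return An object of class `synthetic_scene`: `liver_mesh`,
#'   `distractor_meshes` (list, each with `mesh` and `class_label`),
#'   `landmarks` (named list of model-space 3-vectors), `true_pose`, `seed`.
#' @export
make_scene <- function(seed = 1L, distractor_spec = NULL, n_landmarks = 4L,
                       true_pose = identity_transform(), mesh_args = list()) {
  if (n_landmarks < 3L) {
    stop_liverreg("generation", "n_landmarks must be >= 3 (TRE needs >= 3 landmarks)")
  }
  liver <- do.call(make_liver_mesh, c(list(seed = seed), mesh_args))
  landmarks <- pick_landmarks(liver, n_landmarks)
  distractors <- list()
  if (!is.null(distractor_spec)) {
    clearance <- distractor_spec$clearance_mm %||% 5
    sheet <- make_sheet_mesh(
      width_mm = distractor_spec$width_mm %||% 300,
      depth_mm = distractor_spec$depth_mm %||% 200,
      ripple_amp_mm = distractor_spec$ripple_amp_mm %||% 2)
    # place the sheet above the liver (model-space +z), then shift so the
    # exact sheet-to-liver minimum distance equals the clearance
    z0 <- max(liver$vertices[, 3]) + clearance + 10
    sheet <- transform_mesh(sheet, rigid_transform(diag(3), c(0, 0, z0)))
    gap <- min(points_to_mesh_distance(
      sample_mesh_points(sheet, 2000L, derive_seed(seed, 1, 7, 1, 0))$points,
      liver))
    sheet <- transform_mesh(
      sheet, rigid_transform(diag(3), c(0, 0, clearance - gap)))
    distractors <- list(list(mesh = sheet, class_label = 1L))
  }
  structure(list(liver_mesh = liver, distractor_meshes = distractors,
                 landmarks = landmarks, true_pose = true_pose,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# combine seed components into a valid 32-bit seed without integer overflow
derive_seed <- function(a, am, b, bm, c0) {
  as.integer((as.numeric(a) * am + as.numeric(b) * bm + c0) %% 2147483629)
}

# landmarks at curvature extrema: rank vertices by discrete angle deficit
# (2*pi minus the sum of incident face angles, the standard discrete
# Gaussian-curvature measure), then greedily keep the top-ranked vertices
# subject to a minimum mutual spacing so landmarks spread over the organ
pick_landmarks <- function(mesh, n) {
  deficit <- angle_deficit(mesh)
  ord <- order(abs(deficit), decreasing = TRUE)
  min_gap <- 0.25 * max(dist_range(mesh$vertices))
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == n) break
    if (length(chosen) == 0L ||
        min(sqrt(rowSums(sweep(mesh$vertices[chosen, , drop = FALSE], 2,
                               mesh$vertices[i, ])^2))) > min_gap) {
      chosen <- c(chosen, i)
    }
  }
  # relax the spacing if the mesh is too smooth to fill the quota
  while (length(chosen) < n) {
    min_gap <- min_gap / 2
    for (i in ord) {
      if (length(chosen) == n) break
      if (!(i %in% chosen) &&
          min(sqrt(rowSums(sweep(mesh$vertices[chosen, , drop = FALSE], 2,
                                 mesh$vertices[i, ])^2))) > min_gap) {
        chosen <- c(chosen, i)
      }
    }
  }
  pts <- mesh$vertices[chosen, , drop = FALSE]
  nm <- c("left_lateral_margin", "lower_margin", "falciform_ligament",
          "umbilical_notch")
  if (n > length(nm)) nm <- c(nm, paste0("feature_", seq_len(n - length(nm))))
  stats::setNames(lapply(seq_len(n), function(i) pts[i, ]), nm[seq_len(n)])
}

dist_range <- function(v) {
  apply(v, 2, function(x) diff(range(x)))
}

angle_deficit <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ang_at <- function(a, b, c0) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c0, , drop = FALSE] - v[a, , drop = FALSE]
    cosang <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), .Machine$double.eps)
    acos(pmin(pmax(cosang, -1), 1))
  }
  total <- numeric(nrow(v))
  for (k in 1:3) {
    a <- f[, k]; b <- f[, k %% 3 + 1]; c0 <- f[, (k + 1) %% 3 + 1]
    s <- ang_at(a, b, c0)
    acc <- tapply(s, a, sum)
    total[as.integer(names(acc))] <- total[as.integer(names(acc))] + acc
  }
  2 * pi - total
}

#' Stereo observation of a scene
#'
#' Emulates recording the liver surface with a tracked stereo laparoscope
#' from one viewpoint: surface points are sampled on the liver and any
#' distractor surfaces (in patient space), kept only if visible from both
#' camera centres (front-facing and unoccluded, tested by ray casting
#' against all scene meshes), projected into both cameras, and perturbed by
#' i.i.d. Gaussian pixel noise. Each correspondence carries the integer
#' class label of its source mesh (0 = liver).
#'
#' @param scene a `synthetic_scene`.
#' @param rig a `stereo_rig` in its own local frame (left camera at origin
#'   before `camera_pose`).
#' @param camera_pose `rigid_transform` mapping patient space into the rig
#'   frame (i.e. the laparoscope pose).
#' @param n_points number of visible correspondences to return (>= 1).
#' @param noise_sd_px Gaussian pixel noise sigma.
#' @param seed integer seed.
#' @param class_fractions optional numeric vector of target label
#'   proportions, named by label ("0", "1", ...); default samples in
#'   proportion to visible area.
#' @return An object of class `observation`: the posed `rig`,
#'   `camera_pose`, a `correspondences` data frame
#'   (`ul, vl, ur, vr, label, patch_id`) with attached noiseless
#'   ground-truth points (`attr(, "true_points")`), `noise_sd_px`, and
#'   `visible_fraction` (fraction of liver-surface candidates visible).
#' @export
observe <- function(scene, rig = default_rig(), camera_pose, n_points = 2000L,
                    noise_sd_px = 0, seed = 1L, class_fractions = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), n_points >= 1)
  # pose the rig in patient space: camera_pose maps patient -> rig frame
  posed <- stereo_rig(
    with_pose(rig$left, compose(rig$left$pose, camera_pose)),
    with_pose(rig$right, compose(rig$right$pose, camera_pose)))
  meshes <- c(list(list(mesh = transform_mesh(scene$liver_mesh, scene$true_pose),
                        class_label = 0L)),
              lapply(scene$distractor_meshes, function(d) {
                list(mesh = transform_mesh(d$mesh, scene$true_pose),
                     class_label = d$class_label)
              }))
  cams <- list(posed$left, posed$right)
  cam_centers <- lapply(cams, function(cm) invert(cm$pose)$translation)
  # oversample candidates per mesh, cull to visible, then draw the requested
  # number (proportional to visible area unless class_fractions overrides)
  factor <- 4L
  cand <- list()
  vis_frac_liver <- NA_real_
  for (mi in seq_along(meshes)) {
    m <- meshes[[mi]]
    ns <- n_points * factor
    smp <- sample_mesh_points(m$mesh, ns,
                              derive_seed(scene$seed, 1000, seed, 10, mi))
    vis <- visible_from_both(smp, cam_centers, meshes, cams)
    if (m$class_label == 0L) vis_frac_liver <- mean(vis)
    if (any(vis)) {
      cand[[length(cand) + 1L]] <- list(
        points = smp$points[vis, , drop = FALSE],
        label = m$class_label,
        weight = (sum(vis) / ns) * sum(face_areas(m$mesh)))
    }
  }
  if (length(cand) == 0L) {
    stop_liverreg("empty_observation", "no surface visible from this viewpoint")
  }
  labels_avail <- vapply(cand, function(x) x$label, integer(1))
  vis_area <- vapply(cand, function(x) x$weight, numeric(1))
  if (is.null(class_fractions)) {
    probs <- vis_area / sum(vis_area)
  } else {
    probs <- as.numeric(class_fractions[as.character(labels_avail)])
    probs[is.na(probs)] <- 0
    if (sum(probs) <= 0) {
      stop_liverreg("empty_observation", "class_fractions exclude all visible classes")
    }
    probs <- probs / sum(probs)
  }
  draw <- with_seed(derive_seed(seed, 1, 104729, 1, 0), {
    n_per <- as.vector(stats::rmultinom(1, n_points, probs))
    lapply(seq_along(cand), function(i) {
      if (n_per[i] == 0L) return(integer(0))
      sample.int(nrow(cand[[i]]$points), min(n_per[i], nrow(cand[[i]]$points)),
                 replace = nrow(cand[[i]]$points) < n_per[i])
    })
  })
  pts <- do.call(rbind, lapply(seq_along(cand), function(i) {
    cand[[i]]$points[draw[[i]], , drop = FALSE]
  }))
  labels <- rep(labels_avail, vapply(draw, length, integer(1)))
  uv_l <- project(posed$left, pts)
  uv_r <- project(posed$right, pts)
  if (noise_sd_px > 0) {
    noise <- with_seed(derive_seed(seed, 1, 224737, 1, 0),
                       matrix(stats::rnorm(4L * nrow(pts), 0, noise_sd_px),
                              ncol = 4L))
    uv_l <- uv_l + noise[, 1:2]
    uv_r <- uv_r + noise[, 3:4]
  }
  corr <- data.frame(ul = uv_l[, 1], vl = uv_l[, 2],
                     ur = uv_r[, 1], vr = uv_r[, 2],
                     label = labels, patch_id = seed)
  # drop correspondences whose (possibly noised) pixels left the sensor
  inb <- corr$ul >= 0 & corr$ul <= posed$left$image_size[1] - 1 &
    corr$vl >= 0 & corr$vl <= posed$left$image_size[2] - 1 &
    corr$ur >= 0 & corr$ur <= posed$right$image_size[1] - 1 &
    corr$vr >= 0 & corr$vr <= posed$right$image_size[2] - 1
  corr <- corr[inb, , drop = FALSE]
  rownames(corr) <- NULL
  if (nrow(corr) == 0L) {
    stop_liverreg("empty_observation", "no correspondence inside both images")
  }
  attr(corr, "true_points") <- pts[inb, , drop = FALSE]
  structure(list(rig = posed, camera_pose = camera_pose,
                 correspondences = corr, noise_sd_px = noise_sd_px,
                 visible_fraction = vis_frac_liver),
            class = "observation")
}

with_pose <- function(cam, pose) {
  pinhole_camera(cam$fx, cam$fy, cam$cx, cam$cy, cam$image_size, pose)
}

# a sampled surface point is usable if, for BOTH cameras: the source face is
# front-facing to the camera, the point projects inside the image, and the
# segment from point to camera centre is not blocked by any scene mesh
visible_from_both <- function(smp, cam_centers, meshes, cams) {
  n <- nrow(smp$points)
  vis <- rep(TRUE, n)
  all_v0 <- do.call(rbind, lapply(meshes, function(m) face_corners(m$mesh)$v0))
  all_v1 <- do.call(rbind, lapply(meshes, function(m) face_corners(m$mesh)$v1))
  all_v2 <- do.call(rbind, lapply(meshes, function(m) face_corners(m$mesh)$v2))
  for (ci in seq_along(cam_centers)) {
    if (!any(vis)) break
    cc <- cam_centers[[ci]]
    to_cam <- sweep(-smp$points, 2, -cc)          # cc - point
    seg_len <- sqrt(rowSums(to_cam^2))
    dirs <- to_cam / seg_len
    front <- rowSums(smp$normals * dirs) > 1e-6
    vis <- vis & front
    # in-image test
    idx <- which(vis)
    if (length(idx) == 0L) break
    uv <- tryCatch(project_safe(cams[[ci]], smp$points[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(uv)) { vis[] <- FALSE; break }
    inb <- uv$ok &
      uv$uv[, 1] >= 0 & uv$uv[, 1] <= cams[[ci]]$image_size[1] - 1 &
      uv$uv[, 2] >= 0 & uv$uv[, 2] <= cams[[ci]]$image_size[2] - 1
    vis[idx[!inb]] <- FALSE
    idx <- which(vis)
    if (length(idx) == 0L) break
    t_hit <- ray_mesh_hits_cpp(smp$points[idx, , drop = FALSE],
                               dirs[idx, , drop = FALSE],
                               all_v0, all_v1, all_v2, 1e-6)
    occluded <- t_hit < seg_len[idx] - 1e-6
    vis[idx[occluded]] <- FALSE
  }
  vis
}

# projection that flags behind-camera points instead of erroring
project_safe <- function(cam, pts) {
  pc <- apply_transform(cam$pose, pts)
  ok <- pc[, 3] > 0
  uv <- cbind(cam$fx * pc[, 1] / pmax(pc[, 3], 1e-12) + cam$cx,
              cam$fy * pc[, 2] / pmax(pc[, 3], 1e-12) + cam$cy)
  list(uv = uv, ok = ok)
}

#' A camera pose looking at a target point
#'
#' Convenience builder: returns the patient -> camera transform for a
#' camera at `eye` looking towards `target` with the image x axis as close
#' to `up`-orthogonal as possible.
#'
#' @param eye,target 3-vectors (mm) in patient space.
#' @param up approximate up direction.
#' @return A `rigid_transform` (patient -> camera).
#' @export
look_at <- function(eye, target, up = c(0, 1, 0)) {
  z <- target - eye
  z <- z / sqrt(sum(z^2))
  x <- c(up[2] * z[3] - up[3] * z[2],
         up[3] * z[1] - up[1] * z[3],
         up[1] * z[2] - up[2] * z[1])
  if (sqrt(sum(x^2)) < 1e-9) {
    up <- c(1, 0, 0)
    x <- c(up[2] * z[3] - up[3] * z[2],
           up[3] * z[1] - up[1] * z[3],
           up[1] * z[2] - up[2] * z[1])
  }
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% eye))
}

#' Export a scene to plain-text files
#'
#' Writes the liver mesh and distractor meshes as ASCII PLY, landmarks as a
#' CSV (`name, x, y, z`, model space mm), and a JSON manifest with the
#' ground-truth pose and generator seed.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(scene$liver_mesh, file.path(dir, "liver.ply"))
  for (i in seq_along(scene$distractor_meshes)) {
    write_mesh(scene$distractor_meshes[[i]]$mesh,
               file.path(dir, sprintf("distractor_%d.ply", i)))
  }
  lm <- do.call(rbind, lapply(names(scene$landmarks), function(nm) {
    data.frame(name = nm, x = scene$landmarks[[nm]][1],
               y = scene$landmarks[[nm]][2], z = scene$landmarks[[nm]][3])
  }))
  utils::write.csv(lm, file.path(dir, "landmarks.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(seed = scene$seed,
         true_pose = transform_to_list(scene$true_pose),
         n_distractors = length(scene$distractor_meshes)),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
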