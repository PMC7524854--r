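# shared fixture builders; everything is generated in code, seeded

# random rigid transform with rotation up to `max_deg` and translation up
# to `max_t` mm
random_transform <- function(seed, max_deg = 180, max_t = 100) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  rigid_transform(nearest_rotation(R), runif(3, -max_t, max_t))
}

# a rectified stereo rig: parallel optical axes, baseline along +x
rectified_rig <- function(fx = 1000, baseline_mm = 4,
                          image_size = c(1920L, 1080L)) {
  cx <- image_size[1] / 2; cy <- image_size[2] / 2
  stereo_rig(
    pinhole_camera(fx, fx, cx, cy, image_size, identity_transform()),
    pinhole_camera(fx, fx, cx, cy, image_size,
                   rigid_transform(diag(3), c(-baseline_mm, 0, 0))))
}

# multi-patch observation of a scene from a fan of laparoscope viewpoints,
# reconstructed and bound into one labeled cloud
observe_cloud <- function(scene, n_patches = 3, n_points = 300,
                          noise_sd_px = 0, seed_base = 100,
                          class_fractions = NULL, az_step = 0.5) {
  ctr <- colMeans(scene$liver_mesh$vertices)
  ctr <- apply_transform(scene$true_pose, ctr)
  clouds <- lapply(seq_len(n_patches), function(k) {
    az <- (k - (n_patches + 1) / 2) * az_step
    eye <- ctr + 300 * c(sin(az) * 0.8, -0.55, -0.8 * cos(az))
    obs <- observe(scene, default_rig(), look_at(eye, ctr),
                   n_points = n_points, noise_sd_px = noise_sd_px,
                   seed = seed_base + k, class_fractions = class_fractions)
    reconstruct_patch(obs$rig, obs$correspondences)
  })
  bind_clouds(clouds)
}

table3_phase1_manual <- c(15.4, 22.7, 24.6, 5.9, 16.1, 10.0)
table3_phase2_manual <- c(9.2, 10.6, 17.5, 9.8, 12.5, 16.1, 9.6, 12.9, 2.8, 8.0)
table3_phase2_semiauto <- c(10.4, 8.7, 16.8, 9.8, 20.8, 11.6, 11.1, 16.8, 13.0, 19.9)
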