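# liverreg

Rigid registration and accuracy evaluation for augmented-reality
image-guided laparoscopic liver surgery — with a synthetic-scene harness
so the whole chain is testable without clinical data.

In AR image guidance, a preoperative 3D liver model must be registered to
the intraoperative anatomy. `liverreg` implements and evaluates the two
registration modes such systems offer:

* **manual** — an operator's pose *is* the registration;
* **semi-automatic** — a coarse manual initialisation refined by
  point-to-point **iterative closest point (ICP)** matching against a
  surface point cloud triangulated from the two channels of a stereo
  laparoscope.

The package covers the full chain:

| stage | functions |
|---|---|
| rigid transforms / point sets | `rigid_transform()`, `apply_transform()`, `compose()`, `invert()` |
| stereo camera model | `pinhole_camera()`, `stereo_rig()`, `project()`, `triangulate()`, `reconstruct_patch()` |
| synthetic scenes | `make_liver_mesh()`, `make_scene()`, `observe()` |
| segmentation gate | `gate_points()`, `gate_passthrough()` |
| registration | `kabsch_fit()`, `nearest_correspondences()`, `manual_init()`, `icp_register()` |
| accuracy (TRE) | `landmark_errors()`, `tre_rms()`, `tre_report()` |
| cohort statistics | `summarize_group()`, `shapiro_wilk()`, `two_sample_t_pooled()`, `paired_t()`, `analyze_cohort()` |
| batch pipeline / I/O | `run_pipeline()`, `stats_command()`, PLY/OBJ/CSV/JSON readers and writers |

Accuracy is scored as **target registration error (TRE)**: the root mean
square of Euclidean distances between corresponding anatomical landmarks
on the registered model and the patient, pooled over video frames, in mm
RMS:

    TRE = sqrt( mean( d_i^2 ) )

The segmentation gate reproduces a key clinical failure mode: stereo
reconstruction alone cannot tell liver surface from nearby structures
(e.g. diaphragm), and ICP fed the mixed cloud converges confidently to a
wrong pose; filtering to liver-labelled points first fixes it. The gate
here is an oracle on simulator labels with a configurable symmetric error
rate — a stand-in for a learned segmentation, substitutable behind the
same interface.

## Worked example

Reproduce the packaged two-phase clinical cohort analysis (6 phase-one
patients, manual registration only; 10 phase-two patients, both modes):

```r
library(liverreg)
print(stats_command(fixture = "table3"))
#> Cohort TRE analysis (mm RMS)
#>   phase 1 manual:    n =  6, 15.8 +/- 7.2 mm  (Shapiro-Wilk W = 0.953, p = 0.766)
#>   phase 2 manual:    n = 10, 10.9 +/- 4.2 mm  (Shapiro-Wilk W = 0.960, p = 0.787)
#>   phase 2 semiauto:  n = 10, 13.9 +/- 4.4 mm  (Shapiro-Wilk W = 0.901, p = 0.224)
#>   phase 1 vs phase 2 manual, pooled-independent t: estimate 4.9 mm (-1.1 to 10.9 mm 95% CI; p = 0.104)
#>   phase 2 manual vs semiauto, paired t: estimate -3.0 mm (-6.9 to 0.9 mm 95% CI; p = 0.117)
#>   phase 2 manual vs semiauto, pooled-independent t: estimate -3.0 mm (-7.0 to 1.0 mm 95% CI; p = 0.134)
```

Reading: manual accuracy improved from 15.8 ± 7.2 mm RMS in phase one to
10.9 ± 4.2 mm in phase two (not significant, p = 0.104); in phase two,
semi-automatic registration (13.9 ± 4.4 mm) was 3.0 mm worse than manual
on average, also not significant. The phase-2 contrast is reported under
both the paired and pooled variant deliberately — see the methods
vignette (`vignettes/registration-methods.Rmd`) for why.

And a fully synthetic registration with known ground truth:

```r
scene <- make_scene(seed = 31, n_landmarks = 4)
ctr   <- colMeans(scene$liver_mesh$vertices)
obs   <- observe(scene, default_rig(), look_at(ctr + c(0, -160, -250), ctr),
                 n_points = 500, noise_sd_px = 0, seed = 1)
cloud <- gate_points(reconstruct_patch(obs$rig, obs$correspondences), 0)
init  <- compose(rigid_transform(rot_y(5 * pi / 180), c(10, 0, 0)),
                 scene$true_pose)
res   <- icp_register(cloud, scene$liver_mesh, init,
                      icp_params(max_iterations = 1000))
pose_error(res$transform, scene$true_pose, at = ctr)
```

A command-line pipeline (`inst/cli/liverreg.R`) exposes `simulate`,
`reconstruct`, `gate`, `register`, `evaluate`, `stats` and `run`
subcommands; exit codes distinguish success (0), registration failure
(2), I/O errors (3) and schema errors (4).

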