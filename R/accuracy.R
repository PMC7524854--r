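#' Per-frame landmark distance errors
#'
#' Applies a registration to the model-space landmarks and measures the
#' Euclidean distance (mm) to the corresponding patient-space landmark
#' observed in each video frame. Landmark identification in the 2D image is
#' a human act outside this package's boundary: inputs are already
#' identified 3D positions.
#'
#' @param registration `rigid_transform`, model -> patient space.
#' @param model_landmarks named list (or named 3-column matrix rows) of
#'   model-space landmark positions (mm).
#' @param patient_landmarks_by_frame data frame with columns
#'   `frame_id, name, px, py, pz` (patient space, mm); landmark names may
#'   repeat across frames but must be unique within a frame.
#' @return data frame `frame_id, name, distance` (mm), one row per
#'   observed landmark. Unknown landmark names raise a schema error; an
#'   empty frame table raises an empty-input error.
#' @export
landmark_errors <- function(registration, model_landmarks,
                            patient_landmarks_by_frame) {
  stopifnot(is_rigid_transform(registration))
  pf <- as.data.frame(patient_landmarks_by_frame)
  need <- c("frame_id", "name", "px", "py", "pz")
  if (!all(need %in% names(pf))) {
    stop_liverreg("schema", paste("landmark frames need columns:",
                                  paste(need, collapse = ", ")))
  }
  if (nrow(pf) == 0L) {
    stop_liverreg("empty_input", "no landmark observations")
  }
  if (anyDuplicated(pf[, c("frame_id", "name")])) {
    stop_liverreg("schema", "duplicate landmark name within a frame")
  }
  if (is.matrix(model_landmarks)) {
    model_landmarks <- stats::setNames(
      lapply(seq_len(nrow(model_landmarks)),
             function(i) model_landmarks[i, ]),
      rownames(model_landmarks))
  }
  unknown <- setdiff(unique(pf$name), names(model_landmarks))
  if (length(unknown)) {
    stop_liverreg("schema", paste("unknown landmark name(s):",
                                  paste(unknown, collapse = ", ")))
  }
  model_mat <- do.call(rbind, model_landmarks[pf$name])
  mapped <- apply_transform(registration, model_mat)
  d <- sqrt(rowSums((mapped - as.matrix(pf[, c("px", "py", "pz")]))^2))
  data.frame(frame_id = pf$frame_id, name = pf$name, distance = d)
}

#' Root-mean-square of distance errors
#'
#' The accuracy unit of the evaluation protocol: the square root of the
#' arithmetic mean of the squared distance errors pooled over all frames
#' and landmarks, in millimetre RMS. Full precision internally; outputs are
#' rounded to 1 decimal only at report time.
#'
#' @param distances numeric vector of distance errors (mm), all >= 0.
#' @return RMS in mm.
#' @export
tre_rms <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) == 0L) {
    stop_liverreg("empty_input", "no distances supplied")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_liverreg("schema", "distances must be finite and non-negative")
  }
  sqrt(mean(d^2))
}

#' Target registration error report
#'
#' Bundles the per-frame landmark errors with their pooled RMS.
#'
#' @inheritParams landmark_errors
#' @return An object of class `tre_report`: `per_frame_errors` (data
#'   frame), `tre_mm` (pooled RMS), `n_frames`, `n_landmarks`.
#' @export
tre_report <- function(registration, model_landmarks,
                       patient_landmarks_by_frame) {
  errs <- landmark_errors(registration, model_landmarks,
                          patient_landmarks_by_frame)
  structure(list(per_frame_errors = errs,
                 tre_mm = tre_rms(errs$distance),
                 n_frames = length(unique(errs$frame_id)),
                 n_landmarks = length(unique(errs$name))),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("tre_report: TRE %.1f mm RMS (%d frames, %d landmarks)\n",
              x$tre_mm, x$n_frames, x$n_landmarks))
  invisible(x)
}

#' Serialise a TRE report
#'
#' JSON carries full precision plus the 1-decimal display value.
#'
#' @param report a `tre_report`.
#' @param path file path.
#' @export
tre_report_to_json <- function(report, path) {
  jsonlite::write_json(
    list(tre_mm = report$tre_mm,
         tre_mm_display = sprintf("%.1f", report$tre_mm),
         n_frames = report$n_frames, n_landmarks = report$n_landmarks,
         per_frame_errors = report$per_frame_errors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmark tables
#'
#' Model landmarks: CSV `name, x, y, z` (model space, mm).
#' Patient frames: CSV `frame_id, name, px, py, pz` (patient space, mm).
#'
#' @param path CSV path.
#' @return Named list of 3-vectors, or the frame data frame.
#' @export
read_model_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_liverreg("schema", "model landmark CSV needs columns name, x, y, z")
  }
  stats::setNames(lapply(seq_len(nrow(df)),
                         function(i) as.numeric(df[i, c("x", "y", "z")])),
                  df$name)
}

#' @rdname read_model_landmarks
#' @export
read_frame_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_id", "name", "px", "py", "pz")
  if (!all(need %in% names(df))) {
    stop_liverreg("schema",
                  "frame landmark CSV needs columns frame_id, name, px, py, pz")
  }
  df
}
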