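#' Labeled point clouds
#'
#' Reconstructed intraoperative surface points, each tagged with an integer
#' class label (0 = liver, >= 1 = distractor such as diaphragm) and the id
#' of the acquisition patch it came from.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param labels integer vector, length N, non-negative.
#' @param source_patch_id integer vector, length N (or scalar, recycled).
#' @return An object of class `labeled_point_cloud`.
#' @export
labeled_point_cloud <- function(points, labels = integer(0),
                                source_patch_id = 0L) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3)
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(labels) == 0L) labels <- rep(0L, n)
  labels <- as.integer(labels)
  if (length(source_patch_id) == 1L) source_patch_id <- rep(as.integer(source_patch_id), n)
  if (n > 0 && (ncol(points) != 3L || !all(is.finite(points)))) {
    stop_liverreg("invalid_geometry", "points must be finite N x 3")
  }
  if (length(labels) != n || any(labels < 0L)) {
    stop_liverreg("schema", "labels must be non-negative and match points")
  }
  if (length(source_patch_id) != n) {
    stop_liverreg("schema", "source_patch_id must match points")
  }
  structure(list(points = points, labels = labels,
                 source_patch_id = as.integer(source_patch_id)),
            class = "labeled_point_cloud")
}

#' @export
print.labeled_point_cloud <- function(x, ...) {
  cat(sprintf("labeled_point_cloud: %d points (%d liver, %d distractor)\n",
              nrow(x$points), sum(x$labels == 0L), sum(x$labels != 0L)))
  invisible(x)
}

#' Number of points in a labeled cloud
#' @param cloud a `labeled_point_cloud`.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Concatenate labeled point clouds
#' @param ... `labeled_point_cloud` objects.
#' @return One cloud with all points, labels and patch ids stacked.
#' @export
bind_clouds <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) &&
      !inherits(cs[[1]], "labeled_point_cloud")) cs <- cs[[1]]
  labeled_point_cloud(do.call(rbind, lapply(cs, function(c0) c0$points)),
                      unlist(lapply(cs, function(c0) c0$labels)),
                      unlist(lapply(cs, function(c0) c0$source_patch_id)))
}

#' Segmentation gate: keep liver-labelled points
#'
#' Functional stand-in for a learned liver-surface segmentation: an oracle
#' classifier on the simulator's labels with a configurable symmetric error
#' rate. Each point is kept iff `(label == 0) XOR flip`, where `flip` is an
#' independent Bernoulli(`error_rate`) draw. With `error_rate = 0` the
#' output is exactly the liver-labelled subset, in input order. The gate
#' never fabricates points: the output is always a subset of the input.
#'
#' @param cloud a `labeled_point_cloud`.
#' @param error_rate symmetric misclassification probability in [0, 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return The gated `labeled_point_cloud` (retained points keep their
#'   original labels and patch ids). An empty input yields an empty output.
#' @export
gate_points <- function(cloud, error_rate = 0, seed = 1L) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  if (error_rate < 0 || error_rate >= 1) {
    stop_liverreg("schema", "error_rate must be in [0, 1)")
  }
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  is_liver <- cloud$labels == 0L
  if (error_rate == 0) {
    keep <- is_liver
  } else {
    flip <- with_seed(seed, stats::runif(n) < error_rate)
    keep <- xor(is_liver, flip)
  }
  labeled_point_cloud(cloud$points[keep, , drop = FALSE],
                      cloud$labels[keep], cloud$source_patch_id[keep])
}

#' Pass-through gate (no segmentation)
#'
#' Identity filter reproducing the ungated failure mode, where surface
#' reconstruction cannot discriminate liver from surrounding structures and
#' every reconstructed point reaches the matcher.
#'
#' @param cloud a `labeled_point_cloud`.
#' @return The same cloud, unchanged.
#' @export
gate_passthrough <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_point_cloud"))
  cloud
}

#' Read / write labeled point clouds
#'
#' Primary carrier is ASCII PLY with an integer `label` vertex property
#' (and `patch_id`); CSV fallback has columns `x, y, z, label`.
#'
#' @param cloud a `labeled_point_cloud`.
#' @param path file path; format chosen by extension (`.ply` or `.csv`).
#' @export
write_cloud <- function(cloud, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                                z = cloud$points[, 3], label = cloud$labels,
                                patch_id = cloud$source_patch_id),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    write_ply(path, cloud$points, faces = NULL,
              vertex_int_props = list(label = cloud$labels,
                                      patch_id = cloud$source_patch_id))
  }
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    if (!all(c("x", "y", "z", "label") %in% names(df))) {
      stop_liverreg("schema", "cloud CSV needs columns x, y, z, label")
    }
    labeled_point_cloud(as.matrix(df[, c("x", "y", "z")]), df$label,
                        df$patch_id %||% 0L)
  } else {
    p <- read_ply(path)
    labeled_point_cloud(p$vertices,
                        p$vertex_props$label %||% rep(0L, nrow(p$vertices)),
                        p$vertex_props$patch_id %||% 0L)
  }
}
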