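#' Triangle meshes
#'
#' Minimal triangle-mesh container: `vertices` (V x 3, mm) and `faces`
#' (F x 3, 1-based vertex indices, consistently wound counter-clockwise
#' seen from outside for closed surfaces).
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L || !all(is.finite(vertices))) {
    stop_liverreg("invalid_geometry", "vertices must be a finite V x 3 matrix")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_liverreg("invalid_geometry", "face index out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

face_corners <- function(mesh) {
  list(v0 = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       v1 = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       v2 = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-face areas, normals, and mesh volume
#'
#' `mesh_volume` uses the divergence theorem (sum of signed tetrahedron
#' volumes), valid for closed, consistently wound meshes.
#'
#' @param mesh a `tri_mesh`.
#' @return Areas in mm^2, unit normals (F x 3), volume in mm^3.
#' @export
face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$v1 - fc$v0, fc$v2 - fc$v0)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$v1 - fc$v0, fc$v2 - fc$v0)
  n <- sqrt(rowSums(cr^2))
  cr / pmax(n, .Machine$double.eps)
}

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$v0 * row_cross(fc$v1, fc$v2))) / 6
}

#' Watertightness check
#'
#' A closed 2-manifold has every undirected edge shared by exactly two
#' faces, with opposite orientations.
#'
#' @param mesh a `tri_mesh`.
#' @return TRUE if every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Uniform area-weighted surface sampling
#'
#' Samples points uniformly by area over the surface: faces chosen with
#' probability proportional to area, barycentric coordinates uniform within
#' each face.
#'
#' @param mesh a `tri_mesh`.
#' @param n number of samples.
#' @param seed integer seed (all randomness in this package flows from
#'   explicit seeds).
#' @return list with `points` (n x 3 mm), `face` (face index per sample) and
#'   `normals` (outward unit normal of the source face).
#' @export
sample_mesh_points <- function(mesh, n, seed) {
  stopifnot(n >= 1)
  areas <- face_areas(mesh)
  smp <- with_seed(seed, list(
    fi = sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas),
    r1 = stats::runif(n), r2 = stats::runif(n)))
  fi <- smp$fi
  r1 <- sqrt(smp$r1); r2 <- smp$r2
  a <- 1 - r1; b <- r1 * (1 - r2); c0 <- r1 * r2
  fc <- face_corners(mesh)
  pts <- a * fc$v0[fi, , drop = FALSE] + b * fc$v1[fi, , drop = FALSE] +
    c0 * fc$v2[fi, , drop = FALSE]
  list(points = pts, face = fi, normals = face_normals(mesh)[fi, , drop = FALSE])
}

#' Transform a mesh rigidly
#' @param mesh a `tri_mesh`.
#' @param T a `rigid_transform`.
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, T) {
  tri_mesh(apply_transform(T, mesh$vertices), mesh$faces)
}

#' Exact minimum distance from points to a mesh surface
#'
#' Point-to-triangle distance minimised over all faces; used to verify
#' landmark/surface contracts and distractor clearance.
#'
#' @param points N x 3 matrix (mm).
#' @param mesh a `tri_mesh`.
#' @return numeric vector of N distances (mm).
#' @export
points_to_mesh_distance <- function(points, mesh) {
  points <- as_points_matrix(points)
  fc <- face_corners(mesh)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    out[i] <- min(point_triangle_dist(points[i, ], fc$v0, fc$v1, fc$v2))
  }
  out
}

# face 1-ring: for each face, itself plus every face sharing a vertex,
# as an F x K index matrix padded with NA
face_ring <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  by_vertex <- split(rep(seq_len(nf), 3L), as.vector(f))
  rings <- lapply(seq_len(nf), function(i) {
    unique(c(i, unlist(by_vertex[as.character(f[i, ])], use.names = FALSE)))
  })
  k <- max(lengths(rings))
  out <- matrix(NA_integer_, nf, k)
  for (i in seq_len(nf)) out[i, seq_along(rings[[i]])] <- rings[[i]]
  out
}

# row-wise closest point on triangles: points[i, ] against the triangle
# (v0[i, ], v1[i, ], v2[i, ]); all inputs N x 3
closest_point_on_triangles <- function(points, v0, v1, v2) {
  e0 <- v1 - v0
  e1 <- v2 - v0
  d <- points - v0
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c0 <- rowSums(e1 * e1)
  d0 <- rowSums(e0 * d); d1 <- rowSums(e1 * d)
  det <- pmax(a * c0 - b * b, .Machine$double.eps)
  s <- (c0 * d0 - b * d1) / det
  t0 <- (a * d1 - b * d0) / det
  inside <- s >= 0 & t0 >= 0 & s + t0 <= 1
  pt_at <- function(ss, tt) v0 + ss * e0 + tt * e1
  dist2_to <- function(q) rowSums((q - points)^2)
  # candidate edge projections
  s_e0 <- pmin(pmax(d0 / pmax(a, .Machine$double.eps), 0), 1)
  t_e1 <- pmin(pmax(d1 / pmax(c0, .Machine$double.eps), 0), 1)
  e2 <- v2 - v1
  u_e2 <- pmin(pmax(rowSums(e2 * (points - v1)) /
                      pmax(rowSums(e2 * e2), .Machine$double.eps), 0), 1)
  q1 <- pt_at(s_e0, 0); q2 <- pt_at(0, t_e1); q3 <- pt_at(1 - u_e2, u_e2)
  d2_1 <- dist2_to(q1); d2_2 <- dist2_to(q2); d2_3 <- dist2_to(q3)
  best <- q1
  bd <- d2_1
  sw <- d2_2 < bd; best[sw, ] <- q2[sw, , drop = FALSE]; bd[sw] <- d2_2[sw]
  sw <- d2_3 < bd; best[sw, ] <- q3[sw, , drop = FALSE]; bd[sw] <- d2_3[sw]
  qi <- pt_at(pmin(pmax(s, 0), 1), pmin(pmax(t0, 0), 1))
  best[inside, ] <- qi[inside, , drop = FALSE]
  best
}

# vectorised point-to-triangle distance (Eberly's region decomposition,
# expressed via clamped barycentric projection)
point_triangle_dist <- function(p, v0, v1, v2) {
  e0 <- v1 - v0
  e1 <- v2 - v0
  d <- sweep(-v0, 2, -p)           # p - v0 per triangle
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c0 <- rowSums(e1 * e1)
  d0 <- rowSums(e0 * d); d1 <- rowSums(e1 * d)
  det <- pmax(a * c0 - b * b, .Machine$double.eps)
  s <- (c0 * d0 - b * d1) / det
  t0 <- (a * d1 - b * d0) / det
  # clamp to the triangle: project onto edges when outside
  inside <- s >= 0 & t0 >= 0 & s + t0 <= 1
  s2 <- pmin(pmax(s, 0), 1)
  t2 <- pmin(pmax(t0, 0), 1)
  # candidate closest points: interior projection (clamped) and the three edges
  cand_dist2 <- function(ss, tt) {
    q <- v0 + ss * e0 + tt * e1
    rowSums(sweep(q, 2, p)^2)
  }
  # edge v0-v1 (t=0), edge v0-v2 (s=0), edge v1-v2 (s+t=1)
  s_e0 <- pmin(pmax(d0 / a, 0), 1)
  t_e1 <- pmin(pmax(d1 / c0, 0), 1)
  # param along v1->v2: minimise |v1 + u (v2 - v1) - p|
  e2 <- v2 - v1
  u_e2 <- pmin(pmax(rowSums(e2 * sweep(-v1, 2, -p)) / pmax(rowSums(e2 * e2),
               .Machine$double.eps), 0), 1)
  d2 <- pmin(cand_dist2(s_e0, 0), cand_dist2(0, t_e1),
             cand_dist2(1 - u_e2, u_e2))
  d2[inside] <- cand_dist2(s2, t2)[inside]
  sqrt(pmax(d2, 0))
}

# evaluate `code` under a private RNG stream seeded from an explicit
# integer, restoring the caller's RNG state afterwards (determinism
# contract: identical seeds give bit-identical results, and seeded calls
# never perturb the surrounding RNG)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
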