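#' Read and write triangle meshes (ASCII PLY / OBJ)
#'
#' PLY is the primary carrier (it supports per-vertex integer properties,
#' used for point-cloud labels); OBJ covers plain geometry exchange. Both
#' readers are ASCII-only. Round trips preserve vertices and faces to full
#' float precision.
#'
#' @param path file path; format chosen by extension (`.ply` / `.obj`).
#' @param mesh a `tri_mesh`.
#' @return `read_mesh` returns a `tri_mesh` with attribute `watertight`;
#'   a non-manifold mesh loads with a warning and `watertight = FALSE`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) {
    stop_liverreg("io", paste("file not found:", path))
  }
  m <- if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    read_obj(path)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    p <- read_ply(path)
    if (is.null(p$faces) || nrow(p$faces) == 0L) {
      stop_liverreg("format", paste("PLY has no faces (a point cloud?):", path))
    }
    tri_mesh(p$vertices, p$faces)
  } else {
    stop_liverreg("format", "mesh format must be .ply or .obj")
  }
  wt <- is_watertight(m)
  if (!wt) {
    warning("mesh is not watertight: ", path, call. = FALSE)
  }
  attr(m, "watertight") <- wt
  m
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    write_obj(mesh, path)
  } else {
    write_ply(path, mesh$vertices, mesh$faces)
  }
  invisible(path)
}

# ---- ASCII PLY ----

# writer: vertices (+ optional integer vertex properties), optional faces.
# %.17g keeps doubles exact through the round trip
write_ply <- function(path, vertices, faces = NULL,
                      vertex_int_props = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(vertices)
  header <- c("ply", "format ascii 1.0",
              "comment produced by liverreg (units: mm)",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z")
  for (nm in names(vertex_int_props)) {
    header <- c(header, sprintf("property int %s", nm))
  }
  if (!is.null(faces)) {
    header <- c(header, sprintf("element face %d", nrow(faces)),
                "property list uchar int vertex_indices")
  }
  header <- c(header, "end_header")
  writeLines(header, con)
  vlines <- apply(vertices, 1L, function(r) paste(sprintf("%.17g", r),
                                                  collapse = " "))
  if (length(vertex_int_props)) {
    extra <- do.call(paste, c(lapply(vertex_int_props, as.integer),
                              list(sep = " ")))
    vlines <- paste(vlines, extra)
  }
  writeLines(vlines, con)
  if (!is.null(faces)) {
    writeLines(paste("3", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
               con)
  }
  invisible(path)
}

# reader: enough PLY generality for this package's own files plus simple
# third-party ASCII PLYs (scalar vertex properties, triangular faces)
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop_liverreg("format", sprintf("%s: not a PLY file (line 1)", path))
  }
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) {
    stop_liverreg("format", sprintf("%s: missing end_header", path))
  }
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header))) {
    stop_liverreg("format", sprintf("%s: only ASCII PLY is supported", path))
  }
  elements <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = character(0),
                              list_prop = FALSE)
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        elements[[cur]]$list_prop <- TRUE
      } else {
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[length(tok)])
      }
    }
  }
  if (is.null(elements$vertex)) {
    stop_liverreg("format", sprintf("%s: no vertex element", path))
  }
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  nv <- elements$vertex$count
  if (length(body) < nv) {
    stop_liverreg("format",
                  sprintf("%s: vertex data truncated (line %d)", path,
                          endh + length(body) + 1L))
  }
  vp <- elements$vertex$props
  vdat <- utils::read.table(text = body[seq_len(nv)], col.names = vp,
                            colClasses = "numeric")
  if (!all(c("x", "y", "z") %in% vp)) {
    stop_liverreg("format", sprintf("%s: vertex element lacks x/y/z", path))
  }
  vm <- as.matrix(vdat[, c("x", "y", "z")])
  dimnames(vm) <- NULL
  out <- list(vertices = vm,
              vertex_props = as.list(vdat[, setdiff(vp, c("x", "y", "z")),
                                          drop = FALSE]),
              faces = NULL)
  if (!is.null(elements$face) && elements$face$count > 0L) {
    nf <- elements$face$count
    flines <- body[nv + seq_len(nf)]
    if (length(flines) < nf || anyNA(flines)) {
      stop_liverreg("format", sprintf("%s: face data truncated", path))
    }
    fdat <- strsplit(trimws(flines), "\\s+")
    sizes <- vapply(fdat, function(x) as.integer(x[1]), integer(1))
    if (any(sizes != 3L)) {
      stop_liverreg("format",
                    sprintf("%s: only triangular faces supported (line %d)",
                            path, endh + nv + which(sizes != 3L)[1]))
    }
    out$faces <- do.call(rbind, lapply(fdat, function(x) {
      as.integer(x[2:4]) + 1L
    }))
  }
  out
}

# ---- OBJ ----

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# produced by liverreg (units: mm)", con)
  writeLines(paste("v", sprintf("%.17g", mesh$vertices[, 1]),
                   sprintf("%.17g", mesh$vertices[, 2]),
                   sprintf("%.17g", mesh$vertices[, 3])), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop_liverreg("format", sprintf("%s: OBJ needs v and f records", path))
  }
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    # tolerate v/vt/vn references; only triangles
    idx <- as.integer(sub("/.*$", "", x[-1]))
    if (length(idx) != 3L) {
      stop_liverreg("format", sprintf("%s: only triangular OBJ faces", path))
    }
    idx
  }))
  tri_mesh(verts, faces)
}
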