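#' Construct a triangle surface mesh
#'
#' Vertices are world coordinates in mm; faces index vertices (1-based) and
#' are consistently oriented with outward normals. Meshes produced by
#' [marching_cubes()] are watertight: every edge is shared by exactly two
#' faces.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of vertex indices.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param m a [surface_mesh()].
#' @return scalar area.
#' @export
mesh_area <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  u <- m$vertices[m$faces[, 2], , drop = FALSE] - a
  w <- m$vertices[m$faces[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sum(sqrt(rowSums(cr^2)))
}

#' Enclosed volume of a closed mesh (mm^3), by the divergence theorem
#'
#' Signed tetrahedron sum; positive for outward-oriented watertight meshes.
#' @param m a [surface_mesh()].
#' @return scalar volume.
#' @export
mesh_volume <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Check that every mesh edge is shared by exactly two faces
#' @param m a [surface_mesh()].
#' @return TRUE if watertight (2-manifold without boundary).
#' @export
is_watertight <- function(m) {
  f <- m$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a triangle mesh to OBJ, STL (ASCII) or PLY (ASCII)
#'
#' Coordinates are written in world mm. OBJ and PLY preserve shared vertices;
#' STL stores one triangle at a time, so vertex count may change on a
#' round-trip while surface area is preserved.
#'
#' @param m a [surface_mesh()] with at least one face.
#' @param path output file; extension selects the format unless `format`
#'   is given.
#' @param format `"auto"`, `"obj"`, `"stl"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path, format = c("auto", "obj", "stl", "ply")) {
  format <- match.arg(format)
  if (nrow(m$faces) < 1) stop("refusing to write an empty mesh")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "stl", "ply"))
      stop("unsupported mesh format '", ext, "'; supported: obj, stl, ply")
    format <- ext
  }
  v <- m$vertices; f <- m$faces
  lines <- switch(format,
    obj = c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    stl = {
      a <- v[f[, 1], , drop = FALSE]
      b <- v[f[, 2], , drop = FALSE]
      cc <- v[f[, 3], , drop = FALSE]
      u <- b - a; w <- cc - a
      nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                   u[, 3] * w[, 1] - u[, 1] * w[, 3],
                   u[, 1] * w[, 2] - u[, 2] * w[, 1])
      len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
      nrm <- nrm / len
      body <- vapply(seq_len(nrow(f)), function(i) paste(
        sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2],
                nrm[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("    vertex %.9g %.9g %.9g", cc[i, 1], cc[i, 2], cc[i, 3]),
        "  endloop", "endfacet", sep = "\n"), "")
      c("solid mesh", body, "endsolid mesh")
    })
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#' @param path mesh file (.obj, .stl ascii, .ply ascii).
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
      as.numeric(p[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    surface_mesh(v, f)
  } else if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    start <- which(lines == "end_header") + 1L
    v <- do.call(rbind, lapply(strsplit(lines[start:(start + nv - 1L)],
                                        "\\s+"), function(p)
      as.numeric(p[1:3])))
    f <- do.call(rbind, lapply(
      strsplit(lines[(start + nv):(start + nv + nf - 1L)], "\\s+"),
      function(p) as.integer(p[2:4]) + 1L))
    surface_mesh(v, f)
  } else if (ext == "stl") {
    vl <- grep("vertex", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
    surface_mesh(v, f)
  } else stop("unsupported mesh format '", ext, "'")
}
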