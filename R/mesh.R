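#' Extract the lumen isosurface
#'
#' Isosurface of a mask (iso 0.5, the default route "from the segmentation
#' result") or of an HU volume at a mid-wall iso value. Cells are tessellated
#' into six tetrahedra around a fixed diagonal — a translation-invariant
#' decomposition, so the triangulation agrees between neighbouring cells and
#' the mesh is watertight by construction with no ambiguous configurations.
#' Vertices are placed on grid edges by linear interpolation and mapped to
#' world mm via spacing and origin; faces are oriented outward. If the
#' object touches the volume boundary, the field is zero-padded by one voxel
#' so the surface still closes.
#'
#' Binary masks are anti-aliased first (Gaussian prefilter,
#' `antialias_sigma` voxels) so edge vertices interpolate partial-volume
#' values instead of snapping to edge midpoints; the default 0.6 voxels
#' removes most staircase area excess while biasing the radius of a
#' 5-voxel-radius tube by well under a tenth of a voxel. HU volumes are
#' assumed already smooth and are not prefiltered.
#'
#' @param x a [label_mask()] (binary occupancy is used) or [ct_volume()].
#' @param iso iso value, strictly between the data min and max.
#' @param antialias_sigma prefilter sigma in voxels for binary masks
#'   (0 disables).
#' @return A [surface_mesh()].
#' @export
marching_cubes <- function(x, iso = 0.5, antialias_sigma = 0.6) {
  if (inherits(x, "label_mask")) {
    field <- array(as.numeric(x$data > 0L), dim = dim(x$data))
    if (antialias_sigma > 0)
      field <- fft_convolve(field,
                            gaussian_kernel_3d(rep(antialias_sigma, 3)))
  } else if (inherits(x, "ct_volume")) {
    field <- x$data
  } else stop("`x` must be a label_mask or ct_volume")
  if (!(iso < max(field)))
    stop("iso value ", iso, " outside the data range (max ",
         max(field), "): empty level set")
  d <- dim(field)
  # pad so surfaces close at the boundary (masks pad with background 0)
  lowval <- if (inherits(x, "label_mask")) 0 else min(field)
  padded <- array(lowval, dim = d + 2L)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- field
  mc <- cpp_march_tetra(as.numeric(padded), d[1] + 2L, d[2] + 2L, d[3] + 2L,
                        iso)
  if (nrow(mc$vertices) == 0) stop("empty level set at iso ", iso)
  vox <- mc$vertices - 1  # undo the pad: back to 0-based grid indices
  verts <- index_to_world(x, vox)
  surface_mesh(verts, mc$faces)
}

# vertex adjacency (sparse, symmetric) from the face list
mesh_adjacency <- function(m) {
  f <- m$faces
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = rep(nrow(m$vertices), 2))
  a@x[] <- 1  # duplicate edges collapse to weight 1
  methods::as(a, "CsparseMatrix")
}

#' Curvature smoothing of a surface mesh (Taubin lambda/mu)
#'
#' Alternates a Laplacian shrink step (`lambda`) with a slightly larger
#' inflate step (`mu < -lambda`), the classic non-shrinking low-pass filter
#' on mesh geometry: staircase jag is removed while enclosed volume is
#' preserved to well under 1% at the defaults. Connectivity is untouched, so
#' watertightness is preserved. Zero iterations is the identity.
#'
#' @param m a [surface_mesh()]; must be watertight (every edge on two
#'   faces) — non-manifold input is an error naming offending edges.
#' @param iterations number of lambda+mu passes.
#' @param lambda,mu Taubin step sizes.
#' @return Smoothed [surface_mesh()].
#' @export
curvature_smooth <- function(m, iterations = 20, lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(m, "surface_mesh"))
  if (iterations == 0) return(m)
  f <- m$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2L]
  if (length(bad) > 0)
    stop("mesh is not watertight/manifold; offending edges (vertex pairs): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" and %d more", length(bad) - 5) else "")
  a <- mesh_adjacency(m)
  deg <- Matrix::rowSums(a)
  v <- m$vertices
  for (it in seq_len(iterations)) {
    lap <- as.matrix(a %*% v) / deg - v
    v <- v + lambda * lap
    lap <- as.matrix(a %*% v) / deg - v
    v <- v + mu * lap
  }
  surface_mesh(v, m$faces)
}
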