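#' Thin a lumen mask to a voxel skeleton
#'
#' Homotopy-preserving 3D curve thinning: border voxels that are simple
#' points (removal changes neither foreground 26-topology nor background
#' 6-topology) and not curve endpoints are deleted in six directional
#' subiterations (up/down/north/south/east/west) until stable, with a
#' sequential re-check at deletion time so topology is preserved exactly.
#' The result stays inside the mask and is 26-connected. Discrete skeletons
#' are jagged by nature; [smooth_points()] and [bezier_refine()] lift them
#' to sub-voxel accuracy.
#'
#' @param mask a [label_mask()] with exactly one 26-connected foreground
#'   component (labels 1 and 2 both count as foreground).
#' @return Object of class `skeleton`: `voxels` (n x 3, 1-based indices),
#'   `spacing`, `origin`.
#' @export
thin_skeleton <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask$data)
  m <- as.integer(mask$data > 0L)
  lab <- cpp_label_components(m, d[1], d[2], d[3], 26L)
  ncomp <- max(lab)
  if (ncomp == 0) stop("mask is empty")
  if (ncomp > 1)
    stop("mask has ", ncomp, " connected components; thin one vessel at a ",
         "time (split the mask first)")
  thin <- cpp_thin(m, d[1], d[2], d[3])
  vox <- arrayInd(which(thin == 1L), d)
  structure(list(voxels = vox, spacing = mask$spacing, origin = mask$origin,
                 dim = d),
            class = "skeleton")
}

#' @exportS3Method base::print
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels\n", nrow(x$voxels)))
  invisible(x)
}

skeleton_graph <- function(s) {
  vox <- s$voxels
  n <- nrow(vox)
  # pairs of 26-adjacent skeleton voxels
  key <- vox[, 1] + (max(vox[, 1]) + 2) *
    (vox[, 2] + (max(vox[, 2]) + 2) * vox[, 3])
  off <- neighbor_offsets(26)
  idx_of <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, off[k, ], `+`)
    nbkey <- nb[, 1] + (max(vox[, 1]) + 2) *
      (nb[, 2] + (max(vox[, 2]) + 2) * nb[, 3])
    for (i in seq_len(n)) {
      j <- mget(as.character(nbkey[i]), envir = idx_of,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > i) {
        from <- c(from, i); to <- c(to, j)
        w <- c(w, sqrt(sum(((vox[i, ] - vox[j, ]) * s$spacing)^2)))
      }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Extract the main path through a skeleton
#'
#' Side branches left by thinning are pruned to a single ordered path. With
#' endpoints given, the (weighted) shortest graph path between them; without,
#' the graph-diameter path — the longest shortest-path, with geodesic length
#' measured in mm. Endpoints not on the skeleton are snapped to the nearest
#' skeleton voxel within 3 voxels, else it is an error. Diameter ties are
#' broken by the lexicographically smallest endpoint pair.
#'
#' @param s a `skeleton` from [thin_skeleton()].
#' @param endpoints optional 2 x 3 matrix of voxel indices (1-based).
#' @return n x 3 matrix of ordered voxel indices (class kept plain; feed to
#'   [smooth_points()] / [bezier_refine()] after [index_to_world()]).
#' @export
extract_main_path <- function(s, endpoints = NULL) {
  stopifnot(inherits(s, "skeleton"))
  n <- nrow(s$voxels)
  if (n == 1) return(s$voxels)
  g <- skeleton_graph(s)
  if (igraph::components(g)$no > 1)
    stop("skeleton is not connected")
  if (!is.null(endpoints)) {
    endpoints <- matrix(as.numeric(endpoints), ncol = 3)
    ends <- vapply(1:2, function(k) {
      dd <- sqrt(colSums((t(s$voxels) - endpoints[k, ])^2))
      i <- which.min(dd)
      if (dd[i] > 3)
        stop("endpoint (", paste(endpoints[k, ], collapse = ", "),
             ") is more than 3 voxels from the skeleton")
      i
    }, 1L)
    p <- igraph::shortest_paths(g, ends[1], ends[2],
                                output = "vpath")$vpath[[1]]
    return(s$voxels[as.integer(p), , drop = FALSE])
  }
  deg <- igraph::degree(g)
  leaves <- which(deg <= 1)
  if (length(leaves) < 2) leaves <- seq_len(n)  # cycle: fall back to all
  dm <- igraph::distances(g, v = leaves, to = leaves)
  dm[!is.finite(dm)] <- -Inf
  best <- which(dm == max(dm), arr.ind = TRUE)
  pair <- t(apply(best, 1, function(r)
    sort(c(leaves[r[1]], leaves[r[2]]))))
  pair <- unique(pair)
  ord <- order(pair[, 1], pair[, 2])
  a <- pair[ord[1], 1]; b <- pair[ord[1], 2]
  p <- igraph::shortest_paths(g, a, b, output = "vpath")$vpath[[1]]
  s$voxels[as.integer(p), , drop = FALSE]
}

#' Moving-average smoothing of an ordered point path
#'
#' Coordinate-wise moving average with a window that shrinks symmetrically
#' near the ends, so the first and last points are preserved exactly. This
#' removes the staircase jag of a thinned skeleton before Bezier
#' interpolation.
#'
#' @param points n x 3 matrix of ordered points.
#' @param window odd integer >= 3, <= path length.
#' @return n x 3 matrix of smoothed points.
#' @export
smooth_points <- function(points, window = 5) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (window < 3 || window %% 2 == 0)
    stop("`window` must be an odd integer >= 3")
  if (window > n) stop("`window` exceeds the path length")
  half <- (window - 1) %/% 2
  out <- points
  cs <- apply(rbind(0, points), 2, cumsum)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i, ] <- (cs[i + h + 1, ] - cs[i - h, ]) / (2 * h + 1)
  }
  out
}

new_centerline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-12)
  points <- points[keep, , drop = FALSE]
  n <- nrow(points)
  if (n < 2) stop("a centerline needs at least 2 distinct points")
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  if (n == 2) {
    tang <- rbind(points[2, ] - points[1, ], points[2, ] - points[1, ])
    tang <- tang / sqrt(rowSums(tang^2))
    return(structure(list(points = points, s = s, tangents = tang),
                     class = "centerline"))
  }
  tang <- rbind(points[2, ] - points[1, ],
                points[pmin(3:n, n), , drop = FALSE] -
                  points[pmax(1:(n - 2), 1), , drop = FALSE],
                points[n, ] - points[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, s = s, tangents = tang),
            class = "centerline")
}

#' @exportS3Method base::print
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$s)))
  invisible(x)
}

#' Refine a discrete path to a sub-voxel centerline by local Bezier curves
#'
#' A single global Bezier over all thinned points over-smooths; instead,
#' overlapping local cubic Bezier curves (windows of four consecutive
#' points, 50% overlap) are blended linearly across their shared span to a
#' continuous curve. Because Bezier control points need not lie on the
#' curve, the grid jag of the controls is filtered out while the curve stays
#' close to the path; collinear controls yield a collinear curve. The dense
#' samples are arc-length parameterized with tangents by central
#' differences. Consecutive duplicate points are removed with a warning.
#'
#' @param points n x 3 matrix of ordered (already smoothed) world points,
#'   n >= 4.
#' @param samples_per_segment dense samples per control-point interval.
#' @return A `centerline` (fields `points`, `s`, `tangents`).
#' @export
bezier_refine <- function(points, samples_per_segment = 10) {
  points <- matrix(as.numeric(points), ncol = 3)
  dup <- c(FALSE, rowSums(abs(diff(points))) < 1e-12)
  if (any(dup)) {
    warning("removed ", sum(dup), " duplicate consecutive point(s)")
    points <- points[!dup, , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 4) stop("need at least 4 distinct points for Bezier refinement")
  seg <- sqrt(rowSums(diff(points)^2))
  t_ctrl <- c(0, cumsum(seg))  # chord-length positions of the controls
  ks <- seq(1, n - 3, by = 2)
  if (ks[length(ks)] + 3 < n) ks <- c(ks, n - 3)
  wins <- lapply(ks, function(k) list(k = k, t0 = t_ctrl[k],
                                      t1 = t_ctrl[k + 3]))
  nu <- max(4L * samples_per_segment, (n - 1L) * samples_per_segment)
  u <- seq(0, t_ctrl[n], length.out = nu)
  acc <- matrix(0, nu, 3)
  wsum <- numeric(nu)
  for (wi in seq_along(wins)) {
    w <- wins[[wi]]
    inw <- u >= w$t0 - 1e-12 & u <= w$t1 + 1e-12
    if (!any(inw)) next
    tt <- (u[inw] - w$t0) / (w$t1 - w$t0)
    p0 <- points[w$k, ]; p1 <- points[w$k + 1, ]
    p2 <- points[w$k + 2, ]; p3 <- points[w$k + 3, ]
    b <- outer((1 - tt)^3, p0) + outer(3 * (1 - tt)^2 * tt, p1) +
      outer(3 * (1 - tt) * tt^2, p2) + outer(tt^3, p3)
    # blend weight: distance to the window edge; first/last windows are
    # extended so the curve endpoints keep full weight
    dl <- if (wi == 1) rep(Inf, sum(inw)) else u[inw] - w$t0
    dr <- if (wi == length(wins)) rep(Inf, sum(inw)) else w$t1 - u[inw]
    wgt <- pmin(dl, dr)
    wgt[!is.finite(wgt)] <- max(t_ctrl[n], 1)
    wgt <- pmax(wgt, 1e-12)
    acc[inw, ] <- acc[inw, ] + b * wgt
    wsum[inw] <- wsum[inw] + wgt
  }
  pts <- acc / wsum
  pts[1, ] <- points[1, ]; pts[nu, ] <- points[n, ]
  new_centerline(pts)
}

#' Resample a centerline at uniform arc-length intervals
#'
#' Linear interpolation along the polyline at steps of `step` mm; the first
#' and last points are preserved, and total length is preserved to well
#' under 0.1%. Resampling twice with the same step is idempotent within
#' tolerance.
#'
#' @param c a `centerline`.
#' @param step arc-length step, mm (> 0).
#' @return A resampled `centerline`.
#' @export
resample_centerline <- function(c, step = 0.25) {
  stopifnot(inherits(c, "centerline"), step > 0)
  L <- max(c$s)
  s_new <- seq(0, L, by = step)
  if (L - s_new[length(s_new)] > 1e-9 * max(L, 1)) s_new <- c(s_new, L)
  pts <- cbind(stats::approx(c$s, c$points[, 1], xout = s_new)$y,
               stats::approx(c$s, c$points[, 2], xout = s_new)$y,
               stats::approx(c$s, c$points[, 3], xout = s_new)$y)
  new_centerline(pts)
}

#' Test whether points lie inside a closed mesh (ray crossing)
#'
#' Counts intersections of a +x ray with the mesh triangles
#' (Moller-Trumbore); odd count = inside. Used to verify the invariant that
#' every centerline point lies inside the lumen surface.
#'
#' @param points n x 3 matrix (world mm).
#' @param m a watertight [surface_mesh()].
#' @return logical vector.
#' @export
points_in_mesh <- function(points, m) {
  points <- matrix(as.numeric(points), ncol = 3)
  v0 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v1 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 3], , drop = FALSE]
  e1 <- v1 - v0; e2 <- v2 - v0
  dirx <- c(1, 0, 0)
  # h = dir x e2 (constant dir): h = (0, -e2z, e2y)
  hx <- 0; hy <- -e2[, 3]; hz <- e2[, 2]
  a <- e1[, 2] * hy + e1[, 3] * hz
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    ok <- abs(a) > 1e-12
    sx <- p[1] - v0[, 1]; sy <- p[2] - v0[, 2]; sz <- p[3] - v0[, 3]
    uu <- (sy * hy + sz * hz) / a
    # q = s x e1
    qx <- sy * e1[, 3] - sz * e1[, 2]
    qy <- sz * e1[, 1] - sx * e1[, 3]
    qz <- sx * e1[, 2] - sy * e1[, 1]
    vv <- qx / a
    tt <- (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz) / a
    hit <- ok & uu >= 0 & vv >= 0 & (uu + vv) <= 1 & tt > 1e-9
    sum(hit) %% 2 == 1
  }, TRUE)
}
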