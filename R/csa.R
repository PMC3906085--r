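#' Intersect a plane with a surface mesh and return the lumen contour
#'
#' Triangle-plane intersection segments are chained into closed loops
#' through shared mesh edges (exact keys, no coordinate snapping), which is
#' why the mesh must be watertight: an open chain is an error naming the gap
#' location. When the plane cuts the mesh in several loops (e.g. grazing a
#' bend twice), the loop containing the query point — or failing that the
#' loop with the nearest centroid — is returned, unless `all = TRUE`.
#'
#' @param m a [surface_mesh()].
#' @param center point on the plane (world mm); also the query point used to
#'   select among multiple loops.
#' @param normal plane normal (normalized internally).
#' @param all return all loops as a list instead of the selected one.
#' @return k x 3 matrix of ordered loop vertices (closed implicitly:
#'   last connects to first), or a list of such matrices when `all = TRUE`.
#' @export
slice_mesh <- function(m, center, normal, all = FALSE) {
  stopifnot(inherits(m, "surface_mesh"))
  center <- as.numeric(center)
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  sd <- as.numeric((m$vertices - matrix(center, nrow(m$vertices), 3,
                                        byrow = TRUE)) %*% normal)
  # nudge on-plane vertices so every cut triangle has exactly two cut edges
  eps <- 1e-9 * max(abs(sd), 1)
  sd[sd == 0] <- eps
  f <- m$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  cut <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(cut)) stop("plane does not intersect the mesh")
  fc <- f[cut, , drop = FALSE]
  scut <- cbind(sd[fc[, 1]], sd[fc[, 2]], sd[fc[, 3]])
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  segs_from <- character(0); segs_to <- character(0)
  pt_of <- list()
  ek <- list(c(1, 2), c(2, 3), c(3, 1))
  keys <- matrix("", nrow(fc), 3)
  crossed <- matrix(FALSE, nrow(fc), 3)
  for (e in 1:3) {
    a <- fc[, ek[[e]][1]]; b <- fc[, ek[[e]][2]]
    sa <- scut[, ek[[e]][1]]; sb <- scut[, ek[[e]][2]]
    cr <- sa * sb < 0
    crossed[, e] <- cr
    keys[, e] <- edge_key(a, b)
    if (any(cr)) {
      t <- sa[cr] / (sa[cr] - sb[cr])
      p <- m$vertices[a[cr], , drop = FALSE] +
        t * (m$vertices[b[cr], , drop = FALSE] -
               m$vertices[a[cr], , drop = FALSE])
      kk <- keys[cr, e]
      for (i in seq_along(kk)) pt_of[[kk[i]]] <- p[i, ]
    }
  }
  ncr <- rowSums(crossed)
  if (any(ncr != 2))
    stop("degenerate plane-triangle intersection; move the plane slightly")
  seg <- t(vapply(seq_len(nrow(fc)), function(i)
    keys[i, crossed[i, ]], character(2)))
  # chain: each edge key appears in exactly two segments on a closed mesh
  nbr <- new.env(hash = TRUE)
  for (i in seq_len(nrow(seg))) {
    for (ab in list(seg[i, ], rev(seg[i, ]))) {
      cur <- mget(ab[1], envir = nbr, ifnotfound = list(character(0)))[[1]]
      assign(ab[1], c(cur, ab[2]), envir = nbr)
    }
  }
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (start in unique(as.vector(seg))) {
    if (!is.null(visited[[start]])) next
    chain <- character(0)
    cur <- start; prev <- NA_character_
    closed <- FALSE
    repeat {
      visited[[cur]] <- TRUE
      chain <- c(chain, cur)
      nb <- nbr[[cur]]
      if (!is.na(prev)) {
        i <- match(prev, nb)          # drop one occurrence of where we came
        if (!is.na(i)) nb <- nb[-i]   # from (duplicates allowed)
      }
      if (length(nb) == 0)
        stop("open intersection chain (non-watertight mesh) near (",
             paste(signif(pt_of[[cur]], 6), collapse = ", "), ")")
      nxt <- nb[1]
      if (nxt == start) { closed <- TRUE; break }
      if (!is.null(visited[[nxt]])) break   # defensive: avoid infinite walk
      prev <- cur
      cur <- nxt
    }
    if (closed && length(chain) >= 3)
      loops[[length(loops) + 1]] <- do.call(rbind, pt_of[chain])
  }
  if (length(loops) == 0) stop("plane intersection produced no closed loop")
  if (all) return(loops)
  pick_loop(loops, center, normal)
}

pick_loop <- function(loops, center, normal) {
  if (length(loops) == 1) return(loops[[1]])
  basis <- plane_basis(normal)
  contains <- vapply(loops, function(lp) {
    p2 <- sweep(lp, 2, center) %*% basis
    point_in_poly(matrix(0, 1, 2), p2)
  }, TRUE)
  if (any(contains)) {
    inloops <- loops[contains]
    # smallest containing loop = the lumen wall, not an enclosing structure
    areas <- vapply(inloops, polygon_area, 0.0)
    return(inloops[[which.min(areas)]])
  }
  cdist <- vapply(loops, function(lp)
    sum((colMeans(lp) - center)^2), 0.0)
  loops[[which.min(cdist)]]
}

plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  cbind(e1, e2)
}

# crossing-number point-in-polygon, vectorized over query points
point_in_poly <- function(pts, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- poly[c(2:n, 1), 1]; ye <- poly[c(2:n, 1), 2]
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(n)) {
    cross <- ((ys[k] > pts[, 2]) != (ye[k] > pts[, 2])) &
      (pts[, 1] < xs[k] + (pts[, 2] - ys[k]) * (xe[k] - xs[k]) /
         (ye[k] - ys[k]))
    inside <- xor(inside, cross)
  }
  inside
}

#' Area of a planar 3D polygon (shoelace, shape-free)
#'
#' Half the norm of the summed cross products about the centroid — the
#' direct polygon area with no circularity assumption, exact for planar
#' loops, orientation-independent, and invariant under rigid motion.
#'
#' @param loop k x 3 matrix of ordered vertices (closed implicitly).
#' @return area, mm^2.
#' @export
polygon_area <- function(loop) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  k <- nrow(loop)
  if (k < 3) stop("polygon needs at least 3 vertices")
  c0 <- colMeans(loop)
  a <- sweep(loop, 2, c0)
  b <- a[c(2:k, 1), , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  v <- colSums(cr)
  0.5 * sqrt(sum(v^2))
}

#' Diameter of the largest inscribed circle of a planar polygon
#'
#' The stenosis-robust diameter: the largest circle fitting inside the
#' (possibly non-convex) lumen contour. Solved by rasterizing the polygon
#' interior at 1/20 of the local equivalent radius, taking the grid maximum
#' of distance-to-boundary, then polishing with Nelder-Mead on the
#' distance-to-edges objective.
#'
#' @param loop k x 3 matrix of ordered planar vertices.
#' @return inscribed-circle diameter, mm.
#' @export
inscribed_diameter <- function(loop) {
  loop <- matrix(as.numeric(loop), ncol = 3)
  k <- nrow(loop)
  c0 <- colMeans(loop)
  a <- sweep(loop, 2, c0)
  b <- a[c(2:k, 1), , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- colSums(cr)
  nn <- sqrt(sum(nrm^2))
  if (nn == 0) stop("degenerate polygon")
  basis <- plane_basis(nrm / nn)
  p2 <- a %*% basis
  area <- polygon_area(loop)
  step <- sqrt(area / pi) / 20
  gx <- seq(min(p2[, 1]), max(p2[, 1]), by = step)
  gy <- seq(min(p2[, 2]), max(p2[, 2]), by = step)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- point_in_poly(grid, p2)
  if (!any(inside)) stop("polygon has no interior at this resolution")
  gin <- grid[inside, , drop = FALSE]
  dmin <- dist_to_edges(gin, p2)
  best <- gin[which.max(dmin), ]
  # local refinement: a fine grid around the coarse optimum (the objective
  # is piecewise smooth; nested grids are robust on non-convex contours)
  r_best <- max(dmin)
  for (fine in c(step / 5, step / 25)) {
    off <- seq(-2.5 * fine, 2.5 * fine, length.out = 11)
    g2 <- cbind(rep(best[1] + off, times = 11),
                rep(best[2] + off, each = 11))
    ins2 <- point_in_poly(g2, p2)
    if (!any(ins2)) break
    g2 <- g2[ins2, , drop = FALSE]
    d2 <- dist_to_edges(g2, p2)
    if (max(d2) > r_best) {
      r_best <- max(d2)
      best <- g2[which.max(d2), ]
    }
  }
  2 * r_best
}

# min distance from each 2D point to the polygon boundary
dist_to_edges <- function(pts, poly) {
  n <- nrow(poly)
  xe <- poly[c(2:n, 1), ]
  out <- rep(Inf, nrow(pts))
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- xe[k, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) /
      max(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    out <- pmin(out, sqrt(dx^2 + dy^2))
  }
  out
}

#' Diameter of the circle with the same area
#' @param area area, mm^2 (> 0).
#' @return `2 * sqrt(area / pi)`, mm.
#' @export
equivalent_diameter <- function(area) {
  if (any(area <= 0)) stop("area must be > 0")
  2 * sqrt(area / pi)
}

#' Build a cross-sectional-area profile along a centerline
#'
#' One cutting plane per resampled centerline point, normal to the local
#' tangent, intersected with the lumen mesh. Because the planes follow the
#' tangent, oblique-section overestimation (the 1/cos theta error of
#' fixed-axis slicing) does not occur and the area carries no shape
#' assumption. Deviated planes — a plane whose line of intersection with a
#' neighbouring plane passes within the local lumen radius, or whose area
#' jumps more than `jump_frac` against both neighbours — are repaired by
#' resampling between neighbouring planes: center and normal are replaced by
#' the neighbour interpolation and the station is re-sliced, up to
#' `max_repair` rounds; an unresolvable station is flagged and excluded with
#' a warning.
#'
#' @param m lumen [surface_mesh()].
#' @param cl a `centerline` inside the mesh.
#' @param step plane spacing along arc length, mm.
#' @param jump_frac area-jump fraction marking a deviated plane.
#' @param max_repair repair rounds before a station is dropped.
#' @param inscribed also compute inscribed-circle diameters (slower).
#' @return Object of class `csa_profile`: `sections` data frame (`s`,
#'   `area`, `inscribed`, `equiv`, `flag`), `polygons` list, `centers`,
#'   `normals`.
#' @export
build_profile <- function(m, cl, step = 0.25, jump_frac = 0.3,
                          max_repair = 3, inscribed = TRUE) {
  stopifnot(inherits(m, "surface_mesh"), inherits(cl, "centerline"))
  rc <- resample_centerline(cl, step)
  n <- nrow(rc$points)
  centers <- rc$points
  normals <- rc$tangents
  polys <- vector("list", n)
  areas <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  slice_one <- function(i) {
    lp <- tryCatch(slice_mesh(m, centers[i, ], normals[i, ]),
                   error = function(e) NULL)
    if (is.null(lp)) return(FALSE)
    polys[[i]] <<- lp
    areas[i] <<- polygon_area(lp)
    TRUE
  }
  for (i in seq_len(n)) ok[i] <- slice_one(i)

  deviated <- function() {
    bad <- rep(FALSE, n)
    r_eq <- sqrt(pmax(areas, 0) / pi)
    for (i in seq_len(n)) {
      if (!ok[i]) { bad[i] <- TRUE; next }
      for (j in c(i - 1L, i + 1L)) {
        if (j < 1 || j > n || !ok[j]) next
        d <- plane_line_distance(centers[i, ], normals[i, ],
                                 centers[j, ], normals[j, ])
        if (!is.na(d) && d < r_eq[i]) bad[i] <- TRUE
      }
      lo <- if (i > 1 && ok[i - 1]) areas[i - 1] else NA
      hi <- if (i < n && ok[i + 1]) areas[i + 1] else NA
      if (!is.na(lo) && !is.na(hi)) {
        if (abs(areas[i] - lo) > jump_frac * lo &&
            abs(areas[i] - hi) > jump_frac * hi) bad[i] <- TRUE
      }
    }
    bad
  }
  for (round in seq_len(max_repair)) {
    bad <- deviated()
    if (!any(bad)) break
    for (i in which(bad)) {
      lo <- i - 1L; while (lo >= 1 && (bad[lo] || !ok[lo])) lo <- lo - 1L
      hi <- i + 1L; while (hi <= n && (bad[hi] || !ok[hi])) hi <- hi + 1L
      if (lo >= 1 && hi <= n) {
        w <- (rc$s[i] - rc$s[lo]) / (rc$s[hi] - rc$s[lo])
        centers[i, ] <- (1 - w) * centers[lo, ] + w * centers[hi, ]
        nv <- (1 - w) * normals[lo, ] + w * normals[hi, ]
        normals[i, ] <- nv / sqrt(sum(nv^2))
      } else if (lo >= 1) {
        normals[i, ] <- normals[lo, ]
      } else if (hi <= n) {
        normals[i, ] <- normals[hi, ]
      }
      ok[i] <- slice_one(i)
    }
  }
  bad <- deviated()
  if (any(bad))
    warning(sum(bad), " cross-section(s) flagged as deviated and excluded")
  flag <- ifelse(ok & !bad, "ok", "excluded")
  insc <- rep(NA_real_, n)
  if (inscribed) {
    for (i in which(flag == "ok"))
      insc[i] <- inscribed_diameter(polys[[i]])
  }
  sections <- data.frame(s = rc$s, area = areas, inscribed = insc,
                         equiv = ifelse(is.na(areas) | areas <= 0, NA,
                                        2 * sqrt(pmax(areas, 0) / pi)),
                         flag = flag, stringsAsFactors = FALSE)
  structure(list(sections = sections, polygons = polys,
                 centers = centers, normals = normals),
            class = "csa_profile")
}

# distance from p1 to the intersection line of two planes; NA when parallel
plane_line_distance <- function(p1, n1, p2, n2) {
  d <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  dd <- sum(d^2)
  if (dd < 1e-12) return(NA_real_)
  # point on the line: q = ((c1 n2 - c2 n1) x d) / |d|^2, ci = ni . pi
  c1 <- sum(n1 * p1); c2 <- sum(n2 * p2)
  v <- c1 * n2 - c2 * n1
  q <- c(v[2] * d[3] - v[3] * d[2],
         v[3] * d[1] - v[1] * d[3],
         v[1] * d[2] - v[2] * d[1]) / dd
  w <- p1 - q
  cr <- c(w[2] * d[3] - w[3] * d[2],
          w[3] * d[1] - w[1] * d[3],
          w[1] * d[2] - w[2] * d[1])
  sqrt(sum(cr^2) / dd)
}

#' @exportS3Method base::print
print.csa_profile <- function(x, ...) {
  okr <- x$sections$flag == "ok"
  cat(sprintf("<csa_profile> %d sections (%d ok), s in [%.2f, %.2f] mm\n",
              nrow(x$sections), sum(okr), min(x$sections$s),
              max(x$sections$s)))
  if (any(okr))
    cat(sprintf("  area %.2f-%.2f mm^2\n", min(x$sections$area[okr]),
                max(x$sections$area[okr])))
  invisible(x)
}

#' Write a CSA profile to CSV
#' @param profile a `csa_profile`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- profile$sections
  names(df) <- c("s_mm", "area_mm2", "inscribed_diam_mm", "equiv_diam_mm",
                 "flag")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
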