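#' Specify a synthetic vessel phantom
#'
#' Defines a contrast-filled tubular lumen swept along a parametric
#' centerline, embedded in soft-tissue background, with optional stenosis and
#' calcific insert, Gaussian PSF blur and additive noise. The defaults
#' emulate a typical coronary CT angiography regime: isotropic 0.4 mm
#' voxels, 450 HU contrast-filled lumen over 50 HU soft tissue, calcium at
#' 900 HU, scanner blur of 0.6 mm and 20 HU Gaussian noise.
#'
#' @param centerline list describing the axis curve: `list(model = "line",
#'   length)`, `list(model = "arc", radius, span)` (span in radians, curve in
#'   the x-y plane) or `list(model = "helix", radius, pitch, turns)`.
#' @param profile cross-section: `list(shape = "circle", r)`,
#'   `list(shape = "ellipse", a, b)` (a >= b, mm) or
#'   `list(shape = "crescent", R, r, offset)` — a disk of radius `R` with a
#'   disk of radius `r` centred `offset` mm along the local first frame axis
#'   carved out (`offset < R`, and the carved disk must not swallow the
#'   lumen).
#' @param stenosis `NULL`, or `list(depth, center_s, width)`: a Gaussian area
#'   dip, area scale `1 - depth * exp(-(s - center_s)^2 / (2 width^2))` with
#'   `width` the Gaussian sigma in mm.
#' @param calcific `NULL`, or `list(center_s, radius, offset)`: a spherical
#'   high-HU insert centred `offset` mm from the axis at arc length
#'   `center_s`.
#' @param lumen_hu,background_hu,calcific_hu intensities (HU); lumen must
#'   exceed background and calcium must exceed lumen.
#' @param psf_sigma scanner point-spread sigma in mm (0 disables blur).
#' @param noise_sd additive Gaussian noise sigma in HU (0 disables).
#' @param spacing voxel spacing, mm (length 1 or 3).
#' @param shape optional grid dimensions; computed from the geometry plus
#'   `margin_mm` when `NULL`.
#' @param margin_mm clearance between the tube and the grid boundary.
#' @param seed RNG seed making the noise reproducible.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline = list(model = "line", length = 30),
                         profile = list(shape = "circle", r = 2),
                         stenosis = NULL,
                         calcific = NULL,
                         lumen_hu = 450, background_hu = 50,
                         calcific_hu = 900,
                         psf_sigma = 0.6, noise_sd = 20,
                         spacing = 0.4, shape = NULL, margin_mm = 4,
                         seed = 42L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0))
  if (!(lumen_hu > background_hu))
    stop("lumen HU must exceed background HU")
  if (!(calcific_hu > lumen_hu))
    stop("calcific HU must exceed lumen HU")
  centerline$model <- match.arg(centerline$model, c("line", "arc", "helix"))
  profile$shape <- match.arg(profile$shape,
                             c("circle", "ellipse", "crescent"))
  geo <- switch(profile$shape,
    circle = profile$r,
    ellipse = c(profile$a, profile$b),
    crescent = c(profile$R, profile$r, profile$offset))
  if (any(!is.finite(geo)) || any(geo <= 0))
    stop("profile parameters must be positive")
  if (profile$shape == "ellipse" && profile$b > profile$a)
    stop("ellipse requires a >= b")
  if (profile$shape == "crescent") {
    if (profile$offset >= profile$R)
      stop("crescent offset must be smaller than R (nonempty lumen)")
    if (profile$offset + profile$R <= profile$r)
      stop("crescent carve disk swallows the lumen (empty cross-section)")
  }
  if (!is.null(stenosis)) {
    stopifnot(stenosis$depth > 0, stenosis$depth < 1, stenosis$width > 0)
  }
  structure(list(centerline = centerline, profile = profile,
                 stenosis = stenosis, calcific = calcific,
                 lumen_hu = lumen_hu, background_hu = background_hu,
                 calcific_hu = calcific_hu, psf_sigma = psf_sigma,
                 noise_sd = noise_sd, spacing = spacing, shape = shape,
                 margin_mm = margin_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# --- centerline curve models ------------------------------------------------
# Each model supplies: point(s), tangent(s), frame e1/e2(s), total length,
# and an inverse mapping point -> (s, u, v) in the local cross-section frame.

curve_model <- function(cl) {
  switch(cl$model,
    line = {
      L <- cl$length
      list(
        length = L,
        point = function(s) cbind(0, 0, s),
        tangent = function(s) cbind(0 * s, 0 * s, 1 + 0 * s),
        e1 = function(s) cbind(1 + 0 * s, 0 * s, 0 * s),
        e2 = function(s) cbind(0 * s, 1 + 0 * s, 0 * s),
        suv = function(x, y, z) list(s = z, u = x, v = y))
    },
    arc = {
      R <- cl$radius; span <- cl$span
      L <- R * span
      list(
        length = L,
        point = function(s) cbind(R * cos(s / R), R * sin(s / R), 0),
        tangent = function(s) cbind(-sin(s / R), cos(s / R), 0 * s),
        e1 = function(s) cbind(cos(s / R), sin(s / R), 0 * s),
        e2 = function(s) cbind(0 * s, 0 * s, -1 + 0 * s),
        suv = function(x, y, z) {
          th <- atan2(y, x)
          th[th < 0] <- th[th < 0] + 2 * pi
          list(s = R * th, u = sqrt(x^2 + y^2) - R, v = -z)
        })
    },
    helix = {
      R <- cl$radius; pitch <- cl$pitch; turns <- cl$turns
      p <- pitch / (2 * pi)
      rate <- sqrt(R^2 + p^2)       # ds/dtheta
      thmax <- 2 * pi * turns
      L <- rate * thmax
      pt <- function(th) cbind(R * cos(th), R * sin(th), p * th)
      list(
        length = L,
        point = function(s) pt(s / rate),
        tangent = function(s) {
          th <- s / rate
          cbind(-R * sin(th), R * cos(th), p + 0 * th) / rate
        },
        e1 = function(s) {
          th <- s / rate
          cbind(cos(th), sin(th), 0 * th)
        },
        e2 = function(s) {
          th <- s / rate
          cbind(-p * sin(th), p * cos(th), -R + 0 * th) / rate
        },
        suv = function(x, y, z) {
          th <- z / p                       # initial guess from the climb
          for (i in 1:12) {                 # Newton on (q - h)' . h' = 0
            ct <- cos(th); st <- sin(th)
            f <- R * (x * st - y * ct) + p * (p * th - z)
            fp <- R * (x * ct + y * st) + p^2
            step <- f / pmax(fp, 1e-9)
            step <- pmax(pmin(step, pi / 2), -pi / 2)
            th <- th - step
          }
          ct <- cos(th); st <- sin(th)
          dx <- x - R * ct; dy <- y - R * st; dz <- z - p * th
          list(s = rate * th,
               u = dx * ct + dy * st,
               v = (-p * st * dx + p * ct * dy - R * dz) / rate)
        })
    })
}

stenosis_scale <- function(spec, s) {
  if (is.null(spec$stenosis)) return(rep(1, length(s)))
  st <- spec$stenosis
  1 - st$depth * exp(-(s - st$center_s)^2 / (2 * st$width^2))
}

profile_nominal_area <- function(profile) {
  switch(profile$shape,
    circle = pi * profile$r^2,
    ellipse = pi * profile$a * profile$b,
    crescent = pi * profile$R^2 -
      circle_overlap_area(profile$R, profile$r, profile$offset))
}

profile_nominal_inscribed <- function(profile) {
  switch(profile$shape,
    circle = 2 * profile$r,
    ellipse = 2 * profile$b,
    crescent = {
      R <- profile$R; r <- profile$r; d <- profile$offset
      if (d >= R + r) 2 * R else R + d - r
    })
}

#' Area of the intersection of two disks (the circular "lens")
#'
#' Disks of radius `R` and `r` whose centres are `d` apart.
#' @param R,r disk radii.
#' @param d centre distance.
#' @return overlap area.
#' @export
circle_overlap_area <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R)) +
    r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r)) -
    0.5 * sqrt((-d + r + R) * (d + r - R) * (d - r + R) * (d + r + R))
}

# radial half-width bound of the profile (for grid sizing)
profile_extent <- function(profile) {
  switch(profile$shape,
    circle = profile$r,
    ellipse = profile$a,
    crescent = profile$R)
}

# point membership in the cross-section at scale `sc` (per-point vector)
profile_inside <- function(profile, u, v, sc) {
  switch(profile$shape,
    circle = u^2 + v^2 <= (profile$r * sc)^2,
    ellipse = (u / (profile$a * sc))^2 + (v / (profile$b * sc))^2 <= 1,
    crescent = {
      inside_R <- u^2 + v^2 <= (profile$R * sc)^2
      inside_r <- (u - profile$offset * sc)^2 + v^2 <= (profile$r * sc)^2
      inside_R & !inside_r
    })
}

#' Generate a synthetic CT vessel phantom with analytic ground truth
#'
#' The lumen indicator is rendered with 3 x 3 x 3 sub-voxel supersampling
#' (partial-volume edges), convolved with the Gaussian PSF and corrupted by
#' additive Gaussian noise under the spec seed. The returned ground truth is
#' analytic and noise-free: centerline samples with tangents, and closures
#' for cross-sectional area and inscribed diameter as functions of arc
#' length.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()]) and `truth` (class
#'   `phantom_truth`: fields `length`, `point(s)`, `tangent(s)`, `csa(s)`,
#'   `inscribed(s)`, `samples` data frame, `lumen_fraction` array of
#'   unblurred partial-volume fractions, `nominal_area`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cm <- curve_model(spec$centerline)
  L <- cm$length
  ext <- profile_extent(spec$profile)

  # grid: bounding box of the curve, padded by lumen extent + margin
  ss <- seq(0, L, length.out = 257)
  pts <- cm$point(ss)
  pad <- ext + spec$margin_mm
  if (!is.null(spec$calcific))
    pad <- max(pad, spec$calcific$offset + spec$calcific$radius +
                 spec$margin_mm)
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  tube_lo <- apply(pts, 2, min) - ext
  tube_hi <- apply(pts, 2, max) + ext
  if (is.null(spec$shape)) {
    shape <- pmax(ceiling((hi - lo) / spec$spacing) + 2, 8)
    origin <- lo
  } else {
    shape <- spec$shape
    mid <- (tube_lo + tube_hi) / 2
    origin <- mid - (shape - 1) / 2 * spec$spacing
  }
  # generic sub-voxel grid offset: round geometry (an axis through voxel
  # centres, a radius equal to an integer number of voxels) is a
  # measure-zero alignment that biases every discretized boundary the same
  # way; real acquisitions sit at generic offsets, so the phantom does too
  origin <- origin - spec$spacing * c(0.37, 0.21, 0.44)
  grid_hi <- origin + (shape - 1) * spec$spacing
  need <- 3 * spec$spacing  # >= 3-voxel clearance
  if (any(tube_lo - origin < need) || any(grid_hi - tube_hi < need))
    stop("tube does not fit inside the grid with a 3-voxel margin")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]

  # voxel-centre world coordinates
  xw <- origin[1] + (seq_len(nx) - 1) * spec$spacing[1]
  yw <- origin[2] + (seq_len(ny) - 1) * spec$spacing[2]
  zw <- origin[3] + (seq_len(nz) - 1) * spec$spacing[3]

  sub <- c(-1, 0, 1) / 3
  frac_l <- array(0, dim = shape)
  frac_c <- if (is.null(spec$calcific)) NULL else array(0, dim = shape)
  gx <- rep(xw, times = ny * nz)
  gy <- rep(rep(yw, each = nx), times = nz)
  gz <- rep(zw, each = nx * ny)
  for (ox in sub) for (oy in sub) for (oz in sub) {
    px <- gx + ox * spec$spacing[1]
    py <- gy + oy * spec$spacing[2]
    pz <- gz + oz * spec$spacing[3]
    suv <- cm$suv(px, py, pz)
    ok <- suv$s >= 0 & suv$s <= L
    inside <- rep(FALSE, length(px))
    if (any(ok)) {
      sc <- sqrt(stenosis_scale(spec, suv$s[ok]))
      inside[ok] <- profile_inside(spec$profile, suv$u[ok], suv$v[ok], sc)
    }
    frac_l <- frac_l + inside / 27
    if (!is.null(frac_c)) {
      cal <- spec$calcific
      cc <- cm$point(cal$center_s) + cal$offset * cm$e1(cal$center_s)
      inc <- (px - cc[1])^2 + (py - cc[2])^2 + (pz - cc[3])^2 <=
        cal$radius^2
      frac_c <- frac_c + inc / 27
    }
  }

  hu <- spec$background_hu + (spec$lumen_hu - spec$background_hu) * frac_l
  if (!is.null(frac_c)) {
    # calcium overrides lumen where the insert overlaps it
    hu <- hu + (spec$calcific_hu - spec$background_hu) * frac_c -
      (spec$lumen_hu - spec$background_hu) * pmin(frac_l, frac_c)
  }
  if (spec$psf_sigma > 0)
    hu <- gaussian_blur(hu, spec$psf_sigma, spec$spacing)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(length(hu), sd = spec$noise_sd),
                     dim = shape)
  }
  vol <- ct_volume(hu, spacing = spec$spacing, origin = origin)

  nominal_area <- profile_nominal_area(spec$profile)
  nominal_insc <- profile_nominal_inscribed(spec$profile)
  csa_fun <- function(s) {
    if (any(s < 0 | s > L))
      stop("arc length out of range [0, ", signif(L, 6), "]")
    nominal_area * stenosis_scale(spec, s)
  }
  insc_fun <- function(s) {
    if (any(s < 0 | s > L))
      stop("arc length out of range [0, ", signif(L, 6), "]")
    nominal_insc * sqrt(stenosis_scale(spec, s))
  }
  s_samp <- seq(0, L, by = min(spec$spacing) / 2)
  samples <- data.frame(s = s_samp, cm$point(s_samp), cm$tangent(s_samp))
  names(samples) <- c("s", "x", "y", "z", "tx", "ty", "tz")
  truth <- structure(list(length = L, point = cm$point,
                          tangent = cm$tangent, e1 = cm$e1, e2 = cm$e2,
                          csa = csa_fun, inscribed = insc_fun,
                          samples = samples,
                          lumen_fraction = frac_l,
                          nominal_area = nominal_area,
                          spec = spec, origin = origin),
                     class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Exact cross-sectional area of the phantom at arc length `s`
#'
#' Area of the planar cross-section normal to the true tangent, including
#' the stenosis modulation. Errors when `s` falls outside `[0, length]`.
#'
#' @param truth the `phantom_truth` from [generate_phantom()].
#' @param s arc length(s), mm.
#' @return area(s), mm^2.
#' @export
analytic_csa <- function(truth, s) truth$csa(s)

#' Binary lumen mask of the phantom ground truth
#'
#' Thresholds the unblurred partial-volume lumen fraction; `level = 0.5`
#' marks voxels whose centres are majority-inside the analytic tube.
#'
#' @param truth the `phantom_truth` from [generate_phantom()].
#' @param level fraction threshold in (0, 1].
#' @return A [label_mask()].
#' @export
truth_mask <- function(truth, level = 0.5) {
  m <- array(0L, dim = dim(truth$lumen_fraction))
  m[truth$lumen_fraction >= level] <- 1L
  label_mask(m, spacing = truth$spec$spacing, origin = truth$origin)
}

#' Write phantom ground-truth samples to CSV
#' @param truth the `phantom_truth` from [generate_phantom()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  df <- truth$samples
  df$csa_mm2 <- truth$csa(df$s)
  df$inscribed_mm <- truth$inscribed(df$s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
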