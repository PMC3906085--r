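# Shared fixtures, memoised so expensive phantoms and pipeline runs are
# computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# default study phantom: straight circular tube r = 2 mm, 0.4 mm voxels,
# 0.6 mm PSF blur, 20 HU Gaussian noise, fixed seed
tube_phantom <- function() fixture("tube", function() {
  generate_phantom(phantom_spec())
})

# the same tube without blur or noise
tube_phantom_clean <- function() fixture("tube_clean", function() {
  generate_phantom(phantom_spec(psf_sigma = 0, noise_sd = 0))
})

# full default pipeline on the study tube (heaviest fixture; reused by the
# csa tests and several acceptance checks)
tube_pipeline <- function() fixture("tube_pipeline", function() {
  run_pipeline(pipeline_config(list(input = list(phantom = phantom_spec()))))
})

# stenotic tube: Gaussian area dip, depth 0.5, sigma 3 mm at mid-vessel
stenosis_pipeline <- function() fixture("stenosis_pipeline", function() {
  spec <- phantom_spec(stenosis = list(depth = 0.5, center_s = 15,
                                       width = 3))
  run_pipeline(pipeline_config(list(input = list(phantom = spec),
                                    csa = list(inscribed = FALSE))))
})

# helix phantom (radius 10 mm, pitch 20 mm, one turn), analytic-geometry
# version used for the sub-voxel centerline checks
helix_mask <- function() fixture("helix", function() {
  ph <- generate_phantom(phantom_spec(
    centerline = list(model = "helix", radius = 10, pitch = 20, turns = 1),
    profile = list(shape = "circle", r = 2), psf_sigma = 0, noise_sd = 0))
  list(truth = ph$truth, mask = truth_mask(ph$truth))
})

# RMS distance from points to the sampled analytic centerline
rms_to_curve <- function(pts, samples) {
  sqrt(mean(vapply(seq_len(nrow(pts)), function(i) {
    min((samples$x - pts[i, 1])^2 + (samples$y - pts[i, 2])^2 +
          (samples$z - pts[i, 3])^2)
  }, 0.0)))
}

# polygonal contour of a crescent cross-section (outer disk R, carved disk
# r centred d along +x), traversed outer arc ccw then inner arc back
crescent_polygon <- function(R = 2.2, r = 1.6, d = 1.2, n = 300) {
  x_int <- (d^2 + R^2 - r^2) / (2 * d)
  y_int <- sqrt(R^2 - x_int^2)
  alpha <- atan2(y_int, x_int)
  phi0 <- atan2(y_int, x_int - d)
  th <- seq(alpha, 2 * pi - alpha, length.out = n)
  outer_arc <- cbind(R * cos(th), R * sin(th))
  ph <- seq(2 * pi - phi0, phi0, length.out = n)
  inner_arc <- cbind(d + r * cos(ph), r * sin(ph))
  cbind(rbind(outer_arc, inner_arc[-c(1, n), ]), 0)
}

# binary sphere mask of radius r_vox voxels at unit spacing
sphere_mask <- function(r_vox = 10, pad = 4) {
  n <- 2 * (r_vox + pad) + 1
  ctr <- r_vox + pad + 1 - 0.31          # generic sub-voxel centre
  ax <- seq_len(n)
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr + 0.13)^2, `+`),
              (ax - ctr - 0.21)^2, `+`)
  label_mask(array(as.integer(d2 <= r_vox^2), c(n, n, n)))
}

# solid cylinder mask along z, radius r_vox voxels, unit spacing
cylinder_mask <- function(r_vox = 5, len = 36, pad = 3,
                          cx = 0.37, cy = 0.21) {
  nxy <- 2 * (r_vox + pad) + 1
  nz <- len + 2 * pad
  ctrx <- r_vox + pad + 1 + cx
  ctry <- r_vox + pad + 1 + cy
  ax <- seq_len(nxy)
  d2 <- outer((ax - ctrx)^2, (ax - ctry)^2, `+`)
  slab <- array(as.integer(d2 <= r_vox^2), c(nxy, nxy, 1))
  m <- array(0L, c(nxy, nxy, nz))
  for (z in (pad + 1):(pad + len)) m[, , z] <- slab[, , 1]
  list(mask = label_mask(m), center = c(ctrx, ctry))
}
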