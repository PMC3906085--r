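#' Build and validate a pipeline configuration
#'
#' Stage-parameter blocks with defaults; all parameters are validated
#' against their stage schemas before any computation. A configuration is a
#' plain named list (loadable from YAML via [read_pipeline_config()]), with
#' blocks `input`, `preprocess`, `segment`, `mesh`, `centerline`, `csa`,
#' `validate`, `output`, and a top-level `seed`.
#'
#' @param config named list of (partial) stage blocks; missing values take
#'   the defaults below.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  def <- list(
    input = list(volume = NULL, phantom = NULL),
    preprocess = list(bilateral = TRUE, sigma_spatial = 0.8,
                      sigma_range = 100, wiener = TRUE, psf_sigma = 0.6,
                      nsr = 0.01, selective = FALSE,
                      selective_threshold = 700),
    segment = list(seed_hu = 350, sphere_mm = 2.0, bin_hu = 10,
                   connectivity = 26, refresh_every = Inf,
                   pv_calibrate = TRUE, calibrate_smooth_mm = 0.4,
                   calcific_hu = 700, classify_calcific = FALSE),
    mesh = list(iso = 0.5, smooth_iters = 20, lambda = 0.5, mu = -0.53,
                from_field = TRUE, volume_match = TRUE),
    centerline = list(smooth_window = 5, samples_per_segment = 10,
                      trim_mm = 1.5),
    csa = list(step_mm = 0.25, jump_frac = 0.3, max_repair = 3,
               inscribed = TRUE),
    validate = list(pullback = NULL, offset_mm = 0, trim_mm = 0),
    output = list(dir = NULL),
    seed = 42L,
    verbose = FALSE
  )
  cfg <- utils::modifyList(def, config)
  with(cfg, {
    stopifnot(preprocess$sigma_spatial > 0, preprocess$sigma_range > 0,
              preprocess$nsr >= 0, preprocess$psf_sigma > 0)
    stopifnot(segment$sphere_mm > 0, segment$bin_hu > 0,
              segment$connectivity %in% c(6, 18, 26))
    stopifnot(mesh$smooth_iters >= 0)
    stopifnot(centerline$smooth_window >= 3,
              centerline$smooth_window %% 2 == 1,
              centerline$trim_mm >= 0)
    stopifnot(csa$step_mm > 0, csa$jump_frac > 0, csa$max_repair >= 0)
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Read a phantom spec from a YAML config file
#' @param path YAML file whose keys are [phantom_spec()] arguments.
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

#' Extract a sub-voxel centerline from a lumen mask
#'
#' Thinning, main-path pruning, moving-average smoothing and local Bezier
#' refinement in one call; optionally trims `trim_mm` of arc length from
#' each end (the first/last skeleton voxels sit on the end caps, where
#' cross-sections are not meaningful).
#'
#' @param mask a [label_mask()] of the lumen.
#' @param smooth_window moving-average window (odd).
#' @param samples_per_segment Bezier sampling density.
#' @param endpoints optional endpoints for [extract_main_path()].
#' @param trim_mm arc length cut from each end after refinement.
#' @return list: `centerline` (refined), `raw_path` (world coordinates of
#'   the thinned voxel path), `skeleton`.
#' @export
extract_centerline <- function(mask, smooth_window = 5,
                               samples_per_segment = 10, endpoints = NULL,
                               trim_mm = 0) {
  skel <- thin_skeleton(mask)
  path_vox <- extract_main_path(skel, endpoints)
  path_w <- index_to_world(mask, path_vox - 1)
  win <- min(smooth_window, nrow(path_w) - (nrow(path_w) + 1) %% 2)
  sm <- if (nrow(path_w) >= 3 && win >= 3) smooth_points(path_w, win)
        else path_w
  cl <- bezier_refine(sm, samples_per_segment = samples_per_segment)
  if (trim_mm > 0) cl <- trim_centerline(cl, trim_mm)
  list(centerline = cl, raw_path = path_w, skeleton = skel)
}

trim_centerline <- function(cl, trim_mm) {
  L <- max(cl$s)
  if (2 * trim_mm >= L) stop("trim exceeds centerline length")
  keep <- cl$s >= trim_mm & cl$s <= L - trim_mm
  new_centerline(cl$points[keep, , drop = FALSE])
}

stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full reconstruction pipeline
#'
#' Stage order: input (read a volume or generate a phantom), preprocess,
#' segment, mesh, centerline, CSA profile, validation. With an output
#' directory set, artifacts are written as they are produced (mask and
#' volume as NIfTI, mesh as OBJ, centerline and profile as CSV, report and
#' manifest as JSON; the manifest records a hash of the resolved
#' configuration and the package version). Identical config and seed give
#' byte-identical profile CSVs. With `dry_run = TRUE` the configuration is
#' validated and the resolved stage plan returned without computing.
#'
#' @param config a [pipeline_config()] (or plain list).
#' @param dry_run validate and return the plan only.
#' @return list: `volume`, `mask`, `mesh`, `centerline`, `profile`,
#'   `report`, `artifacts` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (dry_run) {
    plan <- c("input", if (cfg$preprocess$bilateral || cfg$preprocess$wiener)
      "preprocess", "segment", "mesh", "centerline", "csa",
      if (!is.null(cfg$validate$pullback) || !is.null(cfg$input$phantom))
        "validate")
    return(list(plan = plan, config = cfg))
  }
  vb <- isTRUE(cfg$verbose)
  outdir <- cfg$output$dir
  arts <- character(0)
  emit <- function(writer, file) {
    if (is.null(outdir)) return(invisible(NULL))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(outdir, file)
    partial <- file.path(outdir, paste0("partial-", file))
    writer(partial)
    file.rename(partial, p)
    arts[[length(arts) + 1]] <<- p
    invisible(p)
  }

  truth <- NULL
  vol <- stage("input", vb, {
    if (!is.null(cfg$input$phantom)) {
      spec <- if (inherits(cfg$input$phantom, "phantom_spec"))
        cfg$input$phantom else do.call(phantom_spec, cfg$input$phantom)
      spec$seed <- as.integer(cfg$seed)
      ph <- generate_phantom(spec)
      truth <- ph$truth
      ph$volume
    } else if (!is.null(cfg$input$volume)) {
      read_volume(cfg$input$volume)
    } else stop("config must set input$volume or input$phantom")
  })

  restored <- NULL  # linear (mass-conserving) restoration, pre-bilateral
  calib_ref <- NULL # smoothed restored field used for calibration/meshing
  pvol <- stage("preprocess", vb, {
    x <- vol
    if (isTRUE(cfg$preprocess$wiener)) {
      dec <- wiener_deconvolve(x, psf_model(cfg$preprocess$psf_sigma),
                               cfg$preprocess$nsr)
      # full-field restoration by default; selective blending keeps the
      # original away from high-HU (calcific) regions when requested
      x <- if (isTRUE(cfg$preprocess$selective))
        selective_deblur(x, dec, cfg$preprocess$selective_threshold)
      else dec
    }
    restored <- x
    if (isTRUE(cfg$preprocess$bilateral))
      x <- bilateral_filter(x, cfg$preprocess$sigma_spatial,
                            cfg$preprocess$sigma_range)
    x
  })

  mask <- stage("segment", vb, {
    seeds <- detect_seeds(pvol, cfg$segment$seed_hu,
                          cfg$segment$connectivity)
    gp <- grow_params(seed_threshold = cfg$segment$seed_hu,
                      sphere_radius = cfg$segment$sphere_mm,
                      bin_width = cfg$segment$bin_hu,
                      connectivity = cfg$segment$connectivity,
                      refresh_every = cfg$segment$refresh_every)
    mk <- region_grow(pvol, seeds, gp)
    if (isTRUE(cfg$segment$pv_calibrate)) {
      # calibration wants a linear-filtered field: restored, then lightly
      # Gaussian-smoothed so the thresholded set has no noise speckle
      ref <- restored
      if (is.null(ref)) ref <- vol
      ref <- ct_volume(gaussian_blur(ref$data,
                                     cfg$segment$calibrate_smooth_mm,
                                     ref$spacing), ref$spacing, ref$origin)
      calib_ref <- ref
      # lumen level sampled along a provisional centerline: unbiased by
      # boundary noise (deep-mask sampling favours bulges)
      samp <- tryCatch({
        cl0 <- extract_centerline(mk, trim_mm = 1)$centerline
        rc <- resample_centerline(cl0, min(vol$spacing) / 2)
        dmask <- array(FALSE, dim(vol$data))
        idx <- which(mk$data > 0L)
        ai <- arrayInd(idx, dim(vol$data))
        wp <- index_to_world(vol, ai - 1)
        near <- vapply(seq_len(nrow(wp)), function(i)
          min((rc$points[, 1] - wp[i, 1])^2 + (rc$points[, 2] - wp[i, 2])^2 +
                (rc$points[, 3] - wp[i, 3])^2) < 0.25, TRUE)
        dmask[idx[near]] <- TRUE
        if (sum(dmask) < 50) NULL else dmask
      }, error = function(e) NULL)
      # analytic near-axis plateau deficit: even the axis of a thin blurred
      # tube reads low; correct the sampled contrast with the declared PSF
      cscale <- 1
      if (!is.null(samp)) {
        L_hat <- max(1, sum(mk$data > 0L) * voxel_volume(vol))
        len_hat <- tryCatch(max(extract_centerline(mk)$centerline$s) + 2,
                            error = function(e) NA_real_)
        if (is.finite(len_hat) && len_hat > 1) {
          R_hat <- sqrt(L_hat / len_hat / pi)
          sig_eff <- sqrt(cfg$preprocess$psf_sigma^2 +
                            min(vol$spacing)^2 / 12)
          cscale <- 1 / blurred_disk_mean(0.5, R_hat, sig_eff)
        }
      }
      mk <- calibrate_mask_pv(ref, mk, v_mass = vol, lumen_sample = samp,
                              contrast_scale = cscale)
    }
    if (isTRUE(cfg$segment$classify_calcific))
      mk <- classify_calcific(pvol, mk, cfg$segment$calcific_hu)
    mk
  })
  emit(function(p) write_volume(
    ct_volume(array(as.numeric(mask$data), dim(mask$data)), mask$spacing,
              mask$origin), p, format = "nifti"), "mask.nii.gz")

  # calcific plaque is excluded from the lumen surface; CSA is lumen-only
  lumen <- label_mask(array(as.integer(mask$data == 1L), dim(mask$data)),
                      mask$spacing, mask$origin)

  msh <- stage("mesh", vb, {
    thr <- attr(mask, "pv_threshold")
    m <- if (isTRUE(cfg$mesh$from_field) && !is.null(thr) &&
             !is.null(calib_ref)) {
      # calibrated-level-set route: extract the surface from the smooth
      # reference field at the mass-consistent iso instead of re-binarizing;
      # the field is clamped to background outside the mask envelope so no
      # unrelated bright structure enters the surface
      d <- dim(calib_ref$data)
      env <- box_max_filter(array(as.numeric(lumen$data > 0L), dim = d),
                            rep(attr(mask, "pv_envelope_vox"), 3)) > 0
      fld <- calib_ref$data
      fld[!env] <- attr(mask, "pv_background")
      fv <- ct_volume(fld, calib_ref$spacing, calib_ref$origin)
      m0 <- marching_cubes(fv, iso = thr)
      # refine the iso so the enclosed mesh volume matches the mass target
      # exactly (level-set volume and voxel count differ at second order)
      tgt <- attr(mask, "pv_target_voxels") * voxel_volume(fv)
      if (isTRUE(cfg$mesh$volume_match) && !is.null(tgt) &&
          is.finite(tgt)) {
        t0 <- thr; v0 <- mesh_volume(m0)
        t1 <- thr * 0.97 + attr(mask, "pv_background") * 0.03
        for (it in 1:4) {
          m1 <- marching_cubes(fv, iso = t1)
          v1 <- mesh_volume(m1)
          if (abs(v1 - tgt) / tgt < 0.001) { m0 <- m1; break }
          t2 <- t1 + (tgt - v1) * (t1 - t0) / (v1 - v0)
          t0 <- t1; v0 <- v1
          t1 <- t2
          m0 <- m1
        }
      }
      m0
    } else marching_cubes(lumen, cfg$mesh$iso)
    curvature_smooth(m, cfg$mesh$smooth_iters, cfg$mesh$lambda, cfg$mesh$mu)
  })
  emit(function(p) write_mesh(msh, p, format = "obj"), "lumen.obj")

  cl_res <- stage("centerline", vb, extract_centerline(
    lumen, smooth_window = cfg$centerline$smooth_window,
    samples_per_segment = cfg$centerline$samples_per_segment,
    trim_mm = cfg$centerline$trim_mm))
  cl <- cl_res$centerline
  emit(function(p) {
    df <- data.frame(s_mm = cl$s, x = cl$points[, 1], y = cl$points[, 2],
                     z = cl$points[, 3], tx = cl$tangents[, 1],
                     ty = cl$tangents[, 2], tz = cl$tangents[, 3])
    utils::write.csv(df, p, row.names = FALSE)
  }, "centerline.csv")

  profile <- stage("csa", vb, build_profile(
    msh, cl, step = cfg$csa$step_mm, jump_frac = cfg$csa$jump_frac,
    max_repair = cfg$csa$max_repair, inscribed = cfg$csa$inscribed))
  emit(function(p) write_profile_csv(profile, p), "profile.csv")

  report <- list(n_sections = nrow(profile$sections),
                 n_ok = sum(profile$sections$flag == "ok"),
                 lumen_voxels = sum(lumen$data == 1L),
                 calcific_voxels = sum(mask$data == 2L),
                 mesh_vertices = nrow(msh$vertices),
                 mesh_volume_mm3 = mesh_volume(msh))
  if (!is.null(truth)) {
    cmpr <- stage("validate", vb,
                  compare_profile_to_truth(profile, truth))
    report$validation <- cmpr$stats
  } else if (!is.null(cfg$validate$pullback)) {
    frames <- read_pullback(cfg$validate$pullback)
    cmpr <- stage("validate", vb, compare_to_reference(
      profile, frames, offset = cfg$validate$offset_mm,
      trim = cfg$validate$trim_mm))
    report$validation <- cmpr$stats
  }
  emit(function(p) {
    man <- list(config_hash = config_hash(cfg),
                package = as.character(utils::packageVersion("vesselcsa")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = "."))
    jsonlite::write_json(man, p, auto_unbox = TRUE)
  }, "manifest.json")
  emit(function(p) jsonlite::write_json(report, p, auto_unbox = TRUE,
                                        digits = NA), "report.json")

  list(volume = vol, preprocessed = pvol, mask = mask, mesh = msh,
       centerline = cl, raw_path = cl_res$raw_path, profile = profile,
       truth = truth, report = report, artifacts = unlist(arts))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "input")],
                              auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Compare a pipeline CSA profile with phantom ground truth
#'
#' Each profile station's cutting-plane center is projected to the nearest
#' point of the analytic centerline (so no landmark offset is needed) and
#' the analytic CSA there is the reference. Returns aligned pairs and the
#' identity-fit statistics.
#'
#' @param profile a `csa_profile`.
#' @param truth a `phantom_truth`.
#' @return list: `pairs` (`s`, `s_truth`, `ref_area`, `ct_area`,
#'   `pct_error`), `stats` ([identity_fit()] summary).
#' @export
compare_profile_to_truth <- function(profile, truth) {
  sec <- profile$sections
  keep <- sec$flag == "ok" & !is.na(sec$area)
  ctr <- profile$centers[keep, , drop = FALSE]
  samp <- truth$samples
  s_truth <- vapply(seq_len(nrow(ctr)), function(i) {
    d2 <- (samp$x - ctr[i, 1])^2 + (samp$y - ctr[i, 2])^2 +
      (samp$z - ctr[i, 3])^2
    samp$s[which.min(d2)]
  }, 0.0)
  ref <- truth$csa(s_truth)
  pairs <- data.frame(s = sec$s[keep], s_truth = s_truth, ref_area = ref,
                      ct_area = sec$area[keep])
  pairs$pct_error <- percent_error(pairs$ref_area, pairs$ct_area)
  st <- identity_fit(pairs$ref_area, pairs$ct_area)
  st$fit <- NULL
  list(pairs = pairs, stats = st)
}
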