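#' @useDynLib vesselcsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a CT volume
#'
#' A `ct_volume` is the common currency of the pipeline: a 3D scalar grid of
#' intensities in Hounsfield Units (HU; water maps to 0, air to -1000), with
#' strictly positive per-axis voxel spacing in mm and a world-space origin.
#' Voxel indices are 0-based in world-mapping formulas and voxel centres map
#' to world coordinates as `origin + index * spacing` (right-handed axes,
#' array is indexed `[x, y, z]`).
#'
#' @param data 3D numeric array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, mm per voxel along x, y, z; all > 0.
#' @param origin numeric length-3, world mm of voxel (0, 0, 0).
#' @return Object of class `ct_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm, HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Construct a label mask on the grid of a volume
#'
#' Integer labels on the same grid as a parent [ct_volume()]: 0 background,
#' 1 lumen, 2 calcific.
#'
#' @param data 3D integer array of label codes.
#' @param spacing,origin grid geometry, as in [ct_volume()].
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  codes <- c(0L, 1L, 2L)
  if (!all(data %in% codes))
    stop("label codes must be 0 (background), 1 (lumen) or 2 (calcific)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @exportS3Method base::print
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d voxels: %d lumen, %d calcific\n",
              d[1], d[2], d[3], sum(x$data == 1L), sum(x$data == 2L)))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$data)

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
}

#' Map voxel indices to world coordinates
#'
#' Voxel-centre convention: world = origin + index * spacing, with 0-based
#' indices.
#'
#' @param v a [ct_volume()] or [label_mask()].
#' @param index n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
index_to_world <- function(v, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#' @param v a [ct_volume()] or [label_mask()].
#' @param world n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_index <- function(v, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  sweep(sweep(world, 2, v$origin, `-`), 2, v$spacing, `/`)
}

#' Volume of one voxel in mm^3
#' @param v a [ct_volume()] or [label_mask()].
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(v) prod(v$spacing)

#' Read a volumetric image
#'
#' Supported formats: a NIfTI-1 file (`.nii` / `.nii.gz`), a directory
#' holding a single-series DICOM stack, or a raw binary with an explicit
#' sidecar header (see [write_volume()]); the format is inferred from the
#' path unless given. DICOM slices are ordered by their position projected
#' on the slice normal (not by instance number) and the rescale slope and
#' intercept are applied so voxel values are HU. Missing spacing metadata or
#' a non-uniform slice gap is a hard error.
#'
#' @param path file (NIfTI, raw header) or directory (DICOM series).
#' @param format one of `"auto"`, `"nifti"`, `"dicom-series"`, `"raw"`.
#' @param slice_gap_tol relative tolerance on DICOM slice-gap uniformity.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom-series",
                                         "raw"),
                        slice_gap_tol = 0.01) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom-series"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.(raw|bin)$", path)) "raw"
      else stop("cannot infer format of '", path, "'; pass `format`")
  }
  if (format != "dicom-series" && !file.exists(path))
    stop("file not found: ", path)
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      pix <- attr(img, "pixdim")
      if (is.null(pix) || length(pix) < 3 || any(!is.finite(pix[1:3])) ||
          any(pix[1:3] <= 0))
        stop("NIfTI file has missing or invalid voxel spacing")
      hdr <- RNifti::niftiHeader(img)
      origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
      # our writer stores LPS-style offsets negated by the nifti convention;
      # undo the RAS sign flip on x/y so write/read round-trips
      origin[1:2] <- -origin[1:2]
      arr <- array(as.numeric(img), dim = dim(img))
      ct_volume(arr, spacing = as.numeric(pix[1:3]), origin = origin)
    },
    `dicom-series` = read_dicom_series(path, slice_gap_tol = slice_gap_tol),
    raw = read_raw_volume(path)
  )
}

#' Write a volumetric image
#'
#' NIfTI-1 (via RNifti) or raw binary + plain-text sidecar header (`.hdr.json`
#' recording shape, dtype, spacing and origin — the header is required on
#' read, never guessed). Round-trips preserve data, spacing and origin.
#'
#' @param v a [ct_volume()] (a [label_mask()] is accepted and written as
#'   integers).
#' @param path output file; `.nii`/`.nii.gz` or `.raw`.
#' @param format `"auto"`, `"nifti"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "nifti", "raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else if (grepl("\\.(raw|bin)$", path)) "raw"
      else stop("unsupported output format for '", path,
                "'; supported: nifti (.nii/.nii.gz), raw (.raw)")
  }
  if (format == "nifti") {
    img <- RNifti::asNifti(v$data)
    hdr <- list(pixdim = c(-1, v$spacing, 1, 1, 1, 1),
                qoffset_x = -v$origin[1], qoffset_y = -v$origin[2],
                qoffset_z = v$origin[3],
                qform_code = 1L)
    img <- RNifti::`pixdim<-`(img, v$spacing)
    img <- RNifti::asNifti(img, reference = hdr)
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
  } else {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write '", path, "': ",
                                             conditionMessage(e)))
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(v$data), con, size = 8, endian = "little")
    hdr <- list(shape = dim(v$data), dtype = "float64", endian = "little",
                spacing = v$spacing, origin = v$origin)
    jsonlite::write_json(hdr, paste0(path, ".hdr.json"), auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}

read_raw_volume <- function(path) {
  hdr_path <- paste0(path, ".hdr.json")
  if (!file.exists(hdr_path))
    stop("raw volume requires sidecar header '", hdr_path,
         "' (shape, dtype, spacing); refusing to guess")
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  for (f in c("shape", "dtype", "spacing"))
    if (is.null(hdr[[f]])) stop("sidecar header missing field '", f, "'")
  if (!identical(hdr$dtype, "float64"))
    stop("unsupported raw dtype '", hdr$dtype, "' (supported: float64)")
  n <- prod(hdr$shape)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = n, size = 8,
               endian = if (is.null(hdr$endian)) "little" else hdr$endian)
  if (length(x) != n) stop("raw file shorter than header shape implies")
  origin <- if (is.null(hdr$origin)) c(0, 0, 0) else hdr$origin
  ct_volume(array(x, dim = hdr$shape), spacing = hdr$spacing, origin = origin)
}
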