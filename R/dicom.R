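# Minimal DICOM support: enough of the explicit-VR little-endian encoding to
# read an uncompressed single-frame CT series (pixel data, geometry and
# rescale tags) and to write such a series for fixtures. This is not a
# general DICOM implementation: compressed transfer syntaxes, sequences with
# undefined length nesting beyond skipping, and multi-frame objects are out
# of scope.

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

# VRs with the 4-byte length form (2 reserved bytes + uint32 length)
.dcm_long_vr <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  # optional 128-byte preamble + "DICM"
  if (length(raw) > 132L &&
      rawToChar(raw[129:132]) == "DICM") pos <- 133L
  n <- length(raw)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])
  tags <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% .dcm_long_vr) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {  # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    val_at <- pos + hdr
    if (len == -1 || val_at + len - 1L > n + 1L) break
    key <- dcm_tag(group, elem)
    bytes <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = bytes)
    pos <- val_at + len
  }
  tags
}

dcm_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$bytes))
}

dcm_ds <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$bytes, "integer", n = length(t$bytes) / 2, size = 2,
          signed = FALSE, endian = "little")
}

read_dicom_series <- function(dir, slice_gap_tol = 0.01) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, function(f) {
    tags <- read_dicom_file(f)
    rows <- dcm_us(tags, dcm_tag(0x0028, 0x0010))
    cols <- dcm_us(tags, dcm_tag(0x0028, 0x0011))
    if (is.null(rows) || is.null(cols)) return(NULL)  # not an image slice
    ps <- dcm_ds(tags, dcm_tag(0x0028, 0x0030))
    if (is.null(ps) || length(ps) != 2)
      stop("missing PixelSpacing in ", f)
    ipp <- dcm_ds(tags, dcm_tag(0x0020, 0x0032))
    if (is.null(ipp) || length(ipp) != 3)
      stop("missing ImagePositionPatient in ", f)
    iop <- dcm_ds(tags, dcm_tag(0x0020, 0x0037))
    if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
    slope <- dcm_ds(tags, dcm_tag(0x0028, 0x1053)); if (is.null(slope)) slope <- 1
    inter <- dcm_ds(tags, dcm_tag(0x0028, 0x1052)); if (is.null(inter)) inter <- 0
    uid <- dcm_str(tags, dcm_tag(0x0020, 0x000E))
    px <- tags[[dcm_tag(0x7FE0, 0x0010)]]
    if (is.null(px)) stop("missing PixelData in ", f)
    stored <- readBin(px$bytes, "integer", n = length(px$bytes) / 2, size = 2,
                      signed = TRUE, endian = "little")
    if (length(stored) != rows * cols)
      stop("PixelData size mismatch in ", f)
    list(file = f, rows = rows, cols = cols, ps = ps, ipp = ipp, iop = iop,
         hu = stored * slope + inter, uid = uid)
  })
  slices <- Filter(Negate(is.null), slices)
  if (length(slices) == 0) stop("no image slices found in ", dir)
  uids <- unique(vapply(slices, function(s)
    if (is.null(s$uid)) "" else s$uid, ""))
  if (length(uids) > 1)
    stop("directory mixes ", length(uids), " DICOM series; expected one")
  ps0 <- slices[[1]]$ps
  if (!all(vapply(slices, function(s) isTRUE(all.equal(s$ps, ps0)), TRUE)))
    stop("non-uniform in-plane PixelSpacing across slices")
  iop <- slices[[1]]$iop
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), 0.0)
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(proj)
    if (any(gaps <= 0))
      stop("duplicate slice positions in DICOM series")
    gap0 <- stats::median(gaps)
    bad <- which(abs(gaps - gap0) > slice_gap_tol * gap0)
    if (length(bad) > 0)
      stop(sprintf(
        "non-uniform slice gap between '%s' and '%s' (%.4f vs median %.4f mm)",
        basename(slices[[bad[1]]]$file), basename(slices[[bad[1] + 1]]$file),
        gaps[bad[1]], gap0))
    sz <- gap0
  } else sz <- 1.0
  nxp <- slices[[1]]$cols; nyp <- slices[[1]]$rows
  arr <- array(0, dim = c(nxp, nyp, nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]$hu
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  ct_volume(arr, spacing = c(ps0[2], ps0[1], sz), origin = slices[[1]]$ipp)
}

# --- fixture writer (minimal, uncompressed, explicit VR little endian) ------

dcm_elem <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2 == 1)
    bytes <- c(bytes, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  hdr <- c(writeBin(as.integer(c(group, elem)), raw(), size = 2,
                    endian = "little"),
           charToRaw(vr))
  if (vr %in% .dcm_long_vr) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(as.integer(length(bytes)), raw(), size = 4, endian = "little"),
      bytes)
  } else {
    c(hdr, writeBin(as.integer(length(bytes)), raw(), size = 2,
                    endian = "little"), bytes)
  }
}

dcm_elem_str <- function(group, elem, vr, s)
  dcm_elem(group, elem, vr, charToRaw(s))

dcm_elem_us <- function(group, elem, x)
  dcm_elem(group, elem, "US", writeBin(as.integer(x), raw(), size = 2,
                                       endian = "little"))

write_dicom_series <- function(v, dir, rescale_intercept = -1024,
                               rescale_slope = 1,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$data)
  for (k in seq_len(d[3])) {
    stored <- round((v$data[, , k] - rescale_intercept) / rescale_slope)
    stored <- pmax(pmin(stored, 32767), -32768)
    ipp <- v$origin + c(0, 0, (k - 1) * v$spacing[3])
    body <- c(
      dcm_elem_str(0x0008, 0x0060, "CS", "CT"),
      dcm_elem_str(0x0020, 0x000E, "UI", series_uid),
      dcm_elem_str(0x0020, 0x0013, "IS", as.character(d[3] - k + 1)),
      dcm_elem_str(0x0020, 0x0032, "DS",
                   paste(sprintf("%.6f", ipp), collapse = "\\")),
      dcm_elem_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_elem_us(0x0028, 0x0010, d[2]),        # Rows = ny
      dcm_elem_us(0x0028, 0x0011, d[1]),        # Columns = nx
      dcm_elem_str(0x0028, 0x0030, "DS",
                   sprintf("%.6f\\%.6f", v$spacing[2], v$spacing[1])),
      dcm_elem_us(0x0028, 0x0100, 16),
      dcm_elem_us(0x0028, 0x0103, 1),
      dcm_elem_str(0x0028, 0x1052, "DS", as.character(rescale_intercept)),
      dcm_elem_str(0x0028, 0x1053, "DS", as.character(rescale_slope)),
      dcm_elem(0x7FE0, 0x0010, "OW",
               writeBin(as.integer(stored), raw(), size = 2,
                        endian = "little"))
    )
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), body), con)
    close(con)
  }
  invisible(dir)
}
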