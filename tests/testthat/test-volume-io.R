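test_that("ct_volume enforces grid invariants and maps voxel centres", {
  expect_error(ct_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "positive")
  v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.4, 0.5, 0.6),
                 origin = c(-1, 2, 3))
  w <- index_to_world(v, rbind(c(0, 0, 0), c(2, 1, 3)))
  expect_equal(w[1, ], c(-1, 2, 3))
  expect_equal(w[2, ], c(-1 + 0.8, 2.5, 3 + 1.8))
  expect_equal(world_to_index(v, w), rbind(c(0, 0, 0), c(2, 1, 3)))
  expect_equal(voxel_volume(v), 0.12)
})

test_that("label_mask restricts codes to the declared set", {
  expect_error(label_mask(array(3L, c(2, 2, 2))), "codes")
  m <- label_mask(array(c(0L, 1L, 2L, 0L, 0L, 1L, 2L, 1L), c(2, 2, 2)))
  expect_s3_class(m, "label_mask")
})

test_that("NIfTI write/read round-trips data, spacing and origin", {
  set.seed(11)
  v <- ct_volume(array(stats::rnorm(16^3, 0, 300), c(16, 16, 16)),
                 spacing = c(0.4, 0.4, 0.5), origin = c(-3.2, 1.7, 10))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$spacing, c(0.4, 0.4, 0.5), tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-4)
})

test_that("raw format requires its sidecar header and round-trips", {
  v <- ct_volume(array(as.numeric(seq_len(4096)), c(16, 16, 16)),
                 spacing = c(1, 2, 3), origin = c(4, 5, 6))
  f <- tempfile(fileext = ".raw")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
  unlink(paste0(f, ".hdr.json"))
  expect_error(read_volume(f), "sidecar")
})

test_that("unsupported or unwritable outputs raise clear errors", {
  v <- ct_volume(array(0, c(4, 4, 4)))
  expect_error(write_volume(v, "vol.xyz"), "supported")
  expect_error(suppressWarnings(
    write_volume(v, "/nonexistent-dir-xq/vol.raw")), "cannot write")
})

test_that("DICOM series reads back HU with slices ordered by position", {
  set.seed(5)
  v <- ct_volume(array(round(stats::rnorm(16 * 14 * 10, -200, 300)),
                       c(16, 14, 10)),
                 spacing = c(0.5, 0.6, 0.8), origin = c(1, 2, 3))
  d <- tempfile()
  # fixture writer stores InstanceNumber in reverse: ordering must come from
  # the position tag, not the instance number
  vesselcsa:::write_dicom_series(v, d, rescale_intercept = -1024)
  v2 <- read_volume(d)
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
})

test_that("DICOM air voxels come back near -1000 HU under rescale", {
  v <- ct_volume(array(-1000, c(8, 8, 4)), spacing = c(0.5, 0.5, 1))
  d <- tempfile()
  vesselcsa:::write_dicom_series(v, d, rescale_intercept = -1024)
  v2 <- read_volume(d)
  expect_true(all(abs(v2$data + 1000) < 0.5))
})

test_that("non-uniform DICOM slice gap is an error naming the pair", {
  v <- ct_volume(array(0, c(8, 8, 5)), spacing = c(0.5, 0.5, 1))
  d <- tempfile()
  vesselcsa:::write_dicom_series(v, d)
  # replace slice 4 with one whose position breaks the uniform 1 mm gap
  shifted <- ct_volume(array(0, c(8, 8, 1)), spacing = c(0.5, 0.5, 1),
                       origin = c(0, 0, 3.55))
  fdir <- tempfile()
  vesselcsa:::write_dicom_series(shifted, fdir)
  file.copy(file.path(fdir, "slice0001.dcm"), file.path(d, "slice0004.dcm"),
            overwrite = TRUE)
  expect_error(read_volume(d), "non-uniform slice gap")
})

test_that("mesh writers round-trip geometry; STL preserves area only", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  for (fmt in c("obj", "ply")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_mesh(tet, f)
    m2 <- read_mesh(f)
    expect_equal(nrow(m2$vertices), 4)
    expect_equal(nrow(m2$faces), 4)
    expect_equal(mesh_area(m2), mesh_area(tet), tolerance = 1e-6)
  }
  f <- tempfile(fileext = ".stl")
  write_mesh(tet, f)
  m3 <- read_mesh(f)
  expect_equal(mesh_area(m3), mesh_area(tet), tolerance = 1e-6)
  sph <- marching_cubes(sphere_mask(6))
  f2 <- tempfile(fileext = ".obj")
  write_mesh(sph, f2)
  expect_equal(mesh_area(read_mesh(f2)), mesh_area(sph), tolerance = 1e-6)
  empty <- surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_error(write_mesh(empty, tempfile(fileext = ".obj")), "empty")
})
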