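unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

test_that("plane-mesh intersection produces the expected loop and area", {
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  lp <- slice_mesh(cube, c(0.5, 0.5, 0.5), c(0, 0, 1))
  expect_equal(polygon_area(lp), 1.0, tolerance = 1e-9)
  expect_error(slice_mesh(cube, c(0.5, 0.5, 5), c(0, 0, 1)), "intersect")
})

test_that("oblique cylinder sections follow the 1/cos(theta) law", {
  cyl <- cylinder_mask(10, len = 60, pad = 4)
  mk <- label_mask(cyl$mask$data, spacing = c(0.2, 0.2, 0.2))
  m <- curvature_smooth(marching_cubes(mk), 20)
  ctr <- (c(cyl$center, 34) - 1) * 0.2
  for (ang in c(0, 30)) {
    nrm <- c(sin(ang * pi / 180), 0, cos(ang * pi / 180))
    lp <- slice_mesh(m, ctr, nrm)
    expect_equal(polygon_area(lp), pi * 4 / cos(ang * pi / 180),
                 tolerance = 0.01 * pi * 4 / cos(ang * pi / 180))
  }
})

test_that("a plane missing or grazing the surface errors out", {
  sph <- curvature_smooth(marching_cubes(sphere_mask(6)), 10)
  ctr <- colMeans(sph$vertices)
  expect_error(slice_mesh(sph, ctr + c(0, 0, 50), c(0, 0, 1)), "intersect")
})

test_that("polygon area is exact, isometry-invariant and oracle-checked", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(polygon_area(sq), 1.0)
  th <- 0.7; ph <- 1.2
  R1 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  expect_equal(polygon_area(sq %*% t(R2 %*% R1) +
                              matrix(c(3, -2, 7), 4, 3, TRUE)), 1.0,
               tolerance = 1e-12)
  # random simple 12-gon vs Monte-Carlo point-in-polygon area
  set.seed(42)
  ang <- sort(stats::runif(12, 0, 2 * pi))
  rad <- stats::runif(12, 0.5, 2)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  a_shoelace <- polygon_area(cbind(poly, 0))
  n <- 1e6
  qx <- stats::runif(n, -2, 2); qy <- stats::runif(n, -2, 2)
  frac <- mean(vesselcsa:::point_in_poly(cbind(qx, qy), poly))
  expect_equal(a_shoelace, frac * 16, tolerance = 0.002 * a_shoelace)
})

test_that("inscribed diameters match analytic values and the grid oracle", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  circ <- cbind(2 * cos(th), 2 * sin(th), 0)
  expect_equal(inscribed_diameter(circ), 4.0, tolerance = 0.01)
  ell <- cbind(2.13 * cos(th), 1.99 * sin(th), 0)
  expect_equal(inscribed_diameter(ell), 3.98, tolerance = 0.02)
  cres <- crescent_polygon(2.2, 1.6, 1.2)
  d_impl <- inscribed_diameter(cres)
  # brute-force oracle: dense grid of interior distance-to-boundary values
  gx <- seq(-2.2, 2.2, length.out = 2000)
  gr <- cbind(rep(gx, times = 2000), rep(gx, each = 2000))
  ins <- gr[, 1]^2 + gr[, 2]^2 <= 2.2^2 &
    (gr[, 1] - 1.2)^2 + gr[, 2]^2 > 1.6^2
  gi <- gr[ins, ]
  db <- pmin(2.2 - sqrt(gi[, 1]^2 + gi[, 2]^2),
             abs(sqrt((gi[, 1] - 1.2)^2 + gi[, 2]^2) - 1.6))
  expect_equal(d_impl, 2 * max(db), tolerance = 0.01 * 2 * max(db))
})

test_that("equivalent diameter is the circular-area inverse", {
  expect_equal(equivalent_diameter(12.566), 4.0, tolerance = 1e-3)
  expect_equal(equivalent_diameter(13.2), 4.0995, tolerance = 1e-3)
  expect_equal(equivalent_diameter(pi), 2.0)
  expect_error(equivalent_diameter(0), "> 0")
})

test_that("tube profile recovers the analytic CSA without shape assumptions", {
  res <- tube_pipeline()
  sec <- res$profile$sections
  ok <- sec$flag == "ok"
  expect_gt(sum(ok), 50)
  cmp <- compare_profile_to_truth(res$profile, res$truth)
  expect_lt(max(abs(cmp$pairs$pct_error)), 3)
  expect_lte(cmp$stats$rmse_pct, 10)
  # isoperimetric bound; near-equality is checked on a noise-free lumen
  expect_true(all(sec$inscribed[ok] <= sec$equiv[ok] * 1.01))
})

test_that("inscribed approaches equivalent diameter on circular sections", {
  # exact circle polygon: equality to well within 1%
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  circ <- cbind(2 * cos(th), 2 * sin(th), 0)
  expect_gt(inscribed_diameter(circ) / equivalent_diameter(polygon_area(circ)),
            0.99)
  # voxelized clean tube: the residual lattice scallop of a 5-voxel radius
  # costs a few percent of the inscribed radius even after smoothing
  ph <- tube_phantom_clean()
  mk <- truth_mask(ph$truth)
  m <- curvature_smooth(marching_cubes(mk), 20)
  cl <- extract_centerline(mk, trim_mm = 2)$centerline
  pr <- build_profile(m, cl, step = 2)
  sec <- pr$sections[pr$sections$flag == "ok", ]
  expect_gt(min(sec$inscribed / sec$equiv), 0.93)
})

test_that("stenotic minimum area matches the programmed dip", {
  res <- stenosis_pipeline()
  sec <- res$profile$sections
  a <- sec$area[sec$flag == "ok"]
  s <- sec$s[sec$flag == "ok"]
  nominal <- stats::median(a[abs(s - stats::median(s)) > 6])
  expect_equal(min(a) / nominal, 0.5, tolerance = 0.03 / 0.5)
})

test_that("profiles are invariant under rigid rotation", {
  res <- tube_pipeline()
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  m_rot <- surface_mesh(res$mesh$vertices %*% t(R), res$mesh$faces)
  cl_rot <- vesselcsa:::new_centerline(res$centerline$points %*% t(R))
  pr <- build_profile(m_rot, cl_rot, step = 1, inscribed = FALSE)
  pr0 <- build_profile(res$mesh, res$centerline, step = 1, inscribed = FALSE)
  a1 <- pr$sections$area[pr$sections$flag == "ok"]
  a0 <- pr0$sections$area[pr0$sections$flag == "ok"]
  n <- min(length(a0), length(a1))
  expect_lt(max(abs(a1[1:n] - a0[1:n]) / a0[1:n]), 0.005)
})

test_that("helical tubes keep their planes disjoint inside the lumen", {
  hx <- helix_mask()
  msh <- curvature_smooth(marching_cubes(hx$mask), 20)
  cl <- extract_centerline(hx$mask, trim_mm = 2)$centerline
  pr <- build_profile(msh, cl, step = 0.5, inscribed = FALSE)
  sec <- pr$sections
  ok <- sec$flag == "ok"
  expect_gt(mean(ok), 0.97)
  r_eq <- sqrt(sec$area[ok] / pi)
  idx <- which(ok)
  for (k in seq_len(sum(ok) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    d <- vesselcsa:::plane_line_distance(pr$centers[i, ], pr$normals[i, ],
                                         pr$centers[j, ], pr$normals[j, ])
    if (!is.na(d)) expect_gt(d, r_eq[k])
  }
})
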