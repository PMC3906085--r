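test_that("thinning keeps a single voxel and stays near a cylinder axis", {
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 1L
  sk <- thin_skeleton(label_mask(a))
  expect_equal(sk$voxels, matrix(c(3L, 3L, 3L), 1))

  cyl <- cylinder_mask(5, len = 36)
  sk2 <- thin_skeleton(cyl$mask)
  d <- sqrt((sk2$voxels[, 1] - cyl$center[1])^2 +
              (sk2$voxels[, 2] - cyl$center[2])^2)
  expect_lte(max(d), 1)
  expect_error(thin_skeleton(label_mask(array(0L, c(4, 4, 4)))), "empty")
  two <- array(0L, c(10, 6, 6))
  two[2, 2, 2] <- 1L; two[9, 5, 5] <- 1L
  expect_error(thin_skeleton(label_mask(two)), "components")
})

test_that("a solid torus thins to a single closed cycle", {
  n <- 40
  a <- array(0L, c(n, n, 13))
  for (x in 1:n) for (y in 1:n) for (z in 1:13) {
    rr <- sqrt((x - 20.3)^2 + (y - 20.2)^2)
    if ((rr - 12)^2 + (z - 6.4)^2 <= 9) a[x, y, z] <- 1L
  }
  sk <- thin_skeleton(label_mask(a))
  g <- vesselcsa:::skeleton_graph(sk)
  expect_equal(igraph::components(g)$no, 1)
  expect_true(all(igraph::degree(g) == 2))   # every voxel has 2 neighbours
})

test_that("main-path extraction prunes branches and honors endpoints", {
  a <- array(0L, c(30, 30, 30))
  a[15, 15, 5:25] <- 1L
  for (k in 0:6) a[15 + k, 15 + k, 15] <- 1L
  sk <- thin_skeleton(label_mask(a))
  p <- extract_main_path(sk)
  expect_false(any(p[, 1] > 17))             # arm tip discarded
  pe <- extract_main_path(sk, endpoints = rbind(c(15, 15, 5), c(15, 15, 25)))
  expect_false(any(pe[, 1] > 17))   # arm tip never entered
  expect_error(extract_main_path(sk, endpoints = rbind(c(1, 1, 1),
                                                       c(15, 15, 25))),
               "3 voxels")
  # a path-shaped skeleton comes back in path order
  b <- array(0L, c(5, 5, 20)); b[3, 3, 3:17] <- 1L
  skb <- thin_skeleton(label_mask(b))
  pb <- extract_main_path(skb)
  expect_equal(nrow(pb), 13)   # thinning trims one voxel at each end
  expect_true(all(diff(pb[, 3]) == 1) || all(diff(pb[, 3]) == -1))
})

test_that("Y-shaped skeleton diameter path equals the two longest arms", {
  a <- array(0L, c(40, 40, 8))
  a[5:20, 20, 4] <- 1L                        # west arm, length 16
  a[20, 21:36, 4] <- 1L                       # north arm, length 16
  a[21:26, 20, 4] <- 1L                       # short east arm
  sk <- thin_skeleton(label_mask(a))
  p <- extract_main_path(sk)
  # brute force: the longest geodesic among all leaf pairs spans the two
  # 16-voxel arms and excludes the short east arm
  g <- vesselcsa:::skeleton_graph(sk)
  leaves <- which(igraph::degree(g) == 1)
  dm <- igraph::distances(g, v = leaves, to = leaves)
  best <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  brute <- igraph::shortest_paths(g, leaves[best[1]],
                                  to = leaves[best[2]])$vpath[[1]]
  expect_equal(nrow(p), length(brute))
  expect_false(any(p[, 1] > 20 & p[, 2] == 20))  # short arm excluded
  expect_true(any(p[, 1] == min(sk$voxels[, 1])))  # west tip reached
  expect_true(any(p[, 2] == max(sk$voxels[, 2])))  # north tip reached
})

test_that("moving-average smoothing preserves endpoints and kills zigzag", {
  line <- cbind(seq(0, 10, by = 0.5), seq(0, 20, by = 1), 0)
  sm <- smooth_points(line, 5)
  expect_equal(sm, line, tolerance = 1e-12)
  n <- 41
  zig <- cbind(seq_len(n), rep(c(0.5, -0.5), length.out = n), 0)
  smz <- smooth_points(zig, 5)
  expect_lt(max(abs(smz[3:(n - 2), 2])), 0.3)
  expect_equal(smz[1, ], zig[1, ])
  expect_equal(smz[n, ], zig[n, ])
  expect_error(smooth_points(line, 4), "odd")
  expect_error(smooth_points(line[1:3, ], 5), "length")
  big <- smooth_points(zig, n)
  expect_equal(big[1, ], zig[1, ])
  expect_equal(big[n, ], zig[n, ])
})

test_that("Bezier refinement of collinear controls stays on the line", {
  pts <- cbind(seq(0, 9), 2 * seq(0, 9), -seq(0, 9))
  cl <- bezier_refine(pts)
  d <- cl$points - outer(cl$points[, 1], c(1, 2, -1))
  expect_lt(max(abs(d)), 1e-9)
  expect_error(bezier_refine(pts[1:3, ]), "4")
  dup <- rbind(pts[1, ], pts)
  expect_warning(bezier_refine(dup), "duplicate")
})

test_that("refinement reaches sub-voxel accuracy on a jagged helix", {
  hx <- helix_mask()
  res <- extract_centerline(hx$mask, trim_mm = 2)
  raw_rms <- rms_to_curve(res$raw_path, hx$truth$samples)
  ref_rms <- rms_to_curve(res$centerline$points, hx$truth$samples)
  expect_lt(ref_rms, 0.5 * 0.4)              # <= half the voxel spacing
  expect_lt(raw_rms, 1.0 * 0.4)
  expect_lt(ref_rms, raw_rms)
  # total squared discrete curvature strictly decreases
  curv2 <- function(p) sum(rowSums(diff(diff(p))^2))
  rawr <- resample_centerline(vesselcsa:::new_centerline(res$raw_path), 0.25)
  refr <- resample_centerline(res$centerline, 0.25)
  expect_lt(curv2(refr$points), curv2(rawr$points))
})

test_that("refinement bounds length growth and stays inside the mesh", {
  hx <- helix_mask()
  res <- extract_centerline(hx$mask)
  sm <- smooth_points(index_to_world(hx$mask,
                                     extract_main_path(res$skeleton) - 1), 5)
  len_sm <- sum(sqrt(rowSums(diff(sm)^2)))
  expect_lt(max(res$centerline$s) / len_sm, 1.01)
  msh <- curvature_smooth(marching_cubes(hx$mask), 20)
  inside <- points_in_mesh(res$centerline$points, msh)
  expect_true(all(inside))
})

test_that("resampling is uniform, endpoint-preserving and idempotent", {
  pts <- cbind(seq(0, 10, length.out = 41), 0, 0)
  cl <- vesselcsa:::new_centerline(pts)
  r1 <- resample_centerline(cl, 1)
  expect_equal(nrow(r1$points), 11)
  expect_equal(r1$points[1, ], c(0, 0, 0))
  expect_equal(r1$points[11, ], c(10, 0, 0))
  hx <- helix_mask()
  cl2 <- extract_centerline(hx$mask)$centerline
  a <- resample_centerline(cl2, 0.3)
  b <- resample_centerline(a, 0.3)
  expect_equal(a$points, b$points, tolerance = 1e-3)
  expect_lt(abs(max(a$s) - max(cl2$s)) / max(cl2$s), 0.001)
})
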