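# Geometry plumbing: IO, mesh sampling, curvature, weighted subsampling,
# projections and frame handling.

test_that("PLY round-trips a labelled pair within float tolerance", {
  pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 900,
                                              seed = 2))
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(pair$cloud, path)
  back <- read_model(path)
  expect_equal(back$points, unname(pair$cloud$points), tolerance = 1e-5)
  expect_identical(back$labels, pair$cloud$labels)
})

test_that("two-file STL input yields a two-label cloud", {
  pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 600,
                                              seed = 3))
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl_points(pair$cloud$points[pair$cloud$labels == 1, ], p1)
  write_stl_points(pair$cloud$points[pair$cloud$labels == 2, ], p2)
  cloud <- read_model(c(p1, p2), format = "stl")
  expect_setequal(unique(cloud$labels), 1:2)
  expect_gt(sum(cloud$labels == 1), 0)
})

test_that("empty or malformed mesh files are rejected", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid empty", "endsolid empty"), p)
  expect_error(read_stl_mesh(p), "no facets")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a ply", p2)
  expect_error(read_ply(p2), "not a PLY")
})

test_that("binary and ASCII STL readers agree", {
  mesh <- unit_square_mesh()
  p <- withr::local_tempfile(fileext = ".stl")
  # write a minimal binary STL for the same mesh
  con <- file(p, "wb")
  writeBin(raw(80), con)
  writeBin(2L, con, size = 4, endian = "little")
  for (f in seq_len(2)) {
    writeBin(numeric(3), con, size = 4, endian = "little")
    for (v in mesh$faces[f, ]) {
      writeBin(as.numeric(mesh$vertices[v, ]), con, size = 4,
               endian = "little")
    }
    writeBin(raw(2), con)
  }
  close(con)
  bin <- read_stl_mesh(p)
  expect_equal(nrow(bin$faces), 2)
  expect_equal(sort(unique(round(bin$vertices[, 1], 6))), c(0, 1))
})

test_that("mesh sampling is area-uniform and seeded", {
  mesh <- unit_square_mesh()
  pts <- sample_mesh(mesh, 1e4, seed = 1)
  qx <- pts[, 1] > 0.5
  qy <- pts[, 2] > 0.5
  counts <- table(qx, qy)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
  expect_equal(sample_mesh(mesh, 50, seed = 7), sample_mesh(mesh, 50, seed = 7))
  one <- sample_mesh(mesh, 1, seed = 3)
  expect_equal(dim(one), c(1, 3))
  expect_true(all(one >= 0 & one <= 1))
  expect_error(sample_mesh(list(vertices = NULL, faces = NULL), 5), "empty")
})

test_that("surface variation separates planes from curved surfaces", {
  plane <- cbind(matrix(runif(2000), ncol = 2), 0)
  sphere <- fibonacci_sphere(1000, radius = 2)
  cv_plane <- estimate_curvature(plane, 16)
  cv_sphere <- estimate_curvature(sphere, 16)
  expect_lt(max(cv_plane), 1e-8)
  expect_gt(min(cv_sphere), max(cv_plane))
  expect_true(all(cv_sphere <= 1 / 3 + 1e-12))
})

test_that("curvature is invariant under rigid motion", {
  set.seed(5)
  pts <- fibonacci_sphere(600, radius = 3) + matrix(rnorm(1800, 0, 0.01),
                                                    ncol = 3)
  theta <- 0.71
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  moved <- pts %*% t(rot) + matrix(rep(c(5, -2, 3), each = 600), ncol = 3)
  expect_equal(estimate_curvature(pts, 12), estimate_curvature(moved, 12),
               tolerance = 1e-6)
})

test_that("chamfer and edge regions of a synthetic pair score high curvature", {
  pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 3000,
                                              noise_sd = 0, seed = 4))
  cl <- pair$cloud
  cv <- estimate_curvature(cl, 16)
  spec <- pair$spec
  reach <- proxigap:::chamfer_reach(spec)
  zt <- reach$z_centre + spec$contact_height / 2
  facet_interior <- abs(cl$points[, 1]) < 1e-6 &
    abs(cl$points[, 2]) < 0.3 * spec$contact_width &
    abs(cl$points[, 3] - reach$z_centre) < 0.3 * spec$contact_height
  facet_edge <- abs(cl$points[, 1]) < 0.05 &
    abs(cl$points[, 3] - zt) < 0.05
  expect_gt(mean(cv[facet_edge]), mean(cv[facet_interior]))
})

test_that("geometric sampling follows the curvature weights", {
  # n_out = 1 has closed-form inclusion probabilities w_i / sum(w)
  pts <- cbind(seq_len(200) / 10, 0, 0)
  cl <- labeled_cloud(pts, rep(1:2, each = 100))
  curv <- rep(c(0.3, 0.1), each = 100)
  hits <- numeric(200)
  for (r in 1:1000) {
    s <- geometric_sample(cl, 1, curvature = curv, floor_prob = 0,
                          seed = 5000 + r)
    idx <- which(pts[, 1] %in% s$points[, 1])
    hits[idx] <- hits[idx] + 1
  }
  p_hi <- sum(hits[1:100]) / 1000
  p_expect <- 0.3 * 100 / (0.3 * 100 + 0.1 * 100)
  se <- sqrt(p_expect * (1 - p_expect) / 1000)
  expect_lt(abs(p_hi - p_expect), 3 * se)
})

test_that("zero-weight clusters are never sampled and floors restore them", {
  pts <- rbind(cbind(rnorm(50), rnorm(50), 0), cbind(rnorm(50) + 10, rnorm(50), 0))
  cl <- labeled_cloud(pts, rep(1:2, each = 50))
  curv <- rep(c(1, 0), each = 50)
  s <- geometric_sample(cl, 30, curvature = curv, floor_prob = 0, seed = 1)
  expect_true(all(s$labels == 1))
  expect_error(geometric_sample(cl, 10, curvature = rep(0, 100),
                                floor_prob = 0), "zero")
  # enormous floor approaches uniform sampling: labels near 50/50
  tot <- c(0, 0)
  for (r in 1:200) {
    s2 <- geometric_sample(cl, 50, curvature = curv, floor_prob = 1e6,
                           seed = r)
    tot <- tot + tabulate(s2$labels, 2)
  }
  frac <- tot / sum(tot)
  expect_lt(max(abs(frac - 0.5)), 0.02)
})

test_that("projections drop the stated axis and commute with mirroring", {
  cl <- labeled_cloud(rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9),
                            c(0, 1, 0), c(2, 0, 1), c(5, 5, 5)),
                      rep(1:2, each = 3))
  h <- project(cl, "horizontal_xy")
  v <- project(cl, "vertical_xz")
  expect_equal(unname(h$points[1, ]), c(1, 2))
  expect_equal(unname(v$points[1, ]), c(1, 3))
  pm <- project(mirror_cloud(cl), "horizontal_xy")
  hp <- h$points
  hp[, 2] <- -hp[, 2]
  expect_equal(pm$points, hp)
  # idempotent on data already flat in z
  flat <- labeled_cloud(cbind(h$points, 0), cl$labels)
  expect_equal(project(flat, "horizontal_xy")$points, h$points)
})

test_that("frame normalisation undoes rotation about z and translation", {
  pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 2500,
                                              noise_sd = 0, seed = 6))
  theta <- 2.3
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
  moved <- labeled_cloud(pair$cloud$points %*% t(rot) +
                           matrix(rep(c(4, -7, 2), each = nrow(pair$cloud$points)),
                                  ncol = 3),
                         pair$cloud$labels)
  m0 <- measure_all(pair$cloud)
  m1 <- measure_all(moved)
  expect_equal(unlist(m1), unlist(m0), tolerance = 1e-6)
})
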