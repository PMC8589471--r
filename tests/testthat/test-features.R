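# Interproximal feature measurement.

square_pair <- function(side = 1, contact_span = 4, n = 40) {
  # two axis-aligned blocks sharing the plane x = 0 over y in [0, span]
  g <- expand.grid(x = seq(0, side, length.out = 10),
                   y = seq(0, contact_span, length.out = n),
                   z = seq(0, 1, length.out = 6))
  right <- as.matrix(g)
  left <- right
  left[, 1] <- -left[, 1]
  labeled_cloud(rbind(left, right), rep(1:2, each = nrow(right)))
}

test_that("dividing line spans the shared edge of two touching blocks", {
  cl <- square_pair()
  line <- extract_dividing_line(project(cl, "horizontal_xy"), 0.1)
  expect_gte(nrow(line$boundary_points), 2)
  expect_equal(sort(unname(c(line$end_a[2], line$end_b[2]))), c(0, 4),
               tolerance = 1e-9)
  expect_equal(adjacent_line_length(line), 4, tolerance = 1e-9)
})

test_that("separated teeth raise a no-contact error that names the stage", {
  cl <- square_pair()
  pts <- cl$points
  pts[cl$labels == 2, 1] <- pts[cl$labels == 2, 1] + 10
  apart <- labeled_cloud(pts, cl$labels)
  expect_error(extract_dividing_line(project(apart, "horizontal_xy"), 0.1),
               "no contact")
  expect_error(measure_all(apart, measure_config(normalize = FALSE)),
               "extract_dividing_line")
})

test_that("adjacent line length equals the brute-force diameter", {
  for (s in 1:5) {
    pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 3000,
                                                noise_sd = 0.02,
                                                seed = 900 + s))
    line <- extract_dividing_line(project(normalize_frame(pair$cloud),
                                          "horizontal_xy"))
    expect_equal(adjacent_line_length(line),
                 brute_force_diameter(line$boundary_points),
                 tolerance = 1e-12)
  }
})

test_that("two symmetric wedges open at the constructed dihedral angle", {
  # flanks at +/-30 degrees off each contact end: opening angle 60 degrees
  t_seq <- seq(0.05, 2, by = 0.01)
  wedge <- function(sgn_x, end_y, sgn_dir) {
    cbind(sgn_x * (0.02 + t_seq * sin(pi / 6)),
          end_y + sgn_dir * t_seq * cos(pi / 6))
  }
  contact <- cbind(rep(c(-0.001, 0.001), each = 50),
                   rep(seq(0, 2, length.out = 50), 2))
  pts1 <- rbind(contact[1:50, , drop = FALSE],
                wedge(-1, 2, 1), wedge(-1, 0, -1))
  pts2 <- rbind(contact[51:100, , drop = FALSE],
                wedge(1, 2, 1), wedge(1, 0, -1))
  proj <- structure(list(points = rbind(pts1, pts2),
                         labels = rep(1:2, c(nrow(pts1), nrow(pts2))),
                         plane = "horizontal_xy"),
                    class = "projected_cloud")
  ang <- abduction_gap_angles(proj, extension_len = 1, contact_eps = 0.05,
                              angle_k = 4)
  expect_equal(unname(ang["buccal_angle_deg"]), 60, tolerance = 0.02)
  expect_equal(unname(ang["tongue_angle_deg"]), 60, tolerance = 0.02)
})

test_that("synthetic pairs recover their embrasure angles", {
  spec <- tooth_pair_spec(angle_buccal = 54.15, angle_lingual = 52.24,
                          angle_occlusal = 89.26, noise_sd = 0, seed = 21)
  pair <- generate_tooth_pair(spec)
  m <- measure_all(pair$cloud)
  expect_equal(m$buccal_angle_deg, 54.15, tolerance = 0.001)
  expect_equal(m$tongue_angle_deg, 52.24, tolerance = 0.001)
  expect_equal(m$occlusal_angle_deg, 89.26, tolerance = 0.001)
})

test_that("occlusal angle grows monotonically with the generating angle", {
  res <- vapply(c(60, 90, 120), function(a) {
    pair <- generate_tooth_pair(tooth_pair_spec(angle_occlusal = a,
                                                noise_sd = 0, seed = 31))
    measure_all(pair$cloud)$occlusal_angle_deg
  }, numeric(1))
  expect_true(all(diff(res) > 0))
  expect_equal(res, c(60, 90, 120), tolerance = 0.001)
})

test_that("flat rectangular facets give their exact area", {
  pair <- generate_tooth_pair(tooth_pair_spec(contact_width = 4,
                                              contact_height = 1.5,
                                              noise_sd = 0, seed = 41))
  a <- adjacent_surface_area(normalize_frame(pair$cloud))
  expect_equal(a, 6, tolerance = 0.005)
})

test_that("convex hull area dominates the occupancy area", {
  # concave L-shaped footprint: hull closes the notch, occupancy does not
  g <- expand.grid(u = seq(0, 1, by = 0.02), v = seq(0, 1, by = 0.02))
  keep <- !(g$u > 0.5 & g$v > 0.5)
  uv <- as.matrix(g[keep, ])
  hull_area <- proxigap:::area_2d(uv, method = "hull", sigma = 0)
  occ_area <- proxigap:::area_2d(uv, alpha = 0.2, method = "occupancy")
  expect_gt(hull_area, occ_area)
  expect_equal(occ_area, 0.75, tolerance = 0.08)
  expect_equal(hull_area, 0.875, tolerance = 0.01)
})

test_that("area responds monotonically to facet width and height", {
  base <- function(w, h) {
    pair <- generate_tooth_pair(tooth_pair_spec(contact_width = w,
                                                contact_height = h,
                                                noise_sd = 0, seed = 51))
    measure_all(pair$cloud)$adjacent_surface_area_mm2
  }
  widths <- vapply(c(2.8, 3.4, 4.0), base, numeric(1), h = 1.6)
  heights <- vapply(c(1.3, 1.7, 2.1), function(h) base(3.4, h), numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_true(all(diff(heights) > 0))
})

test_that("zero-noise parameter recovery stays within 2% over a random sweep", {
  n_specs <- 50
  rel_err <- matrix(NA_real_, n_specs, 5)
  for (i in seq_len(n_specs)) {
    pair <- generate_tooth_pair(random_spec(i, noise_sd = 0,
                                            points_per_tooth = 6000))
    m <- measure_all(pair$cloud)
    rel_err[i, ] <- abs(unlist(m) / unlist(pair$truth) - 1)
  }
  med <- apply(rel_err, 2, median)
  expect_true(all(med <= 0.02))
})

test_that("noisy parameter recovery stays within 5% median error", {
  n_specs <- 50
  rel_err <- matrix(NA_real_, n_specs, 5)
  for (i in seq_len(n_specs)) {
    pair <- generate_tooth_pair(random_spec(i, noise_sd = 0.05,
                                            points_per_tooth = 6000))
    m <- measure_all(pair$cloud)
    rel_err[i, ] <- abs(unlist(m) / unlist(pair$truth) - 1)
  }
  med <- apply(rel_err, 2, median)
  expect_true(all(med <= 0.05))
})

test_that("measurements carry their configuration as provenance", {
  pair <- generate_tooth_pair(tooth_pair_spec(points_per_tooth = 2500,
                                              noise_sd = 0, seed = 61))
  cfg <- measure_config(contact_eps = 0.05, extension_len = 1.2)
  m <- measure_all(pair$cloud, cfg)
  expect_identical(attr(m, "config")$contact_eps, 0.05)
  expect_identical(attr(m, "config")$extension_len, 1.2)
  expect_true(attr(m, "diagnostics")$n_boundary > 0)
})
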