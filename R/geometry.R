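# Point-cloud plumbing: mesh-to-cloud sampling, curvature estimation and
# curvature-weighted subsampling.

#' Area-weighted uniform sampling of a triangle mesh surface
#'
#' Triangles are chosen with probability proportional to their area and points
#' placed uniformly by barycentric coordinates, the standard construction for
#' turning a surface mesh into a point cloud.
#'
#' @param mesh a `tri_mesh` (see [read_stl_mesh()]), or any list with
#'   `vertices` and `faces`.
#' @param n number of points to draw (>= 1).
#' @param seed optional integer seed for reproducible draws.
#' @return An `n x 3` matrix of on-surface points.
#' @export
sample_mesh <- function(mesh, n, seed = NULL) {
  if (is.null(mesh$vertices) || is.null(mesh$faces) ||
      nrow(mesh$faces) == 0) {
    stopf("empty mesh")
  }
  n <- as.integer(n)
  if (n < 1) stopf("n must be >= 1")
  v <- as.matrix(mesh$vertices)
  f <- as.matrix(mesh$faces)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(area) <= 0) stopf("mesh has zero total area")
  draw <- function() {
    tri <- sample.int(nrow(f), n, replace = TRUE, prob = area)
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    (1 - r1) * a[tri, , drop = FALSE] +
      r1 * (1 - r2) * b[tri, , drop = FALSE] +
      r1 * r2 * c_[tri, , drop = FALSE]
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Surface-variation curvature score per point
#'
#' For each point, the eigenvalues `l1 >= l2 >= l3` of the covariance of its
#' `k_neighbors` nearest neighbours give the surface variation
#' `l3 / (l1 + l2 + l3)`: 0 on a perfect plane, up to 1/3 for fully isotropic
#' neighbourhoods. High values flag edges, ridges and the contact region --
#' the parts of a tooth that carry impaction-relevant shape.
#'
#' @param cloud a [labeled_cloud()] or bare `N x 3` matrix.
#' @param k_neighbors neighbourhood size (>= 4, default 16).
#' @return Numeric vector of scores in `[0, 1/3]`.
#' @export
estimate_curvature <- function(cloud, k_neighbors = 16) {
  pts <- if (inherits(cloud, "labeled_cloud")) cloud$points else
    as.matrix(cloud)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 4) stopf("k_neighbors must be >= 4")
  if (nrow(pts) <= k_neighbors) {
    stopf("cloud must have more than k_neighbors points")
  }
  .surface_variation(pts, k_neighbors)
}

#' Curvature-weighted geometric subsampling
#'
#' Samples `n_out` points without replacement with probability proportional to
#' `curvature + floor_prob`. The floor keeps flat regions represented; as
#' `floor_prob` grows the draw approaches simple random sampling, and with a
#' zero floor only curved regions survive. Label proportions are preserved up
#' to sampling error because selection acts on points, not teeth.
#'
#' @param cloud a [labeled_cloud()].
#' @param n_out number of points to keep (0 < n_out <= N).
#' @param curvature optional precomputed scores (see [estimate_curvature()]);
#'   computed at `k_neighbors = 16` when missing.
#' @param floor_prob non-negative baseline added to every weight.
#' @param seed optional integer seed.
#' @return A subsampled [labeled_cloud()].
#' @export
geometric_sample <- function(cloud, n_out, curvature = NULL,
                             floor_prob = 0.05, seed = NULL) {
  if (!inherits(cloud, "labeled_cloud")) stopf("expected a labeled_cloud")
  n <- nrow(cloud$points)
  n_out <- as.integer(n_out)
  if (n_out < 1 || n_out > n) stopf("n_out must be in 1..N")
  if (floor_prob < 0) stopf("floor_prob must be non-negative")
  if (is.null(curvature)) curvature <- estimate_curvature(cloud)
  if (length(curvature) != n) stopf("curvature length must match the cloud")
  w <- curvature + floor_prob
  if (all(w <= 0)) stopf("all sampling weights are zero; raise floor_prob")
  pick <- function() sample.int(n, n_out, replace = FALSE, prob = w)
  idx <- if (is.null(seed)) pick() else
    withr::with_seed(as.integer(seed), pick())
  idx <- sort(idx)
  labeled_cloud(cloud$points[idx, , drop = FALSE], cloud$labels[idx],
                normals = if (!is.null(cloud$normals))
                  cloud$normals[idx, , drop = FALSE])
}
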