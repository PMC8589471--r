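# Labelled point clouds and their projections: the containers every other
# module operates on.

#' Labelled 3D point cloud
#'
#' Container for a segmented tooth pair: an `N x 3` coordinate matrix in
#' millimetres with an integer tooth label per point. Pair operations require
#' exactly two distinct labels with at least three points each.
#'
#' @param points numeric `N x 3` matrix (mm), columns x, y, z.
#' @param labels integer vector of length `N`; tooth ids (1 = mesial tooth on
#'   the negative-x side of the canonical frame, 2 = distal tooth).
#' @param normals optional `N x 3` matrix of unit normals.
#' @return An object of class `labeled_cloud`.
#' @export
#' @examples
#' pts <- matrix(rnorm(30), ncol = 3)
#' cl <- labeled_cloud(pts, rep(1:2, each = 5))
#' cl
labeled_cloud <- function(points, labels, normals = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stopf("points must have three columns")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stopf("points must be finite")
  labels <- as.integer(labels)
  if (length(labels) != nrow(points)) {
    stopf("labels must match the number of points")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points))) stopf("normals must be N x 3")
  }
  structure(list(points = points, labels = labels, normals = normals),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<labeled_cloud> %d points, labels: %s\n", nrow(x$points),
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

assert_pair <- function(cloud) {
  if (!inherits(cloud, "labeled_cloud")) stopf("expected a labeled_cloud")
  tab <- table(cloud$labels)
  if (length(tab) != 2) {
    stopf("pair operations need exactly two distinct labels (found %d)",
          length(tab))
  }
  if (any(tab < 3)) stopf("each tooth needs at least 3 points")
  invisible(sort(as.integer(names(tab))))
}

split_pair <- function(cloud) {
  ids <- assert_pair(cloud)
  list(ids = ids,
       a = cloud$points[cloud$labels == ids[1], , drop = FALSE],
       b = cloud$points[cloud$labels == ids[2], , drop = FALSE])
}

#' Project a labelled cloud onto a measurement plane
#'
#' `horizontal_xy` is the occlusal view (drops z) used for the dividing line
#' and the tongue/buccal abduction-gap angles; `vertical_xz` is the mesiodistal
#' vertical view (drops y) used for the occlusal abduction-gap angle. Labels
#' are preserved. Projection assumes the cloud is in the canonical frame (see
#' [normalize_frame()]).
#'
#' @param cloud a [labeled_cloud()].
#' @param plane `"horizontal_xy"` or `"vertical_xz"`.
#' @return An object of class `projected_cloud`: 2D points plus labels.
#' @export
project <- function(cloud, plane = c("horizontal_xy", "vertical_xz")) {
  plane <- match.arg(plane)
  if (!inherits(cloud, "labeled_cloud")) stopf("expected a labeled_cloud")
  keep <- if (plane == "horizontal_xy") c(1L, 2L) else c(1L, 3L)
  structure(list(points = cloud$points[, keep, drop = FALSE],
                 labels = cloud$labels, plane = plane),
            class = "projected_cloud")
}

#' @export
print.projected_cloud <- function(x, ...) {
  cat(sprintf("<projected_cloud> plane=%s, %d points\n", x$plane,
              nrow(x$points)))
  invisible(x)
}

#' Rotate and translate a tooth pair into the canonical frame
#'
#' Centres the cloud on the midpoint of the two tooth centroids, takes the
#' supplied occlusal direction as +z and rotates about it so that the
#' inter-centroid axis (projected into the occlusal plane) becomes +x with the
#' lower-labelled tooth on the negative side. Buccal is +y (right-handed
#' frame). The transform is rigid: no scaling, no reflection.
#'
#' @param cloud a [labeled_cloud()] pair.
#' @param occlusal length-3 occlusal (z) direction of the input data.
#' @return A new `labeled_cloud` in the canonical frame.
#' @export
normalize_frame <- function(cloud, occlusal = c(0, 0, 1)) {
  sp <- split_pair(cloud)
  zhat <- unit2(as.numeric(occlusal))
  ca <- colMeans(sp$a)
  cb <- colMeans(sp$b)
  axis <- cb - ca
  axis <- axis - sum(axis * zhat) * zhat     # project into occlusal plane
  xhat <- unit2(axis)
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])   # y = z x x
  rot <- cbind(xhat, yhat, zhat)
  centre <- (ca + cb) / 2
  pts <- sweep(cloud$points, 2, centre) %*% rot
  colnames(pts) <- c("x", "y", "z")
  labeled_cloud(pts, cloud$labels, normals = if (!is.null(cloud$normals))
    cloud$normals %*% rot)
}

#' Mirror a cloud about the xz-plane
#'
#' Flips the buccolingual axis (y -> -y). On a tooth pair this swaps the
#' buccal and lingual embrasures while leaving the adjacent line, facet area
#' and occlusal embrasure untouched; used heavily in the symmetry tests.
#'
#' @param cloud a [labeled_cloud()].
#' @return The mirrored `labeled_cloud`.
#' @export
mirror_cloud <- function(cloud) {
  pts <- cloud$points
  pts[, 2] <- -pts[, 2]
  nrm <- cloud$normals
  if (!is.null(nrm)) nrm[, 2] <- -nrm[, 2]
  labeled_cloud(pts, cloud$labels, normals = nrm)
}
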