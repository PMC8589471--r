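# Interproximal feature measurement: dividing line, adjacent line length,
# tongue/buccal/occlusal abduction-gap angles, adjacent surface area.
#
# All operations are deterministic. Where measurement noise inflates an
# extreme-based quantity (the farthest boundary points, the convex hull), the
# estimated noise level drives an extreme-value correction that vanishes for
# noise-free input; see the methods vignette for the model.

#' Measurement configuration
#'
#' @param contact_eps contact tolerance (mm): two points on opposite teeth
#'   closer than this are treated as in contact. The default, 0.06 mm, mirrors
#'   the 60 micrometre feeler-gauge bound that defines a clinically tight
#'   contact.
#' @param extension_len secant extension used by the angle construction (mm).
#' @param alpha cell scale (mm) of the occupancy-grid area estimator used for
#'   concave facets; the grid cells are `alpha / 2` on a side.
#' @param angle_k number of nearest flank points averaged into each angle arm
#'   anchor (robustness against jitter; 1 reproduces the bare nearest point).
#' @param normalize apply [normalize_frame()] before measuring.
#' @param occlusal occlusal direction handed to [normalize_frame()].
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(contact_eps = 0.06, extension_len = 1.0,
                           alpha = 0.5, angle_k = 6, normalize = TRUE,
                           occlusal = c(0, 0, 1)) {
  if (contact_eps <= 0) stopf("contact_eps must be positive")
  if (extension_len <= 0) stopf("extension_len must be positive")
  if (alpha <= 0) stopf("alpha must be positive")
  structure(list(contact_eps = contact_eps, extension_len = extension_len,
                 alpha = alpha, angle_k = as.integer(angle_k),
                 normalize = isTRUE(normalize), occlusal = occlusal),
            class = "measure_config")
}

# Cross-tooth contact pairs for a 2D projection or 3D cloud. Returns selected
# points, their partners and pair distances, restricted to a strip around the
# inter-tooth gap to keep the nearest-neighbour search small.
contact_pairs <- function(a, b, eps) {
  x_mid <- (quantile(a[, 1], 0.999, names = FALSE) +
              quantile(b[, 1], 0.001, names = FALSE)) / 2
  half <- max(1.0, 5 * eps)
  sa <- a[abs(a[, 1] - x_mid) <= half, , drop = FALSE]
  sb <- b[abs(b[, 1] - x_mid) <= half, , drop = FALSE]
  if (nrow(sa) == 0 || nrow(sb) == 0) return(NULL)
  nn_ab <- .cross_nn(sa, sb)
  nn_ba <- .cross_nn(sb, sa)
  ka <- nn_ab$dist <= eps
  kb <- nn_ba$dist <= eps
  if (!any(ka) && !any(kb)) return(NULL)
  list(p = rbind(sa[ka, , drop = FALSE], sb[kb, , drop = FALSE]),
       q = rbind(sb[nn_ab$index[ka], , drop = FALSE],
                 sa[nn_ba$index[kb], , drop = FALSE]),
       dist = c(nn_ab$dist[ka], nn_ba$dist[kb]))
}

#' Extract the dividing line between two projected teeth
#'
#' The dividing line is the contact boundary seen in the occlusal
#' (horizontal) projection: points of either tooth whose nearest neighbour on
#' the other tooth lies within `contact_eps`, collapsed to the midpoints of
#' those cross-tooth pairs, ordered along the principal direction of the
#' boundary set. Its two farthest points are the ends of the adjacent line.
#'
#' With noisy input the observed extremes overshoot the true boundary ends;
#' when `trim = TRUE` (default) the boundary is trimmed by the expected
#' overshoot of a Gaussian-jittered boundary (estimated from the perpendicular
#' scatter of the midpoints), which leaves noise-free input untouched.
#'
#' @param proj a `horizontal_xy` (or `vertical_xz`) [project()]ion of a pair.
#' @param contact_eps contact tolerance in mm.
#' @param trim debias the boundary extent under noise.
#' @return An object of class `dividing_line`: `boundary_points` (ordered
#'   M x 2), `end_a`, `end_b`, `direction`, plus diagnostics.
#' @export
extract_dividing_line <- function(proj, contact_eps = 0.06, trim = TRUE) {
  if (!inherits(proj, "projected_cloud")) stopf("expected a projected_cloud")
  labs <- sort(unique(proj$labels))
  if (length(labs) != 2) stopf("projection must contain exactly two teeth")
  a <- proj$points[proj$labels == labs[1], , drop = FALSE]
  b <- proj$points[proj$labels == labs[2], , drop = FALSE]
  if (median(a[, 1]) > median(b[, 1])) { tmp <- a; a <- b; b <- tmp }
  cp <- contact_pairs(a, b, contact_eps)
  if (is.null(cp) || nrow(cp$p) < 2) {
    stopf("no contact detected within %.3f mm", contact_eps)
  }
  mid <- (cp$p + cp$q) / 2
  ctr <- colMeans(mid)
  cv <- cov(mid)
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  perp <- ev$vectors[, 2]
  t_val <- drop(sweep(mid, 2, ctr) %*% axis)
  r_val <- drop(sweep(mid, 2, ctr) %*% perp)
  sigma <- mad(r_val, center = 0)
  if (isTRUE(trim) && sigma > 1e-9) {
    lambda <- length(t_val) / max(diff(range(t_val)), 1e-9)
    e <- gaussian_max_excess(sigma, lambda)
    keep <- t_val >= min(t_val) + e & t_val <= max(t_val) - e
    if (sum(keep) >= 2) {
      mid <- mid[keep, , drop = FALSE]
      t_val <- t_val[keep]
    }
  }
  ord <- order(t_val, mid[, 1], mid[, 2])
  mid <- mid[ord, , drop = FALSE]
  ends <- farthest_pair(mid)
  structure(list(boundary_points = mid,
                 end_a = ends$a, end_b = ends$b,
                 direction = unit2(ends$b - ends$a),
                 sigma = sigma, n_pairs = nrow(cp$p),
                 contact_eps = contact_eps, plane = proj$plane),
            class = "dividing_line")
}

#' @export
print.dividing_line <- function(x, ...) {
  cat(sprintf(
    "<dividing_line> %d boundary points, span %.3f mm, plane %s\n",
    nrow(x$boundary_points), sqrt(sum((x$end_b - x$end_a)^2)), x$plane))
  invisible(x)
}

# Farthest pair of a 2D point set (diameter). Hull-reduced when possible;
# ties resolved by the deterministic ordering of the candidates.
farthest_pair <- function(pts) {
  idx <- seq_len(nrow(pts))
  if (nrow(pts) > 3) {
    h <- tryCatch(chull(pts[, 1], pts[, 2]), error = function(e) idx)
    # chull degenerates on (near-)collinear input, so always keep the
    # coordinate extremes as diameter candidates
    ext <- c(which.min(pts[, 1]), which.max(pts[, 1]),
             which.min(pts[, 2]), which.max(pts[, 2]))
    if (length(h) >= 2) idx <- sort(unique(c(h, ext)))
  }
  cand <- pts[idx, , drop = FALSE]
  d <- as.matrix(dist(cand))
  best <- arrayInd(which.max(d), dim(d))
  i <- cand[best[1], ]
  j <- cand[best[2], ]
  # end_a = lexicographically smaller end, for determinism
  if (i[1] > j[1] || (i[1] == j[1] && i[2] > j[2])) { tmp <- i; i <- j; j <- tmp }
  list(a = i, b = j, diameter = d[best])
}

#' Adjacent line length
#'
#' Euclidean distance between the two farthest points of the dividing line,
#' i.e. the buccolingual span of the contact boundary in occlusal view.
#'
#' @param line a [extract_dividing_line()] result.
#' @return Length in mm.
#' @export
adjacent_line_length <- function(line) {
  if (!inherits(line, "dividing_line")) stopf("expected a dividing_line")
  sqrt(sum((line$end_b - line$end_a)^2))
}

# Shared three-point opening-angle construction: vertex at a dividing-line
# end, probe point e extended outward, one arm per tooth anchored near the
# flank point closest to e. The initial anchor (centroid of the k nearest
# points to e) is biased towards e under jitter, because selection by
# distance favours points whose noise points at e; the anchor direction is
# therefore refined by a corridor fit around the current arm, whose
# perpendicular selection is symmetric and hence unbiased. With noise-free
# input the corridor contains exactly the flank points on the arm and the
# construction reduces to the bare three-point angle.
opening_angle <- function(pts_by_tooth, vertex, outward, extension_len, k,
                          sigma = 0) {
  e <- vertex + extension_len * outward
  # corridor width: wide enough to keep most jittered flank points, capped so
  # that sampling structure in the tooth interior stays outside
  half <- min(max(3 * sigma, 0.02), 0.08)
  arm_dir <- function(p) {
    rel <- sweep(p, 2, vertex)
    beyond <- drop(rel %*% outward) > 0
    if (!any(beyond)) stopf("open embrasure undefined: no flank points")
    d2 <- (p[, 1] - e[1])^2 + (p[, 2] - e[2])^2
    take <- order(d2)[seq_len(min(k, length(d2)))]
    u <- unit2(colMeans(p[take, , drop = FALSE]) - vertex)
    sel <- NULL
    for (it in 1:4) {
      t_al <- drop(rel %*% u)
      t_pe <- rel[, 1] * (-u[2]) + rel[, 2] * u[1]
      sel <- t_al > 0.2 * extension_len & t_al < 1.5 * extension_len &
        abs(t_pe) <= half
      if (sum(sel) < 5) {
        sel <- NULL
        break
      }
      u_new <- unit2(colMeans(rel[sel, , drop = FALSE]))
      done <- sum(u * u_new) > 1 - 1e-12
      u <- u_new
      if (done) break
    }
    if (!is.null(sel) && sum(sel) >= 5) {
      # final free line fit: the arm slope from an unanchored principal-axis
      # fit is insensitive to jitter in the vertex itself
      pts <- rel[sel, , drop = FALSE]
      u_free <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
      if (sum(u_free * u) < 0) u_free <- -u_free
      u <- unit2(u_free)
    }
    u
  }
  u1 <- arm_dir(pts_by_tooth[[1]])
  u2 <- arm_dir(pts_by_tooth[[2]])
  deg(acos(min(1, max(-1, sum(u1 * u2)))))
}

#' Tongue and buccal abduction-gap angles
#'
#' The secant through the dividing-line ends is extended outward by
#' `extension_len` at each end; the points of each tooth nearest to the
#' extension tip anchor one arm each, and the opening angle at the end (the
#' vertex) is the abduction-gap angle. Under the canonical frame the end with
#' the larger y is the buccal embrasure, the other the tongue (lingual) one.
#'
#' @param proj `horizontal_xy` projection of the pair.
#' @param line optional precomputed [extract_dividing_line()]; recomputed from
#'   `proj` when missing.
#' @param extension_len probe extension in mm.
#' @param contact_eps contact tolerance used if `line` is recomputed.
#' @param angle_k nearest points averaged per arm anchor.
#' @return Named vector `c(tongue_angle_deg, buccal_angle_deg)`.
#' @export
abduction_gap_angles <- function(proj, line = NULL, extension_len = 1.0,
                                 contact_eps = 0.06, angle_k = 6) {
  if (!inherits(proj, "projected_cloud") || proj$plane != "horizontal_xy") {
    stopf("abduction_gap_angles needs a horizontal_xy projection")
  }
  if (is.null(line)) line <- extract_dividing_line(proj, contact_eps)
  labs <- sort(unique(proj$labels))
  by_tooth <- lapply(labs, function(l) {
    proj$points[proj$labels == l, , drop = FALSE]
  })
  ends <- list(line$end_a, line$end_b)
  ys <- vapply(ends, `[`, numeric(1), 2)
  buccal_end <- ends[[which.max(ys)]]
  tongue_end <- ends[[which.min(ys)]]
  ang <- function(v, other) {
    opening_angle(by_tooth, v, unit2(v - other), extension_len, angle_k,
                  sigma = line$sigma * sqrt(2))
  }
  c(tongue_angle_deg = ang(tongue_end, buccal_end),
    buccal_angle_deg = ang(buccal_end, tongue_end))
}

#' Occlusal abduction-gap angle
#'
#' Same three-point construction as [abduction_gap_angles()], applied in the
#' mesiodistal vertical (`vertical_xz`) projection with the occlusal-side
#' (maximal-z) end of the recomputed dividing line as vertex.
#'
#' @inheritParams abduction_gap_angles
#' @param proj `vertical_xz` projection of the pair.
#' @return Angle in degrees.
#' @export
occlusal_abduction_angle <- function(proj, extension_len = 1.0,
                                     contact_eps = 0.06, angle_k = 6) {
  if (!inherits(proj, "projected_cloud") || proj$plane != "vertical_xz") {
    stopf("occlusal_abduction_angle needs a vertical_xz projection")
  }
  line <- extract_dividing_line(proj, contact_eps)
  labs <- sort(unique(proj$labels))
  by_tooth <- lapply(labs, function(l) {
    proj$points[proj$labels == l, , drop = FALSE]
  })
  ends <- list(line$end_a, line$end_b)
  zs <- vapply(ends, `[`, numeric(1), 2)
  vertex <- ends[[which.max(zs)]]
  other <- ends[[which.min(zs)]]
  unname(opening_angle(by_tooth, vertex, unit2(vertex - other),
                       extension_len, angle_k,
                       sigma = line$sigma * sqrt(2)))
}

#' Adjacent surface area
#'
#' Collects the 3D points of either tooth whose nearest cross-tooth neighbour
#' lies within `contact_eps`, fits the vertical partition plane (containing
#' the occlusal axis, least squares through the contact points), projects the
#' contact points onto it and measures the footprint area.
#'
#' Two estimators are available: `"hull"` (default) takes the convex hull,
#' with an extreme-value shrinkage matched to the estimated point noise so
#' that jitter does not inflate the area, and is exact for convex facets at
#' zero noise; `"occupancy"` counts bounding-box-fitted grid cells of side
#' `alpha / 2` that contain points, which also handles concave facets. The
#' hull area is an upper bound for the occupancy area on the same points.
#'
#' @param cloud a [labeled_cloud()] pair in the canonical frame.
#' @param contact_eps contact tolerance in mm.
#' @param alpha occupancy cell scale in mm (cells are `alpha / 2` per side).
#' @param method `"hull"` or `"occupancy"`.
#' @return Area in mm^2.
#' @export
adjacent_surface_area <- function(cloud, contact_eps = 0.06, alpha = 0.5,
                                  method = c("hull", "occupancy")) {
  method <- match.arg(method)
  sp <- split_pair(cloud)
  cp <- contact_pairs(sp$a, sp$b, contact_eps)
  if (is.null(cp) || nrow(cp$p) < 3) {
    stopf("no measurable contact facet within %.3f mm", contact_eps)
  }
  ctr <- colMeans(cp$p)
  cv <- cov(cp$p[, 1:2, drop = FALSE])
  n2 <- eigen(cv, symmetric = TRUE)$vectors[, 2]   # small-variance direction
  nrm <- c(n2, 0)                                  # vertical partition plane
  uax <- c(-n2[2], n2[1], 0)                       # in-plane horizontal axis
  rel <- sweep(cp$p, 2, ctr)
  uv <- cbind(rel %*% uax, rel %*% c(0, 0, 1))
  r <- drop(rel %*% nrm)
  r_partner <- drop(sweep(cp$q, 2, ctr) %*% nrm)
  # isotropic noise estimate from the pair common mode r + r_partner, whose
  # variance is 2 sigma^2: the contact-tolerance selection censors mainly the
  # pair *difference*, so the common mode is close to uncensored.
  sigma <- sd(r + r_partner) / sqrt(2)
  area_2d(uv, alpha = alpha, method = method, sigma = sigma)
}

# Area of a 2D point footprint; shared by the hull and occupancy estimators.
area_2d <- function(uv, alpha = 0.5, method = "hull", sigma = 0) {
  if (nrow(uv) < 3) stopf("no measurable contact facet (fewer than 3 points)")
  if (method == "hull") {
    h <- chull(uv[, 1], uv[, 2])
    hull <- uv[h, , drop = FALSE]
    a0 <- polygon_area(hull)
    if (sigma <= 1e-6 || a0 <= 0) return(a0)
    # noisy input: the hull of jittered points overshoots the facet, so
    # switch to a density-normalised count, which is insensitive to jitter:
    # area = n / density, with the point density measured by neighbour
    # counts around interior points and a half-spacing strip subtracted
    # because the outermost samples sit on the facet boundary itself. Both
    # teeth sample the shared facet, hence the factor 2 in the spacing.
    n <- nrow(uv)
    r_nb <- 5 * sqrt(a0 / n)
    q1 <- quantile(uv[, 1], c(0.2, 0.8), names = FALSE)
    q2 <- quantile(uv[, 2], c(0.2, 0.8), names = FALSE)
    interior <- uv[, 1] > q1[1] & uv[, 1] < q1[2] &
      uv[, 2] > q2[1] & uv[, 2] < q2[2]
    ctr <- uv[if (any(interior)) interior else rep(TRUE, n), , drop = FALSE]
    if (nrow(ctr) > 300) {
      ctr <- ctr[round(seq(1, nrow(ctr), length.out = 300)), , drop = FALSE]
    }
    cnt <- vapply(seq_len(nrow(ctr)), function(i) {
      sum((uv[, 1] - ctr[i, 1])^2 + (uv[, 2] - ctr[i, 2])^2 <= r_nb^2) - 1
    }, numeric(1))
    rho <- mean(cnt) / (pi * r_nb^2)
    if (rho <= 0) return(a0)
    per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ,
                                         drop = FALSE])^2)))
    return(max(0, n / rho - per * sqrt(2 / rho) / 2))
  }
  cell <- alpha / 2
  ru <- range(uv[, 1]); rv <- range(uv[, 2])
  nu <- max(1L, round(diff(ru) / cell))
  nv <- max(1L, round(diff(rv) / cell))
  cu <- diff(ru) / nu
  cv_ <- diff(rv) / nv
  iu <- pmin(nu, pmax(1L, ceiling((uv[, 1] - ru[1]) / max(cu, 1e-12))))
  iv <- pmin(nv, pmax(1L, ceiling((uv[, 2] - rv[1]) / max(cv_, 1e-12))))
  length(unique(iu + nu * (iv - 1L))) * cu * cv_
}

#' Measure all five interproximal features of a tooth pair
#'
#' Runs frame normalisation, the occlusal and vertical projections and the
#' five measurements; errors are re-signalled with the failing stage name.
#'
#' @param cloud a [labeled_cloud()] pair.
#' @param config a [measure_config()].
#' @return One-row data frame with columns `adjacent_line_length_mm`,
#'   `adjacent_surface_area_mm2`, `tongue_angle_deg`, `buccal_angle_deg`,
#'   `occlusal_angle_deg`; the configuration and boundary diagnostics are
#'   attached as attributes `config` and `diagnostics`.
#' @export
#' @examples
#' pair <- generate_tooth_pair(tooth_pair_spec(noise_sd = 0, seed = 3))
#' measure_all(pair$cloud)
measure_all <- function(cloud, config = measure_config()) {
  if (!inherits(config, "measure_config")) stopf("expected a measure_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("%s: %s", name, conditionMessage(e))
    })
  }
  if (config$normalize) {
    cloud <- stage("normalize_frame",
                   normalize_frame(cloud, occlusal = config$occlusal))
  }
  hxy <- project(cloud, "horizontal_xy")
  line <- stage("extract_dividing_line",
                extract_dividing_line(hxy, config$contact_eps))
  if (config$normalize) {
    # contact-aligned refinement: the inter-centroid axis is only a coarse
    # mesiodistal estimate, so rotate about z until the dividing line runs
    # exactly buccolingually, which squares the contact plane with x.
    d <- line$direction
    if (d[2] < 0) d <- -d
    psi <- atan2(d[1], d[2])
    if (abs(psi) > 1e-10) {
      pts <- cloud$points
      rot <- cbind(c(cos(psi), sin(psi), 0), c(-sin(psi), cos(psi), 0),
                   c(0, 0, 1))
      cloud <- labeled_cloud(pts %*% t(rot), cloud$labels)
      hxy <- project(cloud, "horizontal_xy")
      line <- stage("extract_dividing_line",
                    extract_dividing_line(hxy, config$contact_eps))
    }
  }
  vxz <- project(cloud, "vertical_xz")
  len <- stage("adjacent_line_length", adjacent_line_length(line))
  ang <- stage("abduction_gap_angles",
               abduction_gap_angles(hxy, line, config$extension_len,
                                    config$contact_eps, config$angle_k))
  occ <- stage("occlusal_abduction_angle",
               occlusal_abduction_angle(vxz, config$extension_len,
                                        config$contact_eps, config$angle_k))
  area <- stage("adjacent_surface_area",
                adjacent_surface_area(cloud, config$contact_eps,
                                      config$alpha))
  out <- data.frame(adjacent_line_length_mm = len,
                    adjacent_surface_area_mm2 = area,
                    tongue_angle_deg = unname(ang["tongue_angle_deg"]),
                    buccal_angle_deg = unname(ang["buccal_angle_deg"]),
                    occlusal_angle_deg = occ)
  attr(out, "config") <- config
  attr(out, "diagnostics") <- list(n_boundary = nrow(line$boundary_points),
                                   boundary_sigma = line$sigma)
  out
}
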