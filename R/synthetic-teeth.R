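# Synthetic molar pairs with analytically known interproximal geometry.
#
# Each tooth is a superellipse prism (curved enough to exercise curvature
# sampling) whose facing face is replaced by an explicit contact construction:
# a flat vertical contact facet of known width (buccolingual) and height
# (occlusocervical), flanked by planar chamfers whose dihedral openings equal
# the requested embrasure angles. The two facets coincide at zero noise, as
# two touching teeth do, which makes every ground-truth value exact by
# construction.

#' Specification of a synthetic molar pair
#'
#' Defaults reproduce a reference low-risk contact morphology: adjacent line
#' length 3.52 mm, facet area 6.21 mm^2, tongue/buccal/occlusal embrasure
#' openings 52.24 / 54.15 / 89.26 degrees.
#'
#' @param crown_width_md mesiodistal crown extent per tooth (mm).
#' @param crown_width_bl buccolingual crown extent (mm).
#' @param crown_height occlusocervical crown extent (mm).
#' @param contact_width buccolingual extent of the flat contact facet (mm);
#'   this is the ground-truth adjacent line length.
#' @param contact_height occlusocervical extent of the facet (mm). Facet area
#'   ground truth is `contact_width * contact_height`.
#' @param angle_buccal,angle_lingual,angle_occlusal total dihedral opening of
#'   the buccal, lingual and occlusal embrasures (degrees, in (0, 180)).
#' @param points_per_tooth approximate number of surface points per tooth.
#' @param noise_sd isotropic Gaussian jitter applied to every coordinate (mm);
#'   0.02 mm is a typical intraoral-scanner noise scale.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `tooth_pair_spec`.
#' @export
#' @examples
#' spec <- tooth_pair_spec(contact_width = 4, angle_buccal = 60,
#'                         angle_lingual = 60, angle_occlusal = 90,
#'                         noise_sd = 0)
#' spec
tooth_pair_spec <- function(crown_width_md = 10,
                            crown_width_bl = 10.5,
                            crown_height = 7.5,
                            contact_width = 3.52,
                            contact_height = 6.21 / 3.52,
                            angle_buccal = 54.15,
                            angle_lingual = 52.24,
                            angle_occlusal = 89.26,
                            points_per_tooth = 8000,
                            noise_sd = 0.02,
                            seed = 1L) {
  spec <- list(crown_width_md = crown_width_md,
               crown_width_bl = crown_width_bl,
               crown_height = crown_height,
               contact_width = contact_width,
               contact_height = contact_height,
               angle_buccal = angle_buccal,
               angle_lingual = angle_lingual,
               angle_occlusal = angle_occlusal,
               points_per_tooth = as.integer(points_per_tooth),
               noise_sd = noise_sd,
               seed = as.integer(seed))
  lens <- c("crown_width_md", "crown_width_bl", "crown_height",
            "contact_width", "contact_height")
  for (nm in lens) {
    if (!is.finite(spec[[nm]]) || spec[[nm]] <= 0) {
      stopf("%s must be a positive length", nm)
    }
  }
  angs <- c("angle_buccal", "angle_lingual", "angle_occlusal")
  for (nm in angs) {
    if (!is.finite(spec[[nm]]) || spec[[nm]] <= 0 || spec[[nm]] >= 180) {
      stopf("%s must lie strictly between 0 and 180 degrees", nm)
    }
  }
  if (spec$contact_width >= spec$crown_width_bl) {
    stopf("contact_width must be smaller than crown_width_bl")
  }
  if (spec$contact_height >= spec$crown_height) {
    stopf("contact_height must be smaller than crown_height")
  }
  if (spec$points_per_tooth < 500) stopf("points_per_tooth must be >= 500")
  if (spec$noise_sd < 0) stopf("noise_sd must be non-negative")
  # embrasure chamfers must fit inside the crown
  reach <- chamfer_reach(spec)
  if (spec$contact_width / 2 + reach$y > 0.95 * spec$crown_width_bl / 2) {
    stopf("chamfers would exceed the buccolingual crown extent")
  }
  zb <- reach$z_centre - spec$contact_height / 2
  if (zb - reach$z < 0.15) {
    stopf("chamfers would exceed the occlusocervical crown extent")
  }
  class(spec) <- "tooth_pair_spec"
  spec
}

#' @export
print.tooth_pair_spec <- function(x, ...) {
  cat(sprintf(paste0("<tooth_pair_spec> contact %.2f x %.2f mm, angles ",
                     "t/b/o = %.2f/%.2f/%.2f deg, n=%d, noise %.3f mm\n"),
              x$contact_width, x$contact_height, x$angle_lingual,
              x$angle_buccal, x$angle_occlusal, x$points_per_tooth,
              x$noise_sd))
  invisible(x)
}

# Chamfer footprint: how far the embrasure chamfers extend from the facet
# edges, and where the facet sits vertically. Reach is capped so the probe
# geometry used by the angle measurement (about 1 mm) is always covered.
chamfer_reach <- function(spec) {
  ry <- min(1.6, 0.9 * (spec$crown_width_bl - spec$contact_width) / 2)
  rz <- 1.6
  zc <- spec$crown_height - spec$contact_height / 2 - rz - 0.3
  list(y = ry, z = rz, z_centre = zc)
}

# Face retreat profiles (capped linear chamfers). `y`/`z` vectorised.
face_fy <- function(y, spec, reach) {
  w2 <- spec$contact_width / 2
  tb <- tan(rad(spec$angle_buccal / 2))
  tl <- tan(rad(spec$angle_lingual / 2))
  db <- pmin(pmax(y - w2, 0), reach$y)
  dl <- pmin(pmax(-y - w2, 0), reach$y)
  db * tb + dl * tl
}

face_fz <- function(z, spec, reach) {
  h2 <- spec$contact_height / 2
  zt <- reach$z_centre + h2
  zb <- reach$z_centre - h2
  to <- tan(rad(spec$angle_occlusal / 2))
  tc <- tan(rad(70 / 2))  # cervical embrasure fixed at a 70 degree opening
  do_ <- pmin(pmax(z - zt, 0), reach$z)
  dc <- pmin(pmax(zb - z, 0), reach$z)
  do_ * to + dc * tc
}

# Row offsets for chamfer sampling: a geometric ladder starting at 0.2 mm so
# that, at zero noise, no chamfer point falls within the contact tolerance of
# the opposing tooth in any projection (the facet itself carries the exact
# boundary). For embrasure openings of at least 35 degrees the first row sits
# more than 0.06 mm off the facet plane.
chamfer_offsets <- function(reach) {
  d <- 0.2
  out <- numeric(0)
  while (d <= reach) {
    out <- c(out, d)
    d <- d * 1.35
  }
  out
}

superellipse_xy <- function(phi, a, b, m = 4) {
  cbind(a / 2 * sign(cos(phi)) * abs(cos(phi))^(2 / m),
        b / 2 * sign(sin(phi)) * abs(sin(phi))^(2 / m))
}

# Structured (deterministic) samples of the facing face of one tooth:
# facet grid plus chamfer ladders. Returned in the tooth-2 (+x) orientation.
face_points <- function(spec, reach) {
  w2 <- spec$contact_width / 2
  h2 <- spec$contact_height / 2
  zt <- reach$z_centre + h2
  zb <- reach$z_centre - h2
  gy <- seq(-w2, w2, length.out = max(2L, round(spec$contact_width / 0.05) + 1L))
  gz <- seq(zb, zt, length.out = max(2L, round(spec$contact_height / 0.05) + 1L))
  facet <- cbind(0, rep(gy, times = length(gz)), rep(gz, each = length(gy)))

  offs <- chamfer_offsets(reach$y)
  zspan <- seq(zb - 0.8 * reach$z, zt + 0.8 * reach$z, by = 0.08)
  side <- do.call(rbind, lapply(offs, function(d) {
    yb <- w2 + d
    rbind(cbind(face_fy(yb, spec, reach) + face_fz(zspan, spec, reach),
                yb, zspan),
          cbind(face_fy(-yb, spec, reach) + face_fz(zspan, spec, reach),
                -yb, zspan))
  }))

  offz <- chamfer_offsets(reach$z)
  yspan <- seq(-(w2 + 0.8 * reach$y), w2 + 0.8 * reach$y, by = 0.08)
  topbot <- do.call(rbind, lapply(offz, function(d) {
    rbind(cbind(face_fy(yspan, spec, reach) + face_fz(zt + d, spec, reach),
                yspan, zt + d),
          cbind(face_fy(yspan, spec, reach) + face_fz(zb - d, spec, reach),
                yspan, zb - d))
  }))
  rbind(facet, side, topbot)
}

# Random samples of the tooth body (superellipse wall and occlusal cap),
# clipped away from the facing-face construction.
body_points <- function(spec, reach, n) {
  if (n <= 0) return(matrix(numeric(0), ncol = 3))
  cx <- spec$crown_width_md / 2
  n_wall <- round(0.7 * n)
  n_top <- n - n_wall
  phi <- runif(n_wall, 0, 2 * pi)
  xy <- superellipse_xy(phi, spec$crown_width_md, spec$crown_width_bl)
  wall <- cbind(cx + xy[, 1], xy[, 2], runif(n_wall, 0, spec$crown_height))
  # occlusal cap by rejection inside the superellipse footprint
  m <- 4
  px <- runif(3 * n_top, -0.5, 0.5) * spec$crown_width_md
  py <- runif(3 * n_top, -0.5, 0.5) * spec$crown_width_bl
  keep <- (abs(2 * px / spec$crown_width_md)^m +
             abs(2 * py / spec$crown_width_bl)^m) <= 1
  px <- px[keep][seq_len(min(n_top, sum(keep)))]
  py <- py[keep][seq_len(min(n_top, sum(keep)))]
  top <- cbind(cx + px, py, spec$crown_height)
  pts <- rbind(wall, top)
  face <- face_fy(pts[, 2], spec, reach) + face_fz(pts[, 3], spec, reach)
  pts[pts[, 1] >= face + 0.15, , drop = FALSE]
}

#' Generate a labelled synthetic molar pair
#'
#' Builds the two teeth in the canonical frame (x mesiodistal, +y buccal,
#' z occlusal), meeting at a flat vertical contact facet at x = 0 whose width,
#' height and flanking embrasure openings are taken from the spec; applies
#' isotropic Gaussian jitter; and returns the cloud together with the
#' ground-truth values of the five interproximal features.
#'
#' @param spec a [tooth_pair_spec()].
#' @return A list of class `tooth_pair` with elements `cloud`
#'   (a [labeled_cloud()]), `truth` (one-row data frame of the five features)
#'   and `spec`.
#' @export
#' @examples
#' pair <- generate_tooth_pair(tooth_pair_spec(noise_sd = 0, seed = 7))
#' pair$truth
generate_tooth_pair <- function(spec) {
  if (!inherits(spec, "tooth_pair_spec")) stopf("expected a tooth_pair_spec")
  reach <- chamfer_reach(spec)
  face <- face_points(spec, reach)
  withr::with_seed(spec$seed, {
    # at least a quarter of the budget goes to the crown body so the cloud
    # always spans the full tooth, even when the contact patches dominate
    n_body <- max(round(0.25 * spec$points_per_tooth),
                  spec$points_per_tooth - nrow(face))
    body2 <- body_points(spec, reach, n_body)
    body1 <- body_points(spec, reach, n_body)
    p2 <- rbind(face, body2)
    p1 <- rbind(face, body1)
    p1[, 1] <- -p1[, 1]                       # mirror tooth 1 across x = 0
    pts <- rbind(p1, p2)
    labels <- rep(1:2, c(nrow(p1), nrow(p2)))
    if (spec$noise_sd > 0) {
      pts <- pts + matrix(rnorm(length(pts), 0, spec$noise_sd), ncol = 3)
    }
  })
  colnames(pts) <- c("x", "y", "z")
  truth <- data.frame(adjacent_line_length_mm = spec$contact_width,
                      adjacent_surface_area_mm2 =
                        spec$contact_width * spec$contact_height,
                      tongue_angle_deg = spec$angle_lingual,
                      buccal_angle_deg = spec$angle_buccal,
                      occlusal_angle_deg = spec$angle_occlusal)
  structure(list(cloud = labeled_cloud(pts, labels), truth = truth,
                 spec = spec),
            class = "tooth_pair")
}

#' @export
print.tooth_pair <- function(x, ...) {
  cat("<tooth_pair>\n")
  print(x$cloud)
  cat("ground truth:\n")
  print(x$truth, row.names = FALSE)
  invisible(x)
}
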