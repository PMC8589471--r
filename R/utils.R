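# Internal helpers shared across modules.

feature_names <- function() {
  c("adjacent_line_length_mm", "adjacent_surface_area_mm2",
    "tongue_angle_deg", "buccal_angle_deg", "occlusal_angle_deg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

vmsg <- function(...) {
  if (isTRUE(getOption("proxigap.verbose", FALSE))) {
    message(sprintf(...))
  }
}

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("cannot normalise a zero-length vector")
  v / n
}

deg <- function(rad) rad * 180 / pi
rad <- function(d) d * pi / 180

#' Expected maximum of a noisy half-plane boundary
#'
#' Mean of `max_i (U_i + e_i)` where the `U_i` form a Poisson process of the
#' given `intensity` on the negative half-line (the body of the object, whose
#' true boundary sits at 0) and the `e_i` are independent Gaussian measurement
#' errors with standard deviation `sigma`. This is the expected amount by which
#' the observed extreme of a jittered point sample overshoots the true support
#' of the sampled shape; it is used to debias dividing-line endpoints and
#' convex-hull areas. The correction vanishes as `sigma -> 0`.
#'
#' @param sigma Gaussian noise standard deviation (same units as the data).
#' @param intensity points per unit length along the direction of interest.
#' @return Expected overshoot (non-negative scalar).
#' @keywords internal
gaussian_max_excess <- function(sigma, intensity) {
  if (!is.finite(sigma) || !is.finite(intensity) ||
      sigma <= 0 || intensity <= 0) {
    return(0)
  }
  nu <- intensity * sigma
  # P(M <= t) = exp(-nu * I(t/sigma)),  I(z) = phi(z) - z * (1 - Phi(z))
  Iz <- function(z) dnorm(z) - z * pnorm(z, lower.tail = FALSE)
  Fz <- function(z) exp(-nu * Iz(z))
  upper <- integrate(function(z) 1 - Fz(z), 0, Inf,
                     rel.tol = 1e-7, stop.on.error = FALSE)$value
  lower <- integrate(Fz, -Inf, 0, rel.tol = 1e-7,
                     stop.on.error = FALSE)$value
  max(0, sigma * (upper - lower))
}

# Shoelace area of a polygon given as a two-column matrix of vertices.
polygon_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  abs(pracma::polyarea(xy[, 1], xy[, 2]))
}

# Deterministic child seeds derived from one pipeline seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(teeth = 11L, cohort = 23L, measure = 37L, analyse = 53L,
               score = 71L, body = 83L, noise = 97L)
  off <- offsets[[stage]] %||% 131L
  as.integer((as.numeric(seed) * 1000L + off) %% 2147483647)
}
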