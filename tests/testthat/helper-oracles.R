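# Independent oracles and shared fixtures for the test suite.

# Brute-force diameter of a 2D point set: O(M^2) reference for the
# farthest-pair machinery inside the dividing line.
brute_force_diameter <- function(pts) {
  m <- nrow(pts)
  best <- 0
  for (i in seq_len(m - 1)) {
    d2 <- (pts[(i + 1):m, 1] - pts[i, 1])^2 + (pts[(i + 1):m, 2] - pts[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Independent Newton-Raphson maximiser of the Bernoulli log-likelihood,
# written directly from the score and observed information.
newton_logistic <- function(X, y, iter = 50) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(iter)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    score <- drop(t(X1) %*% (y - p))
    info <- t(X1) %*% (X1 * w)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# Random tooth-pair specs for the parameter-recovery sweeps.
random_spec <- function(i, noise_sd, points_per_tooth = 8000) {
  withr::with_seed(7000 + i, {
    tooth_pair_spec(contact_width = runif(1, 2.6, 4.4),
                    contact_height = runif(1, 1.3, 2.2),
                    angle_buccal = runif(1, 40, 110),
                    angle_lingual = runif(1, 40, 110),
                    angle_occlusal = runif(1, 55, 130),
                    points_per_tooth = points_per_tooth,
                    noise_sd = noise_sd,
                    seed = 7000 + i)
  })
}

# Correlation structure with one weak item (the tongue angle analogue):
# two correlated blocks plus an item that barely touches either.
weak_item_correlation <- function() {
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- 0.55
  R[1, 5] <- R[5, 1] <- -0.40
  R[2, 5] <- R[5, 2] <- -0.40
  R[4, 5] <- R[5, 4] <- -0.35
  R[3, 4] <- R[4, 3] <- -0.10
  R[3, 1] <- R[1, 3] <- 0.05
  R[3, 2] <- R[2, 3] <- 0.08
  R
}

# Simple closed unit-cube mesh for the sampling tests.
unit_square_mesh <- function() {
  v <- matrix(c(0, 0, 0,
                1, 0, 0,
                1, 1, 0,
                0, 1, 0), ncol = 3, byrow = TRUE)
  structure(list(vertices = v,
                 faces = matrix(c(1, 2, 3, 1, 3, 4), ncol = 3, byrow = TRUE)),
            class = "tri_mesh")
}

fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
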