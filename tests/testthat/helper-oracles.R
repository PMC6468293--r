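# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check.

# proper rotation from a seeded QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimum RMSD over all proper rotations by direct optimization over Euler
# angles (multi-start Nelder-Mead), after centering both point sets
brute_force_min_rmsd <- function(mobile, reference) {
  a <- scale(mobile, scale = FALSE)
  b <- scale(reference, scale = FALSE)
  euler <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  f <- function(p) sqrt(mean(rowSums((a %*% t(euler(p)) - b)^2)))
  best <- Inf
  set.seed(42)
  starts <- rbind(c(0, 0, 0), matrix(runif(3 * 20, -pi, pi), ncol = 3))
  for (k in seq_len(nrow(starts))) {
    fit <- optim(starts[k, ], f, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# accessible area of two intersecting spheres (radii already include probe)
two_sphere_areas <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  stopifnot(d > abs(r1 - r2)) # neither engulfed
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1, 4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Monte-Carlo SASA with seeded uniform sphere sampling: an independent route
# (random directions, per-point inclusion test written longhand)
mc_sasa <- function(structure, probe = 1.4, n = 20000, seed = 99) {
  set.seed(seed)
  xyz <- cbind(structure$x, structure$y, structure$z)
  r <- structure$vdw + probe
  m <- nrow(xyz)
  total <- 0
  for (i in seq_len(m)) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n)
    for (j in seq_len(m)) {
      if (j == i) next
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 + (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= r[j]^2
    }
    total <- total + mean(exposed) * 4 * pi * r[i]^2
  }
  total
}

# path where a locally provided copy of PDB entry 6MFV is expected; the
# reference-structure acceptance checks need this file (it is never downloaded)
local_6mfv <- function() testthat::test_path("data", "6MFV.cif")

ph0952_config <- function() {
  system.file("extdata", "ph0952.yaml", package = "standscan")
}
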