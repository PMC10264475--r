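# Independent oracles and shared fixtures for the test suite.

# Brute-force minimal RMSD over rigid motions: centers both point sets,
# then numerically minimises over a rotation-vector parameterisation from
# many starting points. Independent of the analytic Kabsch path.
oracle_min_rmsd <- function(mobile, reference, n_starts = 24) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  R0 <- sweep(reference, 2, cr)
  rotvec_to_mat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  objective <- function(v) {
    sqrt(mean(rowSums((M %*% t(rotvec_to_mat(v)) - R0)^2)))
  }
  best <- Inf
  set.seed(20240915)
  starts <- rbind(matrix(0, 1, 3), matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                                          ncol = 3))
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# Closed-form SASA of two equal fused spheres of radius R at distance d
# (d < 2R): each sphere loses a cap of height h = R - d/2.
oracle_fused_pair_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Closed-form volume of the union of two equal spheres of radius R at
# distance d (inclusion-exclusion with the lens intersection volume).
oracle_fused_pair_volume <- function(R, d) {
  lens <- pi * (2 * R - d)^2 * (d^2 + 4 * d * R) / (12 * d)
  2 * (4 / 3) * pi * R^3 - lens
}

# A minimal hand-built protein topology: one atom per residue, element C,
# explicit radii; used for contact-map boundary fixtures.
point_residue_topology <- function(n, radius = 1.0) {
  top <- topology(data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    resid = seq_len(n) - 1L, resname = "GLY", chain = "A",
    is_solvent = FALSE, stringsAsFactors = FALSE
  ))
  top$atoms$radius <- radius
  top
}

# CA-only topology for alignment fixtures (no radii needed).
ca_only_topology <- function(n) point_residue_topology(n)

# Compact three-shell point cloud (one CA per residue). Parameter-recovery
# tests need a compact, reasonably large selection: uniform-weight
# superposition leaks a share of the pooled rigid-motion noise into every
# residue, and on small or elongated selections that leakage inflates the
# apparent fluctuation of low-amplitude residues.
ca_cloud_fixture <- function(n_per_shell = 100) {
  pts <- rbind(fibonacci_sphere(n_per_shell) * 6,
               fibonacci_sphere(n_per_shell) * 9,
               fibonacci_sphere(n_per_shell) * 12)
  list(top = ca_only_topology(nrow(pts)), frm = frame(pts), n = nrow(pts))
}

make_static_trajectory <- function(top, coords, n_frames = 4, dt = 1) {
  trajectory(top, lapply(seq_len(n_frames), function(k) {
    frame(coords, time = (k - 1) * dt)
  }))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
}

# Chiral 4-point set and its mirror image (no proper rotation maps one
# onto the other).
chiral_points <- function() {
  A <- rbind(c(0, 0, 0), c(1.7, 0, 0), c(0, 1.3, 0), c(0.3, 0.4, 1.9))
  list(A = A, mirrored = A %*% diag(c(1, 1, -1)))
}

# Frames alternating between two conformations whose displacement field
# is balanced (zero net translation, symmetric cross-covariance), so the
# optimal superposition is the identity and per-atom RMSF is exactly
# half the flip distance.
flip_fixture <- function(a = 4, d = 0.8, n_frames = 6) {
  top <- ca_only_topology(5)
  X <- rbind(c(a, 0, 0), c(0, a, 0), c(-a, 0, 0), c(0, -a, 0), c(0, 0, a))
  Y <- X
  Y[1, 1] <- a + d
  Y[3, 1] <- -a - d
  frames <- lapply(seq_len(n_frames), function(k) {
    frame(if (k %% 2 == 1) X else Y, time = k - 1)
  })
  list(top = top, traj = trajectory(top, frames), d = d)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
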