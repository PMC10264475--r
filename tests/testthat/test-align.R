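# Kabsch superposition, RMSD schemes, replica averaging and RMSF.

test_that("kabsch superposition is exact under rigid motions", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  s <- kabsch_superpose(X, X)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  Y <- X %*% t(rotation_z(90))
  Y <- sweep(Y, 2, c(5, 0, 0), `+`)
  s2 <- kabsch_superpose(Y, X)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(Y, s2), X, tolerance = 1e-8)
})

test_that("chiral point sets match the numeric-minimisation oracle, not zero", {
  ch <- chiral_points()
  got <- kabsch_superpose(ch$mirrored, ch$A)$rmsd
  want <- oracle_min_rmsd(ch$mirrored, ch$A)
  expect_gt(got, 0.3)  # a mirror image must NOT superpose to zero
  expect_equal(got, want, tolerance = 1e-5)
  expect_equal(det(kabsch_superpose(ch$mirrored, ch$A)$rotation), 1,
               tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 points")
  line <- cbind(1:5, 0, 0) * 1.0
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("kabsch rmsd agrees with the bio3d fitted-rmsd implementation", {
  set.seed(19)
  for (i in 1:5) {
    A <- matrix(rnorm(30, sd = 2), ncol = 3)
    B <- A + matrix(rnorm(30, sd = 0.7), ncol = 3)
    ours <- kabsch_superpose(B, A)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
    expect_lt(abs(ours - theirs), 5.1e-4)  # bio3d reports 3 decimals
  }
})

test_that("fitted rmsd never exceeds unfitted rmsd", {
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(24), ncol = 3)
    B <- matrix(rnorm(24), ncol = 3)
    unfitted <- sqrt(mean(rowSums((A - B)^2)))
    expect_lte(kabsch_superpose(A, B)$rmsd, unfitted + 1e-12)
  }
})

test_that("rmsd series vanish for static and rigidly-rotated trajectories", {
  top <- ca_only_topology(6)
  set.seed(3)
  X <- matrix(rnorm(18, sd = 3), ncol = 3)
  static <- make_static_trajectory(top, X, n_frames = 5)
  s <- rmsd_series(static, rmsd_scheme("first_frame"), selection = "calpha")
  expect_equal(s$values, rep(0, 5), tolerance = 1e-10)
  rigid <- trajectory(top, lapply(1:5, function(k) {
    frame(sweep(X %*% t(rotation_z(30 * k)), 2, c(k, -k, 2 * k), `+`), time = k - 1)
  }))
  s2 <- rmsd_series(rigid, rmsd_scheme("first_frame"))
  expect_equal(s2$values, rep(0, 5), tolerance = 1e-8)
})

test_that("a linear morph gives a nondecreasing series ending at the endpoint rmsd", {
  top <- ca_only_topology(6)
  set.seed(8)
  A <- matrix(rnorm(18, sd = 3), ncol = 3)
  B <- A + matrix(rnorm(18, sd = 1), ncol = 3)
  frames <- lapply(0:10, function(k) frame(A + (k / 10) * (B - A), time = k))
  s <- rmsd_series(trajectory(top, frames), rmsd_scheme("first_frame"))
  expect_true(all(diff(s$values) >= -1e-9))
  expect_equal(s$values[11], kabsch_superpose(B, A)$rmsd, tolerance = 1e-9)
  # invariant under one global rigid motion applied to every frame
  moved <- trajectory(top, lapply(frames, function(f) {
    frame(sweep(f$coords %*% t(rotation_z(57)), 2, c(1, 2, 3), `+`), time = f$time)
  }))
  s_m <- rmsd_series(moved, rmsd_scheme("first_frame"))
  expect_equal(s_m$values, s$values, tolerance = 1e-8)
})

test_that("scheme references are wired to the right frames", {
  top <- ca_only_topology(5)
  set.seed(12)
  A <- matrix(rnorm(15, sd = 3), ncol = 3)
  B <- A + 0.5
  traj <- trajectory(top, list(frame(A, 0), frame(B, 1)))
  ext <- rmsd_series(traj, rmsd_scheme("external_reference", reference = frame(A, 0)))
  expect_equal(ext$values[1], 0, tolerance = 1e-10)
  pm <- rmsd_scheme("parent_mapped", references = list(frame(A, 0)))
  expect_equal(rmsd_series(traj, pm, replica_index = 1)$values[1], 0,
               tolerance = 1e-10)
  expect_error(rmsd_series(traj, pm, replica_index = 2), "replica 2")
  expect_error(rmsd_series(traj, pm), "replica index")
})

test_that("replica mean series averages pointwise with sd", {
  base <- metric_series(0:3, c(1, 2, 3, 4))
  five <- replicate(5, base, simplify = FALSE)
  m <- replica_mean_series(five)
  expect_equal(m$values, base$values)
  expect_equal(m$sd, rep(0, 4))
  singles <- lapply(1:5, function(v) metric_series(0, v))
  expect_equal(replica_mean_series(singles)$values, 3)
  expect_error(replica_mean_series(list(base, metric_series(0:4, 1:5))),
               "lengths differ")
})

test_that("average structures recover midpoints and jittered means", {
  top <- ca_only_topology(5)
  X <- rbind(c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0), c(0, -4, 0), c(0, 0, 4))
  # static trajectory: the average is the frame itself
  avg0 <- average_structure(make_static_trajectory(top, X), selection = "calpha")
  expect_equal(avg0$coords, X, tolerance = 1e-10)
  # one atom displaced +d / -d with the fit anchored on the other atoms
  d <- c(0.6, 0, 0)
  Xp <- X; Xp[5, ] <- X[5, ] + d
  Xm <- X; Xm[5, ] <- X[5, ] - d
  traj <- trajectory(top, list(frame(Xm, 0), frame(Xp, 1)))
  avg <- average_structure(traj, selection = 1:4)
  expect_equal(avg$coords, X, tolerance = 1e-10)
  # Gaussian jitter: mean recovered within 3 sigma / sqrt(n) per coordinate
  sigma <- 0.1; nfr <- 400
  jit <- with_preserved_seed(99, {
    trajectory(top, lapply(seq_len(nfr), function(k) {
      frame(X + matrix(rnorm(15, sd = sigma), ncol = 3), time = k - 1)
    }))
  })
  # the average lives in the first frame's (noisy) coordinate frame, so
  # compare after superposing it back onto the ground truth
  avg_j <- average_structure(jit, selection = "calpha")
  sup <- kabsch_superpose(avg_j$coords, X)
  expect_lt(max(abs(apply_superposition(avg_j$coords, sup) - X)),
            3 * sigma / sqrt(nfr))
})

test_that("rmsf is zero for static replicas and d/2 for balanced flips", {
  top <- ca_only_topology(5)
  X <- rbind(c(4, 0, 0), c(0, 4, 0), c(-4, 0, 0), c(0, -4, 0), c(0, 0, 4))
  static_set <- replica_set(
    lapply(1:3, function(i) make_static_trajectory(top, X)),
    condition("solution"))
  expect_equal(rmsf_profile(static_set)$rmsf, rep(0, 5), tolerance = 1e-10)
  fx <- flip_fixture(d = 0.8)
  prof <- rmsf_profile(fx$traj)
  expect_equal(prof$rmsf, c(0.4, 0, 0.4, 0, 0), tolerance = 1e-9)
})

test_that("rmsf recovers per-residue amplitudes as sigma * sqrt(3)", {
  cloud <- ca_cloud_fixture()
  sig <- rep(c(0.2, 0.4, 0.8), length.out = cloud$n)
  sim <- simulate_replicas(cloud$top, cloud$frm, scale = 1, tau_relax = 10,
                           sigma = sig, n_frames = 1000, dt = 1,
                           n_replicas = 2, seed = 77)  # 2000 pooled frames
  prof <- rmsf_profile(sim$replica_set)
  rel_err <- abs(prof$rmsf - sig * sqrt(3)) / (sig * sqrt(3))
  expect_lt(max(rel_err), 0.05)
})

test_that("rmsf is invariant under rigid motion and replica permutation", {
  toy <- make_toy_protein(10, n_side_atoms = 0, polar_backbone = FALSE, seed = 9)
  sim <- simulate_replicas(toy$topology, toy$frame, scale = 1, tau_relax = 10,
                           sigma = 0.4, n_frames = 40, dt = 1,
                           n_replicas = 3, seed = 31)
  rs <- sim$replica_set
  base <- rmsf_profile(rs)
  moved <- replica_set(lapply(rs$replicas, function(tr) {
    trajectory(tr$topology, lapply(tr$frames, function(f) {
      frame(sweep(f$coords %*% t(rotation_z(123)), 2, c(10, -4, 2), `+`),
            time = f$time)
    }))
  }), rs$condition)
  expect_equal(rmsf_profile(moved)$rmsf, base$rmsf, tolerance = 1e-8)
  # permutation changes the (arbitrary) anchor frame of the first
  # superposition pass, so agreement is to the refinement tolerance
  permuted <- replica_set(rs$replicas[c(3, 1, 2)], rs$condition)
  expect_equal(rmsf_profile(permuted)$rmsf, base$rmsf, tolerance = 1e-3)
})
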