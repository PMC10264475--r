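# CCS, SASA, envelope volume, convexity, window statistics and
# compaction-delta arithmetic, against closed-form geometry oracles.

test_that("projection CCS matches sphere and far-pair closed forms", {
  sph <- make_sphere_fixture(2)
  ccs <- ccs_projection_approximation(sph$frame$coords, sph$topology,
                                      n_rotations = 200, seed = 7)
  expect_close(ccs$value, 4 * pi, max(3 * ccs$uncertainty, 0.02 * 4 * pi))
  # two unit spheres 1000 A apart: shadows add, CCS -> 2 pi
  far <- make_dumbbell_fixture(1, 1000)
  ccs2 <- ccs_projection_approximation(far$frame$coords, far$topology,
                                       n_rotations = 150, seed = 3)
  expect_close(ccs2$value, 2 * pi, max(3 * ccs2$uncertainty, 0.02 * 2 * pi))
  expect_error(ccs_projection_approximation(far$frame$coords, c(1, NA)),
               "missing radius")
})

test_that("the grid and Monte-Carlo CCS estimators agree", {
  toy <- make_toy_protein(6, seed = 5)
  xyz <- toy$frame$coords
  g <- ccs_projection_approximation(xyz, toy$topology, n_rotations = 120, seed = 1)
  m <- ccs_projection_approximation(xyz, toy$topology, n_rotations = 120, seed = 1,
                                    method = "mc", mc_points = 6000)
  expect_close(m$value, g$value, 3 * sqrt(g$uncertainty^2 + m$uncertainty^2) + 0.01 * g$value)
})

test_that("CCS and SASA scale as s^2, volume as s^3", {
  toy <- make_toy_protein(6, seed = 6)
  xyz <- toy$frame$coords
  r <- toy$topology$atoms$radius
  s <- 1.6
  ccs1 <- ccs_projection_approximation(xyz, r, n_rotations = 150, seed = 2)
  ccs2 <- ccs_projection_approximation(xyz * s, r * s, n_rotations = 150, seed = 2)
  expect_close(ccs2$value, s^2 * ccs1$value,
               3 * (s^2 * ccs1$uncertainty + ccs2$uncertainty) + 0.01 * ccs2$value)
  sa1 <- sasa_shrake_rupley(xyz, r, probe_radius = 0)
  sa2 <- sasa_shrake_rupley(xyz * s, r * s, probe_radius = 0)
  expect_equal(sa2$value, s^2 * sa1$value, tolerance = 1e-9)
  v1 <- envelope_volume(xyz, r, 0.25)
  v2 <- envelope_volume(xyz * s, r * s, 0.25)
  expect_equal(v2$value, s^3 * v1$value, tolerance = 0.02)
})

test_that("shape metrics are invariant under rigid motion", {
  toy <- make_toy_protein(5, seed = 8)
  xyz <- toy$frame$coords
  r <- toy$topology$atoms$radius
  moved <- sweep(xyz %*% t(rotation_z(77)), 2, c(30, -12, 5), `+`)
  sa <- sasa_shrake_rupley(xyz, r)$value
  sa_m <- sasa_shrake_rupley(moved, r)$value
  expect_equal(sa_m, sa, tolerance = 5e-3)
  v <- envelope_volume(xyz, r, 0.3)$value
  v_m <- envelope_volume(moved, r, 0.3)$value
  expect_equal(v_m, v, tolerance = 0.02)  # voxel-lattice alignment noise
  c1 <- ccs_projection_approximation(xyz, r, n_rotations = 150, seed = 4)
  c2 <- ccs_projection_approximation(moved, r, n_rotations = 150, seed = 9)
  expect_close(c2$value, c1$value,
               3 * (c1$uncertainty + c2$uncertainty) + 0.01 * c1$value)
})

test_that("CCS calibration multiplies and validates", {
  expect_equal(round_half_away(apply_ccs_calibration(851, 1.14)), 970)
  expect_equal(apply_ccs_calibration(123.4, 1.0), 123.4)
  expect_equal(apply_ccs_calibration(100, 1.14), 114)
  expect_error(apply_ccs_calibration(100, 0), "positive")
  expect_error(apply_ccs_calibration(-1, 1.14), "positive")
})

test_that("Shrake-Rupley matches isolated-sphere and fused-pair closed forms", {
  sph <- make_sphere_fixture(1.9)
  sa <- sasa_shrake_rupley(sph$frame$coords, sph$topology, probe_radius = 1.4)
  expect_equal(sa$value, 4 * pi * 3.3^2, tolerance = 1e-9)  # isolated: exact
  pair <- make_dumbbell_fixture(2, 2)  # extended radius 2, probe folded in
  sa2 <- sasa_shrake_rupley(pair$frame$coords, pair$topology, probe_radius = 0)
  expect_equal(sa2$value, oracle_fused_pair_area(2, 2), tolerance = 0.01)
  expect_equal(oracle_fused_pair_area(2, 2), 24 * pi)  # spherical-cap algebra
  # a tightly caged atom contributes no area
  cage_dirs <- fibonacci_sphere(40)
  coords <- rbind(c(0, 0, 0), cage_dirs * 1.1)
  radii <- c(0.8, rep(1.0, 40))
  sa3 <- sasa_shrake_rupley(coords, radii, probe_radius = 0)
  expect_equal(attr(sa3, "per_atom")[1], 0)
  expect_error(sasa_shrake_rupley(coords, radii, n_sphere_points = 8), ">= 16")
})

test_that("envelope volume matches sphere, disjoint and lens closed forms", {
  sph <- make_sphere_fixture(1.5)
  v <- envelope_volume(sph$frame$coords, sph$topology, 0.2)
  expect_equal(v$value, 4 / 3 * pi * 1.5^3, tolerance = 0.02)
  far <- make_dumbbell_fixture(1.5, 30)
  v2 <- envelope_volume(far$frame$coords, far$topology, 0.2)
  expect_equal(v2$value, 2 * 4 / 3 * pi * 1.5^3, tolerance = 0.02)
  lens <- make_dumbbell_fixture(2, 3)
  v3 <- envelope_volume(lens$frame$coords, lens$topology, 0.15)
  expect_equal(v3$value, oracle_fused_pair_volume(2, 3), tolerance = 0.02)
  expect_error(envelope_volume(sph$frame$coords, sph$topology, 2), "radius")
})

test_that("voxel refinement reduces the volume discretisation error", {
  sph <- make_sphere_fixture(1.5)
  truth <- 4 / 3 * pi * 1.5^3
  errs <- vapply(c(0.4, 0.1), function(h) {
    abs(envelope_volume(sph$frame$coords, sph$topology, h)$value - truth)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("surface-to-shadow ratio is 4 for convex bodies, >= 4 otherwise", {
  sph <- make_sphere_fixture(3)
  r1 <- convexity_ratio(sph$frame$coords, sph$topology, seed = 11,
                        n_rotations = 300)
  expect_close(as.numeric(r1), 4, max(3 * attr(r1, "se"), 0.01))
  far <- make_dumbbell_fixture(1.5, 1000)
  r2 <- convexity_ratio(far$frame$coords, far$topology, seed = 12,
                        n_rotations = 200)
  expect_close(as.numeric(r2), 4, max(3 * attr(r2, "se"), 0.02))
  bell <- make_dumbbell_fixture(2, 3)
  r3 <- convexity_ratio(bell$frame$coords, bell$topology, seed = 13,
                        n_rotations = 200)
  expect_gte(as.numeric(r3), 4 - 3 * attr(r3, "se"))
})

test_that("window statistics pool frames across replicas", {
  s <- metric_series((0:7) * 1000, 1:8)
  st <- window_stats(list(s), last_fraction(0.5))
  expect_equal(st$mean, 6.5)
  expect_equal(window_stats(list(metric_series(0:3, rep(2, 4))), NULL)$sd, 0)
  long <- metric_series((0:199) * 1000, rep(1, 200))  # 200 frames at 1 ns
  expect_equal(window_stats(list(long, long), last_ps(50000))$n, 100)
})

test_that("compaction deltas reproduce the published arithmetic", {
  trp <- compaction_deltas(381, c(361, 357, 357), c(386, 383, 383))
  expect_equal(trp$delta_vs_vacuum_pct, 7L)
  expect_equal(trp$delta_vs_solution_pct, 1L)
  ctf_sasa <- compaction_deltas(4520, c(3781, 3975, 3805), c(4813, 4863, 4921))
  expect_equal(ctf_sasa$delta_vs_vacuum_pct, 26L)
  expect_equal(ctf_sasa$delta_vs_solution_pct, 8L)
  same <- compaction_deltas(100, c(100, 100, 100), c(100, 100, 100))
  expect_equal(same$delta_vs_vacuum_pct, 0L)
  expect_equal(same$delta_vs_solution_pct, 0L)
  expect_error(compaction_deltas(100, c(100, 100), c(100, 100, 100)), "length")
  expect_error(compaction_deltas(-1, 1, 1), "positive")
})

test_that("rounding half away from zero matches the reporting convention", {
  expect_equal(round_half_away(c(0.5, -0.5, 1.4, -1.5, 13.51)),
               c(1, -1, 1, -2, 14))
})

test_that("compacted conformations shrink every shape metric", {
  toy <- make_toy_protein(8, seed = 21)
  xyz <- toy$frame$coords
  r <- toy$topology$atoms$radius
  s <- 0.8
  compact <- sweep(sweep(xyz, 2, colMeans(xyz)) * s, 2, colMeans(xyz), `+`)
  expect_lt(ccs_projection_approximation(compact, r, 100, seed = 1)$value,
            ccs_projection_approximation(xyz, r, 100, seed = 1)$value)
  expect_lt(sasa_shrake_rupley(compact, r)$value, sasa_shrake_rupley(xyz, r)$value)
  expect_lt(envelope_volume(compact, r, 0.3)$value,
            envelope_volume(xyz, r, 0.3)$value)
})
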