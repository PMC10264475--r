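# Contact maps, difference maps, composites and hydrogen-bond counting.

two_residue_frame <- function(gap) {
  top <- point_residue_topology(2)
  list(top = top, frm = frame(rbind(c(0, 0, 0), c(gap, 0, 0))))
}

test_that("the 3.5 A contact rule is boundary-inclusive", {
  at <- two_residue_frame(3.5)
  M <- contact_matrix_frame(at$frm, at$top)
  expect_equal(M[1, 2], 1)
  just_out <- two_residue_frame(3.51)
  M2 <- contact_matrix_frame(just_out$frm, just_out$top)
  expect_equal(M2[1, 2], 0)
  expect_equal(diag(M2), c(GLY0 = 1, GLY1 = 1))
  expect_true(isTRUE(all.equal(M, t(M))))
})

test_that("contact matrices match an exhaustive all-pairs oracle", {
  toy <- make_toy_protein(5, seed = 14)
  top <- toy$topology
  xyz <- toy$frame$coords
  res <- residue_table(top)
  oracle <- diag(1, nrow(res))
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i == j) next
      ai <- res$first[i]:res$last[i]
      aj <- res$first[j]:res$last[j]
      dmin <- min(sqrt(outer(rowSums(xyz[ai, , drop = FALSE]^2),
                             rowSums(xyz[aj, , drop = FALSE]^2), `+`) -
                       2 * xyz[ai, , drop = FALSE] %*% t(xyz[aj, , drop = FALSE])))
      if (dmin <= 3.5) oracle[i, j] <- 1
    }
  }
  got_cell <- contact_matrix_frame(toy$frame, top, method = "cell")
  got_brute <- contact_matrix_frame(toy$frame, top, method = "brute")
  expect_equal(unname(got_cell), oracle)
  expect_equal(got_cell, got_brute)
})

test_that("cell-list and brute-force searches agree on random frames", {
  set.seed(55)
  for (rep in 1:4) {
    coords <- matrix(runif(3 * 60, 0, 15), ncol = 3)
    a <- close_atom_pairs(coords, 3.5, method = "cell")
    b <- close_atom_pairs(coords, 3.5, method = "brute")
    expect_equal(a, b)
  }
})

test_that("occupancy pools frames across replicas", {
  top <- point_residue_topology(2)
  near <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  far <- rbind(c(0, 0, 0), c(9.0, 0, 0))
  mk_traj <- function(states) {
    trajectory(top, lapply(seq_along(states), function(k) {
      frame(if (states[k]) near else far, time = k - 1)
    }))
  }
  # contact present in 2 of 4 frames of one replica
  rs1 <- replica_set(list(mk_traj(c(TRUE, TRUE, FALSE, FALSE))),
                     condition("solution"))
  expect_equal(occupancy_map(rs1)$occupancy[1, 2], 0.5)
  # present in all frames of 1 of 5 equal-length replicas
  rs2 <- replica_set(c(list(mk_traj(rep(TRUE, 4))),
                       lapply(1:4, function(i) mk_traj(rep(FALSE, 4)))),
                     condition("rehydration", 0))
  expect_equal(occupancy_map(rs2)$occupancy[1, 2], 0.2)
  # all frames
  rs3 <- replica_set(list(mk_traj(rep(TRUE, 3))), condition("solution"))
  expect_equal(occupancy_map(rs3)$occupancy[1, 2], 1.0)
  occ <- occupancy_map(rs2)
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  expect_equal(diag(occ$occupancy), c(GLY0 = 1, GLY1 = 1))
})

test_that("occupancy is invariant under replica permutation and rigid motion", {
  toy <- make_toy_protein(6, seed = 23)
  sim <- simulate_replicas(toy$topology, toy$frame, scale = 0.9, tau_relax = 5,
                           sigma = 0.3, n_frames = 6, dt = 1, n_replicas = 3,
                           seed = 41)
  rs <- sim$replica_set
  base <- occupancy_map(rs)
  perm <- replica_set(rs$replicas[c(2, 3, 1)], rs$condition)
  expect_equal(occupancy_map(perm)$occupancy, base$occupancy)
  moved <- replica_set(lapply(rs$replicas, function(tr) {
    trajectory(tr$topology, lapply(tr$frames, function(f) {
      frame(sweep(f$coords %*% t(rotation_z(31)), 2, c(5, 5, -5), `+`),
            time = f$time)
    }))
  }), rs$condition)
  expect_equal(occupancy_map(moved)$occupancy, base$occupancy)
})

test_that("larger cutoffs never remove contacts", {
  toy <- make_toy_protein(6, seed = 27)
  m1 <- contact_matrix_frame(toy$frame, toy$topology, cutoff = 3.5)
  m2 <- contact_matrix_frame(toy$frame, toy$topology, cutoff = 5.0)
  expect_true(all(m2 - m1 >= 0))
})

test_that("difference maps hit the +1/-1 endpoints and antisymmetry", {
  top <- point_residue_topology(2)
  near <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  far <- rbind(c(0, 0, 0), c(9.0, 0, 0))
  always <- replica_set(list(trajectory(top, list(frame(near, 0)))),
                        condition("rehydration", 0))
  never <- replica_set(list(trajectory(top, list(frame(far, 0)))),
                       condition("vacuum", 0))
  occ_a <- occupancy_map(always)
  occ_n <- occupancy_map(never)
  d <- difference_map(occ_a, occ_n)
  expect_equal(d$delta[1, 2], 1)           # contact only in the first map
  expect_equal(difference_map(occ_n, occ_a)$delta[1, 2], -1)
  expect_equal(difference_map(occ_a, occ_a)$delta, 0 * occ_a$occupancy)
  expect_equal(d$delta + difference_map(occ_n, occ_a)$delta,
               0 * d$delta)                # diff(A,B) + diff(B,A) = 0
  expect_equal(diag(d$delta), c(GLY0 = 0, GLY1 = 0))
  expect_true(all(d$delta >= -1 & d$delta <= 1))
})

test_that("composite maps pack triangles and zero the diagonal", {
  toy <- make_toy_protein(6, seed = 31)
  sim1 <- simulate_replicas(toy$topology, toy$frame, scale = 0.85, tau_relax = 5,
                            sigma = 0.3, n_frames = 5, dt = 1, n_replicas = 2,
                            seed = 1)
  sim2 <- simulate_replicas(toy$topology, toy$frame, scale = 0.95, tau_relax = 5,
                            sigma = 0.3, n_frames = 5, dt = 1, n_replicas = 2,
                            seed = 2)
  occ1 <- occupancy_map(sim1$replica_set)
  occ2 <- occupancy_map(sim2$replica_set)
  d12 <- difference_map(occ1, occ2)
  d21 <- difference_map(occ2, occ1)
  comp <- composite_triangle_map(d12, d21)
  expect_equal(comp[lower.tri(comp)], d12$delta[lower.tri(comp)])
  expect_equal(comp[upper.tri(comp)], d21$delta[upper.tri(comp)])
  expect_equal(diag(comp), setNames(rep(0, 6), rownames(comp)))
  # identical symmetric sources give a symmetric composite
  sym <- composite_triangle_map(d12, d12)
  expect_equal(sym, t(sym))
})

test_that("hydrogen bonds respect both distance and angle cutoffs", {
  mk_sys <- function(oa_dist, angle_deg) {
    th <- angle_deg * pi / 180
    atoms <- data.frame(
      serial = 1:4,
      name = c("N", "H", "OW", "HW1"),
      element = c("N", "H", "O", "H"),
      resid = c(0L, 0L, 1L, 1L),
      resname = c("ALA", "ALA", "HOH", "HOH"),
      chain = c("A", "A", "W", "W"),
      is_solvent = c(FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
    coords <- rbind(
      c(0, 0, 0),                                  # donor N
      c(1.0, 0, 0),                                # attached H
      c(oa_dist * cos(th), oa_dist * sin(th), 0),  # water O acceptor
      c(oa_dist * cos(th) + 0.96, oa_dist * sin(th), 0)  # water H, points away
    )
    list(top = topology(atoms), frm = frame(coords))
  }
  ok <- mk_sys(2.9, 5)
  expect_equal(hbond_count_frame(ok$frm, ok$top), 1L)
  too_far <- mk_sys(3.6, 5)
  expect_equal(hbond_count_frame(too_far$frm, too_far$top), 0L)
  bent <- mk_sys(2.9, 40)
  expect_equal(hbond_count_frame(bent$frm, bent$top), 0L)
  at_cut <- mk_sys(3.5, 29.9)
  expect_equal(hbond_count_frame(at_cut$frm, at_cut$top), 1L)  # inclusive bounds
  # no solvent: count 0 with a warning
  toy <- make_toy_protein(3, seed = 1)
  expect_warning(n0 <- hbond_count_frame(toy$frame, toy$topology), "no solvent")
  expect_equal(n0, 0L)
})

test_that("planted waters give exact counts and pooled statistics", {
  toy <- make_toy_protein(12, seed = 3)
  aug <- add_waters_with_hbonds(toy$topology, toy$frame, k_bonded = 3,
                                k_far = 10, seed = 2)
  expect_equal(hbond_count_frame(aug$frame, aug$topology), 3L)
  none <- add_waters_with_hbonds(toy$topology, toy$frame, k_bonded = 0,
                                 k_far = 4, seed = 2)
  expect_equal(hbond_count_frame(none$frame, none$topology), 0L)
  # constant count c -> mean c, sd 0
  traj <- trajectory(aug$topology, list(frame(aug$frame$coords, 0),
                                        frame(aug$frame$coords, 1)))
  rs <- replica_set(list(traj), condition("solution"))
  st <- hbond_series_mean(rs)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 0)
  # alternating k and k+2 planted bonds -> mean k+1
  aug5 <- add_waters_with_hbonds(toy$topology, toy$frame, k_bonded = 5,
                                 k_far = 8, seed = 2)
  alt <- trajectory(aug5$topology, list(frame(aug5$frame$coords, 0),
                                        frame(aug5$frame$coords + c(0, 0, 0), 1)))
  # build the k-bond variant by pushing two bonded waters far away
  pushed <- aug5$frame$coords
  sol_o <- which(aug5$topology$atoms$is_solvent &
                 aug5$topology$atoms$element == "O")[1:2]
  for (o in sol_o) pushed[c(o, o + 1, o + 2), ] <-
    pushed[c(o, o + 1, o + 2), ] + 50
  alt2 <- trajectory(aug5$topology, list(frame(aug5$frame$coords, 0),
                                         frame(pushed, 1)))
  st2 <- hbond_series_mean(replica_set(list(alt2), condition("solution")))
  expect_equal(st2$mean, 4)  # (5 + 3) / 2
})
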