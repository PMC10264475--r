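# synthetic: seeded generators for replica trajectory sets with
# closed-form ground truth, idealized shape fixtures, and placeable
# solvent for hydrogen-bond checks. These stand in for the molecular
# dynamics runs so the full analysis battery runs at desk scale.

#' Build a toy helical protein
#'
#' C-alpha atoms are laid on a helical arc with exactly `spacing`
#' Angstrom between consecutive C-alphas. Each residue further carries a
#' polar backbone (an outward-pointing N-H donor and an inward carbonyl
#' O acceptor) and `n_side_atoms` carbon dummies whose placement is
#' seeded -- different seeds give different side-chain placements while
#' the backbone stays fixed.
#'
#' @param n_residues number of residues (>= 2).
#' @param n_side_atoms carbon dummy atoms per residue (>= 0).
#' @param spacing consecutive C-alpha distance, Angstrom (default 3.8).
#' @param seed RNG seed for the side-chain placement.
#' @param polar_backbone include the N/H/O backbone atoms (needed for
#'   hydrogen-bond tests).
#' @return list with `topology` (radii assigned) and `frame`.
#' @export
make_toy_protein <- function(n_residues, n_side_atoms = 2, spacing = 3.8,
                             seed = 1, polar_backbone = TRUE) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  dtheta <- 100 * pi / 180
  rho <- min(2.3, 0.9 * spacing / (2 * sin(dtheta / 2)))
  chord <- 2 * rho * sin(dtheta / 2)
  rise <- sqrt(spacing^2 - chord^2)
  k <- seq_len(n_residues) - 1
  theta <- k * dtheta
  ca <- cbind(rho * cos(theta), rho * sin(theta), k * rise)
  outward <- cbind(cos(theta), sin(theta), 0)
  atoms <- list()
  coords <- list()
  with_preserved_seed(seed, {
    for (i in seq_len(n_residues)) {
      res_atoms <- data.frame(name = "CA", element = "C", stringsAsFactors = FALSE)
      res_coords <- ca[i, , drop = FALSE]
      if (polar_backbone) {
        nN <- ca[i, ] + 1.3 * outward[i, ]
        nH <- nN + 1.0 * outward[i, ]
        nO <- ca[i, ] - 1.2 * outward[i, ] + c(0, 0, 0.4)
        res_atoms <- rbind(res_atoms, data.frame(
          name = c("N", "H", "O"), element = c("N", "H", "O")))
        res_coords <- rbind(res_coords, rbind(nN, nH, nO))
      }
      if (n_side_atoms > 0) {
        for (j in seq_len(n_side_atoms)) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          res_atoms <- rbind(res_atoms, data.frame(
            name = paste0("CB", j), element = "C"))
          res_coords <- rbind(res_coords, ca[i, ] + 1.5 * j * u)
        }
      }
      res_atoms$resid <- i - 1L
      atoms[[i]] <- res_atoms
      coords[[i]] <- res_coords
    }
  })
  atoms <- do.call(rbind, atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resname <- "ALA"
  atoms$chain <- "A"
  atoms$is_solvent <- FALSE
  top <- assign_radii(topology(atoms))
  list(topology = top, frame = frame(do.call(rbind, coords), time = 0))
}

single_atom_topology <- function(n, radius, element = "C", resname = "SPH") {
  atoms <- data.frame(
    serial = seq_len(n), name = "X", element = element,
    resid = seq_len(n) - 1L, resname = resname, chain = "A",
    is_solvent = FALSE, stringsAsFactors = FALSE
  )
  top <- topology(atoms)
  top$atoms$radius <- rep(radius, length.out = n)
  top
}

#' Single-sphere shape fixture
#'
#' One atom with an explicit radius: every analytic shape quantity is
#' known in closed form (shadow `pi r^2`, surface `4 pi r^2`, volume
#' `4/3 pi r^3`).
#'
#' @param radius sphere radius, Angstrom.
#' @param center sphere center.
#' @return list with `topology` (radius set) and `frame`.
#' @export
make_sphere_fixture <- function(radius, center = c(0, 0, 0)) {
  if (radius <= 0) stop("radius must be positive")
  list(topology = single_atom_topology(1, radius),
       frame = frame(matrix(center, 1, 3), time = 0))
}

#' Two-sphere (dumbbell) shape fixture
#'
#' Two equal spheres along x separated by `separation`; far-separated
#' dumbbells have additive shadows and volumes, overlapping ones follow
#' the lens (sphere-intersection) closed forms.
#'
#' @param radius sphere radii, Angstrom.
#' @param separation center-to-center distance, Angstrom.
#' @return list with `topology` and `frame`.
#' @export
make_dumbbell_fixture <- function(radius, separation) {
  if (radius <= 0) stop("radius must be positive")
  if (separation < 0) stop("separation must be >= 0")
  coords <- rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0))
  list(topology = single_atom_topology(2, radius), frame = frame(coords, time = 0))
}

#' Simulate a rehydration-style replica set with known ground truth
#'
#' Frame coordinates follow a compacted start relaxing exponentially
#' toward the expanded reference, plus independent per-atom isotropic
#' Gaussian jitter with per-residue amplitudes:
#' `X(t) = X_exp + (s - 1) (X_exp - center) exp(-t / tau) + noise`.
#' At `t = 0` the structure is the uniformly compacted conformation
#' (scale `s` about the centroid); as `t >> tau` it converges to the
#' expanded reference. Replicas differ by deterministic seed offsets.
#'
#' @param top a [topology()].
#' @param start_frame the expanded reference [frame()].
#' @param scale compaction scale `s` in (0, 1]; `s = 1` means no
#'   relaxation (fluctuation-only control).
#' @param tau_relax relaxation time constant, ps.
#' @param sigma per-residue fluctuation amplitude(s), Angstrom (scalar or
#'   one per residue; applied to every atom of the residue).
#' @param n_frames frames per replica.
#' @param dt frame spacing, ps (first frame at t = 0).
#' @param n_replicas replica count (study default 5).
#' @param seed master seed; replica `i` uses `seed + i`.
#' @param cond condition label for the resulting set.
#' @return list with `replica_set` and `ground_truth` (expected final
#'   first-frame RMSD for the noise-free case, expected RMSF
#'   `sigma * sqrt(3)`, expected compact/expanded shape ratios `s^2` /
#'   `s^3`, and the per-replica seeds).
#' @export
simulate_replicas <- function(top, start_frame, scale = 0.8, tau_relax = 50,
                              sigma = 0, n_frames = 100, dt = 1,
                              n_replicas = 5, seed = 1,
                              cond = condition("rehydration", 0)) {
  stopifnot(inherits(top, "topology"))
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  if (tau_relax <= 0) stop("tau_relax must be positive")
  if (n_frames < 1) stop("need at least one frame")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  x_exp <- if (inherits(start_frame, "frame")) start_frame$coords else start_frame
  if (nrow(x_exp) != n_atoms(top)) stop("start frame does not match topology")
  nres <- length(unique(top$atoms$resid))
  sig_res <- rep(sigma, length.out = nres)
  sig_atom <- sig_res[match(top$atoms$resid, sort(unique(top$atoms$resid)))]
  center <- colMeans(x_exp)
  dev <- sweep(x_exp, 2, center)
  times <- (seq_len(n_frames) - 1) * dt
  seeds <- seed + seq_len(n_replicas)
  replicas <- lapply(seq_len(n_replicas), function(rep_i) {
    with_preserved_seed(seeds[rep_i], {
      frames <- lapply(seq_len(n_frames), function(k) {
        decay <- exp(-times[k] / tau_relax)
        noise <- matrix(stats::rnorm(length(x_exp), sd = rep(sig_atom, 3)),
                        ncol = 3)
        frame(x_exp + (scale - 1) * dev * decay + noise, time = times[k])
      })
      trajectory(top, frames)
    })
  })
  x_compact <- x_exp + (scale - 1) * dev
  ca <- select_atoms(top, "calpha")
  final_rmsd <- if (scale < 1) {
    kabsch_superpose(x_exp[ca, , drop = FALSE], x_compact[ca, , drop = FALSE])$rmsd
  } else 0
  list(
    replica_set = replica_set(replicas, cond),
    ground_truth = list(
      expected_final_rmsd_f = final_rmsd,
      expected_rmsf = sig_res * sqrt(3),
      expected_area_ratio = scale^2,
      expected_volume_ratio = scale^3,
      replica_seeds = seeds
    )
  )
}

#' Add water molecules with planted hydrogen bonds
#'
#' Places `k_bonded` three-site waters at ideal hydrogen-bond geometry
#' (acceptor oxygen 2.9 Angstrom from a protein N-H donor along the N-H
#' direction, so the H-D-A angle is ~0), with the water hydrogens (O-H
#' 0.96 Angstrom) pointing away from the protein, and `k_far` waters
#' beyond 8 Angstrom from every protein atom. The planted count is the
#' generator's ground truth for the hydrogen-bond counter.
#'
#' @param top protein [topology()] (needs `>= k_bonded` N-H donors).
#' @param frm protein [frame()].
#' @param k_bonded waters at ideal bond geometry.
#' @param k_far distant waters.
#' @param seed RNG seed (far-water directions).
#' @return list with augmented `topology`, `frame`, and `ground_truth`
#'   (`k_bonded`).
#' @export
add_waters_with_hbonds <- function(top, frm, k_bonded, k_far = 0, seed = 1) {
  stopifnot(inherits(top, "topology"))
  coords <- if (inherits(frm, "frame")) frm$coords else frm
  a <- top$atoms
  pro <- which(!a$is_solvent)
  dn <- find_donors(coords, top, pro)
  if (k_bonded > length(dn$donor)) {
    stop(sprintf("need %d protein donor sites, topology has %d",
                 k_bonded, length(dn$donor)))
  }
  polar_protein <- pro[a$element[pro] %in% c("N", "O")]
  acceptors_protein <- polar_protein
  deg <- function(x) x * 180 / pi
  angle_at <- function(v1, v2) {
    deg(acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)))
  }
  # a candidate site is accepted only if, under the counting criterion
  # itself (D-A <= 3.5 A, H-D-A <= 30 deg), the new water makes exactly
  # one bond: the planted one. Exact by construction, robust to jitter.
  site_bond_count <- function(ow, hws) {
    n_bonds <- 0L
    for (k2 in seq_along(dn$donor)) {
      d2 <- dn$donor[k2]
      if (sqrt(sum((coords[d2, ] - ow)^2)) > 3.5) next
      for (hh in dn$hydrogens[[k2]]) {
        if (angle_at(coords[hh, ] - coords[d2, ], ow - coords[d2, ]) <= 30) {
          n_bonds <- n_bonds + 1L
          break
        }
      }
    }
    for (a2 in acceptors_protein) {
      if (sqrt(sum((coords[a2, ] - ow)^2)) > 3.5) next
      for (r2 in seq_len(nrow(hws))) {
        if (angle_at(hws[r2, ] - ow, coords[a2, ] - ow) <= 30) {
          n_bonds <- n_bonds + 1L
          break
        }
      }
    }
    n_bonds
  }
  placed_o <- list()
  placed_h <- list()
  used <- 0
  for (k in seq_along(dn$donor)) {
    if (used >= k_bonded) break
    d <- dn$donor[k]
    h <- dn$hydrogens[[k]][1]
    u <- coords[h, ] - coords[d, ]
    u <- u / sqrt(sum(u^2))
    ow <- coords[d, ] + 2.9 * u
    # hydrogens fan outward, bisector along +u (away from the donor)
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- p - sum(p * u) * u
    p <- p / sqrt(sum(p^2))
    th <- 52.25 * pi / 180
    hws <- rbind(ow + 0.96 * (cos(th) * u + sin(th) * p),
                 ow + 0.96 * (cos(th) * u - sin(th) * p))
    if (site_bond_count(ow, hws) != 1L) next
    if (length(placed_o)) {
      dw <- min(sqrt(colSums((do.call(cbind, placed_o) - ow)^2)))
      if (dw <= 3.0) next  # keep waters sterically apart
    }
    used <- used + 1
    placed_o[[used]] <- ow
    placed_h[[used]] <- hws
  }
  if (used < k_bonded) {
    stop("insufficient clear donor sites for the requested bonded waters")
  }
  far_o <- list()
  far_h <- list()
  if (k_far > 0) {
    centroid <- colMeans(coords[pro, , drop = FALSE])
    rmax <- max(sqrt(rowSums(sweep(coords[pro, , drop = FALSE], 2, centroid)^2)))
    with_preserved_seed(seed, {
      for (j in seq_len(k_far)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        ow <- centroid + (rmax + 10 + 2.5 * j) * u
        far_o[[j]] <- ow
        far_h[[j]] <- rbind(ow + c(0.96, 0, 0), ow + c(-0.24, 0.93, 0))
      }
    })
  }
  all_o <- c(placed_o, far_o)
  all_h <- c(placed_h, far_h)
  nw <- length(all_o)
  wat_coords <- do.call(rbind, lapply(seq_len(nw), function(i) {
    rbind(all_o[[i]], all_h[[i]])
  }))
  next_resid <- max(a$resid) + 1L
  wat_atoms <- data.frame(
    serial = max(a$serial) + seq_len(3 * nw),
    name = rep(c("OW", "HW1", "HW2"), nw),
    element = rep(c("O", "H", "H"), nw),
    resid = rep(next_resid + seq_len(nw) - 1L, each = 3),
    resname = "HOH", chain = "W", is_solvent = TRUE,
    stringsAsFactors = FALSE
  )
  new_atoms <- rbind(a[, names(wat_atoms)], wat_atoms)
  new_top <- topology(new_atoms)
  new_top <- assign_radii(new_top)
  if (all(is.finite(a$radius))) {
    new_top$atoms$radius[seq_len(nrow(a))] <- a$radius
  }
  list(
    topology = new_top,
    frame = frame(rbind(coords, wat_coords), time = if (inherits(frm, "frame")) frm$time else 0),
    ground_truth = list(k_bonded = as.integer(k_bonded), k_far = as.integer(k_far))
  )
}

#' Write a replica set as multi-model PDB files with a ground-truth sidecar
#'
#' Emits `replica_<i>.pdb` per replica plus `ground_truth.json`, so the
#' whole pipeline can run from files exactly as with real data.
#'
#' @param rset a [replica_set()].
#' @param dir output directory (created if needed).
#' @param ground_truth optional list serialized to JSON alongside.
#' @return character vector of written PDB paths, invisibly.
#' @export
write_replica_set <- function(rset, dir, ground_truth = NULL) {
  stopifnot(inherits(rset, "replica_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(rset$replicas), function(i) {
    p <- file.path(dir, sprintf("replica_%d.pdb", i))
    write_trajectory(rset$replicas[[i]], p)
    p
  }, character(1))
  meta <- list(condition = format(rset$condition),
               n_replicas = length(rset$replicas))
  if (!is.null(ground_truth)) meta$ground_truth <- ground_truth
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
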