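# shape: projection-approximation CCS, Shrake-Rupley SASA, envelope
# volume, window statistics, CCS calibration, convexity diagnostics and
# the compaction-delta report arithmetic.

#' Shape result container
#'
#' @param metric `"ccs"`, `"sasa"` or `"volume"`.
#' @param value metric value (Angstrom^2 for ccs/sasa, Angstrom^3 for volume).
#' @param uncertainty Monte-Carlo standard error or across-replica sd.
#' @param n sample count behind `value` (orientations, frames, ...).
#' @return object of class `shape_result`.
#' @export
shape_result <- function(metric, value, uncertainty = NA_real_, n = NA_integer_) {
  stopifnot(metric %in% c("ccs", "sasa", "volume"))
  if (!is.finite(value) || value <= 0) stop(metric, " value must be positive")
  if (is.finite(uncertainty) && uncertainty < 0) stop("uncertainty must be >= 0")
  structure(list(metric = metric, value = value,
                 uncertainty = uncertainty, n = n),
            class = "shape_result")
}

#' @export
print.shape_result <- function(x, ...) {
  u <- if (x$metric == "volume") "A^3" else "A^2"
  cat(sprintf("<shape_result> %s = %.3f %s (+/- %.3g, n = %d)\n",
              x$metric, x$value, u, x$uncertainty, x$n))
  invisible(x)
}

resolve_radii <- function(top_or_radii, n) {
  r <- if (inherits(top_or_radii, "topology")) top_or_radii$atoms$radius else as.numeric(top_or_radii)
  if (length(r) == 1) r <- rep(r, n)
  if (length(r) != n) stop("need one radius per atom")
  if (any(!is.finite(r))) stop("missing radius for one or more atoms; run assign_radii()")
  if (any(r <= 0)) stop("all radii must be positive")
  r
}

# Count grid cells (pixel centers) covered by the union of discs.
# Pixel centers sit at offset + (k + 0.5) * res on an unbounded lattice;
# sparse per-disc enumeration keeps far-separated bodies cheap.
disc_union_pixels <- function(px, py, r, res, ox, oy) {
  keys <- vector("list", length(px))
  for (i in seq_along(px)) {
    ix <- seq.int(floor((px[i] - r[i] - ox) / res), floor((px[i] + r[i] - ox) / res))
    xc <- ox + (ix + 0.5) * res
    half <- sqrt(pmax(r[i]^2 - (xc - px[i])^2, 0))
    iy_lo <- ceiling((py[i] - half - oy) / res - 0.5)
    iy_hi <- floor((py[i] + half - oy) / res - 0.5)
    nrows <- pmax(iy_hi - iy_lo + 1, 0)
    if (sum(nrows) == 0) next
    col_ix <- rep(ix, nrows)
    col_iy <- unlist(lapply(which(nrows > 0), function(k) seq.int(iy_lo[k], iy_hi[k])))
    keys[[i]] <- (col_ix + 2^25) * 2^26 + (col_iy + 2^25)
  }
  length(unique(unlist(keys)))
}

#' Projection-approximation collision cross section
#'
#' The CCS is estimated as the mean shadow (projected) area of the union
#' of atomic spheres over uniformly random orientations. Each
#' orientation's shadow is rasterized on a grid of `resolution` Angstrom
#' with a uniformly random sub-pixel offset, which makes the
#' per-orientation area estimate unbiased; the Monte-Carlo standard error
#' over orientations is reported.
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param radii per-atom radii (Angstrom), a single value, or a
#'   [topology()] with assigned radii.
#' @param n_rotations number of random orientations (default 300).
#' @param seed RNG seed; the same seed gives the same value.
#' @param resolution raster pixel edge in Angstrom.
#' @param method `"grid"` (rasterization, default) or `"mc"`
#'   (points-in-bounding-box Monte Carlo).
#' @param mc_points samples per orientation for `method = "mc"`.
#' @return a [shape_result()] (`value` in Angstrom^2, `uncertainty` = MC
#'   standard error, `n` = `n_rotations`).
#' @export
ccs_projection_approximation <- function(coords, radii, n_rotations = 300,
                                         seed = 1, resolution = 0.2,
                                         method = c("grid", "mc"),
                                         mc_points = 4000) {
  check_coords(coords)
  method <- match.arg(method)
  n <- nrow(coords)
  if (n < 1) stop("need at least one atom")
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  r <- resolve_radii(radii, n)
  areas <- with_preserved_seed(seed, {
    rots <- random_rotations(n_rotations)
    vapply(rots, function(R) {
      p <- coords %*% t(R)
      if (method == "grid") {
        off <- stats::runif(2, 0, resolution)
        npx <- disc_union_pixels(p[, 1], p[, 2], r, resolution, off[1], off[2])
        npx * resolution^2
      } else {
        xlim <- range(p[, 1] - r, p[, 1] + r)
        ylim <- range(p[, 2] - r, p[, 2] + r)
        sx <- stats::runif(mc_points, xlim[1], xlim[2])
        sy <- stats::runif(mc_points, ylim[1], ylim[2])
        covered <- rep(FALSE, mc_points)
        for (i in seq_len(n)) {
          covered <- covered | ((sx - p[i, 1])^2 + (sy - p[i, 2])^2 <= r[i]^2)
        }
        mean(covered) * diff(xlim) * diff(ylim)
      }
    }, numeric(1))
  })
  se <- if (n_rotations > 1) stats::sd(areas) / sqrt(n_rotations) else 0
  shape_result("ccs", mean(areas), se, as.integer(n_rotations))
}

#' Apply an empirical CCS calibration factor
#'
#' The projection approximation systematically underestimates CCS;
#' a multiplicative factor (default 1.14) brings vacuum values on par
#' with ion-mobility experiments. Report tables round the calibrated
#' value to integer Angstrom^2; this function returns full precision.
#'
#' @param ccs_value positive CCS in Angstrom^2 (or a [shape_result()]).
#' @param factor positive multiplicative factor.
#' @return calibrated CCS (numeric).
#' @export
apply_ccs_calibration <- function(ccs_value, factor = 1.14) {
  if (inherits(ccs_value, "shape_result")) ccs_value <- ccs_value$value
  if (!is.finite(factor) || factor <= 0) stop("calibration factor must be positive")
  if (!is.finite(ccs_value) || ccs_value <= 0) stop("CCS value must be positive")
  ccs_value * factor
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's accessible sphere (radius `r_i + probe_radius`) is sampled
#' with a deterministic golden-section spiral point set; a point is
#' exposed when it lies outside every other atom's accessible sphere. The
#' atom contributes its sphere area times the exposed fraction.
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param radii per-atom radii / topology, as in
#'   [ccs_projection_approximation()].
#' @param probe_radius probe sphere radius (Angstrom, conventionally 1.4;
#'   0 gives the van der Waals surface used by the convexity diagnostic).
#' @param n_sphere_points test points per atom (>= 16; default 960).
#' @param residue_index optional per-atom residue ids for the breakdown.
#' @return a [shape_result()] (Angstrom^2) with attributes `per_atom`
#'   and, when `residue_index` is given, `per_residue`.
#' @export
sasa_shrake_rupley <- function(coords, radii, probe_radius = 1.4,
                               n_sphere_points = 960, residue_index = NULL) {
  check_coords(coords)
  n <- nrow(coords)
  if (n < 1) stop("need at least one atom")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 16) stop("n_sphere_points must be >= 16")
  r <- resolve_radii(radii, n) + probe_radius
  pts <- fibonacci_sphere(n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, coords[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      keep <- exposed
      dx <- sp[keep, 1] - coords[j, 1]
      dy <- sp[keep, 2] - coords[j, 2]
      dz <- sp[keep, 3] - coords[j, 3]
      exposed[keep] <- (dx * dx + dy * dy + dz * dz) > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  res <- shape_result("sasa", max(sum(per_atom), .Machine$double.xmin),
                      0, as.integer(n_sphere_points))
  attr(res, "per_atom") <- per_atom
  if (!is.null(residue_index)) {
    attr(res, "per_residue") <- tapply(per_atom, residue_index, sum)
  }
  res
}

#' Van der Waals envelope volume by voxel counting
#'
#' Volume of the union of atomic spheres, counted as voxel centers lying
#' inside any sphere times the voxel volume. Deterministic; converges to
#' the exact union volume as `voxel_size` shrinks.
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param radii per-atom radii / topology.
#' @param voxel_size voxel edge (Angstrom); must not exceed the smallest
#'   radius.
#' @return a [shape_result()] (Angstrom^3).
#' @export
envelope_volume <- function(coords, radii, voxel_size = 0.3) {
  check_coords(coords)
  n <- nrow(coords)
  if (n < 1) stop("need at least one atom")
  r <- resolve_radii(radii, n)
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (voxel_size > min(r)) {
    stop("voxel_size larger than the smallest atomic radius; shrink the grid")
  }
  h <- voxel_size
  keys <- vector("list", n)
  base <- 2^12  # voxel index offset; extents to ~4000 voxels stay exact in doubles
  if (max(abs(range(coords)) + max(r)) / h >= base) {
    stop("structure extent too large for this voxel_size")
  }
  for (i in seq_len(n)) {
    ix <- seq.int(floor((coords[i, 1] - r[i]) / h), floor((coords[i, 1] + r[i]) / h))
    xc <- (ix + 0.5) * h
    dx2 <- (xc - coords[i, 1])^2
    cols <- vector("list", length(ix))
    for (k in seq_along(ix)) {
      rem <- r[i]^2 - dx2[k]
      if (rem <= 0) next
      half <- sqrt(rem)
      iy <- seq.int(ceiling((coords[i, 2] - half) / h - 0.5),
                    floor((coords[i, 2] + half) / h - 0.5))
      if (!length(iy)) next
      yc <- (iy + 0.5) * h
      rem2 <- rem - (yc - coords[i, 2])^2
      ok <- rem2 > 0
      if (!any(ok)) next
      halfz <- sqrt(rem2[ok])
      iz_lo <- ceiling((coords[i, 3] - halfz) / h - 0.5)
      iz_hi <- floor((coords[i, 3] + halfz) / h - 0.5)
      nz <- pmax(iz_hi - iz_lo + 1, 0)
      if (sum(nz) == 0) next
      iy_ok <- iy[ok]
      col_iy <- rep(iy_ok, nz)
      col_iz <- unlist(lapply(which(nz > 0), function(m) seq.int(iz_lo[m], iz_hi[m])))
      cols[[k]] <- ((ix[k] + base) * 2^13 + (col_iy + base)) * 2^13 + (col_iz + base)
    }
    keys[[i]] <- unlist(cols)
  }
  count <- length(unique(unlist(keys)))
  shape_result("volume", count * h^3, 0, as.integer(count))
}

#' Surface-to-shadow convexity diagnostic
#'
#' For a convex body the orientation-averaged projected area equals one
#' quarter of its surface area (Cauchy's surface formula), so the ratio
#' of probe-zero SASA to projection-approximation CCS is 4 for a single
#' sphere and `>= 4` for non-convex bodies. Both quantities are evaluated
#' on the same radii.
#'
#' @param coords `n x 3` coordinates.
#' @param radii per-atom radii / topology.
#' @param seed RNG seed for the CCS orientations.
#' @param n_rotations CCS orientation count.
#' @param n_sphere_points SASA point density.
#' @return the ratio `A_s / Omega` (numeric) with attribute `se` (the MC
#'   standard error propagated from the CCS denominator).
#' @export
convexity_ratio <- function(coords, radii, seed = 1, n_rotations = 300,
                            n_sphere_points = 960) {
  sasa <- sasa_shrake_rupley(coords, radii, probe_radius = 0,
                             n_sphere_points = n_sphere_points)
  ccs <- ccs_projection_approximation(coords, radii, n_rotations = n_rotations,
                                      seed = seed)
  ratio <- sasa$value / ccs$value
  attr(ratio, "se") <- ratio * ccs$uncertainty / ccs$value
  ratio
}

#' Pooled window statistics over replica metric series
#'
#' All frames falling inside the analysis window, pooled across replicas,
#' contribute to a single mean and standard deviation -- the convention
#' for the last-50-ns condition averages.
#'
#' @param series_list list of [metric_series()], one per replica.
#' @param window a [last_ps()] or [last_fraction()] window, or `NULL` for
#'   all frames.
#' @return list with `mean`, `sd`, `n` (pooled frame count).
#' @export
window_stats <- function(series_list, window = NULL) {
  if (!length(series_list)) stop("empty series list")
  pool <- unlist(lapply(series_list, function(s) {
    idx <- if (is.null(window)) seq_along(s$values) else window_frame_indices(s$times, window)
    s$values[idx]
  }))
  if (!length(pool)) stop("empty pooled window")
  list(mean = mean(pool),
       sd = if (length(pool) > 1) stats::sd(pool) else 0,
       n = length(pool))
}

#' Rounded compaction deltas (report-table arithmetic)
#'
#' Percent change of the rehydrated state relative to (a) the vacuum
#' state and (b) the solution control, averaged over field strengths and
#' rounded half away from zero -- the arithmetic behind the report
#' table's signed-integer delta columns:
#' `delta_vs_vacuum = round(mean_f 100 (R_f - V_f) / V_f)` and
#' `delta_vs_solution = round(mean_f 100 (R_f - S) / S)`.
#'
#' @param solution_mean positive scalar, the solution-control mean.
#' @param vacuum_means positive vector of vacuum means, one per field
#'   strength.
#' @param rehydration_means positive vector of rehydration means, same
#'   length and field order as `vacuum_means`.
#' @return list with integer `delta_vs_vacuum_pct` and
#'   `delta_vs_solution_pct`.
#' @export
compaction_deltas <- function(solution_mean, vacuum_means, rehydration_means) {
  if (length(vacuum_means) != length(rehydration_means) || !length(vacuum_means)) {
    stop("vacuum and rehydration means must be non-empty and the same length")
  }
  vals <- c(solution_mean, vacuum_means, rehydration_means)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all condition means must be positive and finite")
  }
  dv <- mean(100 * (rehydration_means - vacuum_means) / vacuum_means)
  ds <- mean(100 * (rehydration_means - solution_mean) / solution_mean)
  list(delta_vs_vacuum_pct = as.integer(round_half_away(dv)),
       delta_vs_solution_pct = as.integer(round_half_away(ds)))
}

#' Shape metric time series for a trajectory
#'
#' Convenience wrapper evaluating one shape metric on (a selection of)
#' every frame, for feeding [window_stats()].
#'
#' @param traj a [trajectory()] whose topology has assigned radii.
#' @param metric `"ccs"`, `"sasa"` or `"volume"`.
#' @param selection atom selection (default `"protein"`).
#' @param ccs_n_rotations,ccs_resolution,ccs_seed CCS settings.
#' @param sasa_probe,sasa_n_points SASA settings.
#' @param voxel_size volume voxel edge.
#' @return a [metric_series()].
#' @export
shape_series <- function(traj, metric = c("ccs", "sasa", "volume"),
                         selection = "protein",
                         ccs_n_rotations = 300, ccs_resolution = 0.2,
                         ccs_seed = 1,
                         sasa_probe = 1.4, sasa_n_points = 960,
                         voxel_size = 0.3) {
  metric <- match.arg(metric)
  idx <- select_atoms(traj$topology, selection)
  r <- resolve_radii(traj$topology, n_atoms(traj$topology))[idx]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- traj$frames[[k]]$coords[idx, , drop = FALSE]
    switch(metric,
      ccs = ccs_projection_approximation(xyz, r, n_rotations = ccs_n_rotations,
                                         seed = ccs_seed + k,
                                         resolution = ccs_resolution)$value,
      sasa = sasa_shrake_rupley(xyz, r, probe_radius = sasa_probe,
                                n_sphere_points = sasa_n_points)$value,
      volume = envelope_volume(xyz, r, voxel_size = voxel_size)$value
    )
  }, numeric(1))
  metric_series(traj$times, vals,
                units = if (metric == "volume") "A^3" else "A^2",
                label = metric)
}
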