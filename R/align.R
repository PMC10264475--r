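# align: Kabsch superposition, the three RMSD reference schemes,
# replica averaging, average structures, and concatenated-replica RMSF.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two matched point sets. Reflections are never
#' returned: the smallest singular direction is sign-corrected so
#' `det(rotation) = +1`, which matters for chiral structures.
#'
#' @param mobile `n x 3` coordinates to move.
#' @param reference `n x 3` target coordinates.
#' @param weights optional non-negative per-point weights (default
#'   uniform). Mass weighting can be passed here; the package default is
#'   uniform weights over the selection.
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length 3), and `rmsd` (Angstrom). The fitted
#'   coordinates are `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  check_coords(mobile, "mobile coordinates")
  check_coords(reference, "reference coordinates")
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("mobile and reference must have equal point counts")
  if (n < 3) stop("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  R0 <- sweep(reference, 2, cr)
  H <- t(M * w) %*% R0
  sv <- svd(H)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) {
    stop("degenerate (collinear) point set: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- M %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - R0)^2)))
  structure(list(
    rotation = R,
    translation = as.numeric(cr - as.numeric(R %*% cm)),
    rmsd = rmsd
  ), class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param sup a `superposition` from [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sup) {
  stopifnot(inherits(sup, "superposition"))
  sweep(coords %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' RMSD reference scheme
#'
#' The three reference choices used to follow rehydration dynamics:
#' \describe{
#'   \item{`first_frame`}{each trajectory against its own initial
#'     structure (how far a replica has moved from its start).}
#'   \item{`external_reference`}{all replicas against one shared frame,
#'     e.g. the final structure of a solution control run (distance from
#'     the native solution state).}
#'   \item{`parent_mapped`}{replica `i` against its own "parent"
#'     reference, e.g. the final frame of replica `i` of the zero-field
#'     rehydration; pairing is by replica index.}
#' }
#'
#' @param variant one of `"first_frame"`, `"external_reference"`,
#'   `"parent_mapped"`.
#' @param reference a [frame()] (or coordinate matrix), required for
#'   `external_reference`.
#' @param references list of frames, one per replica, required for
#'   `parent_mapped`.
#' @return object of class `rmsd_scheme`.
#' @export
rmsd_scheme <- function(variant = c("first_frame", "external_reference", "parent_mapped"),
                        reference = NULL, references = NULL) {
  variant <- match.arg(variant)
  if (variant == "external_reference" && is.null(reference)) {
    stop("external_reference scheme needs a reference frame")
  }
  if (variant == "parent_mapped" && is.null(references)) {
    stop("parent_mapped scheme needs one reference per replica")
  }
  structure(list(variant = variant, reference = reference, references = references),
            class = "rmsd_scheme")
}

#' Per-frame scalar metric series
#'
#' @param times frame times (ps).
#' @param values one scalar per frame.
#' @param units unit label (`"A"`, `"A^2"`, `"A^3"`, `"count"`).
#' @param sd optional pointwise standard deviation (for averaged series).
#' @param label optional description.
#' @return object of class `metric_series`.
#' @export
metric_series <- function(times, values, units = "A", sd = NULL, label = NULL) {
  stopifnot(length(times) == length(values))
  if (!all(is.finite(values))) stop("metric values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 sd = sd, units = units, label = label),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %d points [%s]%s\n", length(x$values), x$units,
              if (is.null(x$label)) "" else paste0(" ", x$label)))
  invisible(x)
}

scheme_reference_coords <- function(scheme, traj, replica_index) {
  ref <- switch(scheme$variant,
    first_frame = traj$frames[[1]],
    external_reference = scheme$reference,
    parent_mapped = {
      if (is.null(replica_index)) {
        stop("parent_mapped scheme needs a replica index")
      }
      if (replica_index > length(scheme$references) ||
          is.null(scheme$references[[replica_index]])) {
        stop("parent_mapped scheme has no reference for replica ", replica_index)
      }
      scheme$references[[replica_index]]
    }
  )
  if (inherits(ref, "frame")) ref$coords else ref
}

#' RMSD time series for one trajectory
#'
#' Each frame's selected atoms are optimally superposed on the scheme's
#' reference (Kabsch, uniform weights) and the residual RMSD recorded.
#'
#' @param traj a [trajectory()].
#' @param scheme an [rmsd_scheme()].
#' @param selection atom selection (default `"calpha"`).
#' @param replica_index replica number, required for `parent_mapped`.
#' @return a [metric_series()] in Angstrom.
#' @export
rmsd_series <- function(traj, scheme, selection = "calpha", replica_index = NULL) {
  stopifnot(inherits(scheme, "rmsd_scheme"))
  idx <- select_atoms(traj$topology, selection)
  ref <- scheme_reference_coords(scheme, traj, replica_index)
  if (nrow(ref) != n_atoms(traj$topology) && nrow(ref) != length(idx)) {
    stop("reference frame does not match the trajectory topology or selection")
  }
  refsel <- if (nrow(ref) == length(idx)) ref else ref[idx, , drop = FALSE]
  vals <- vapply(traj$frames, function(f) {
    kabsch_superpose(f$coords[idx, , drop = FALSE], refsel)$rmsd
  }, numeric(1))
  metric_series(traj$times, vals, units = "A",
                label = paste0("rmsd_", scheme$variant))
}

#' RMSD series for every replica of a set
#'
#' @param rset a [replica_set()].
#' @param scheme an [rmsd_scheme()].
#' @param selection atom selection.
#' @return list of [metric_series()], one per replica.
#' @export
rmsd_replica_series <- function(rset, scheme, selection = "calpha") {
  stopifnot(inherits(rset, "replica_set"))
  lapply(seq_along(rset$replicas), function(i) {
    rmsd_series(rset$replicas[[i]], scheme, selection, replica_index = i)
  })
}

#' Pointwise mean (and sd) over replica series
#'
#' Averages the individual per-replica traces into one mean trace, the
#' way per-replica RMSD trends are reduced to a single curve per
#' condition.
#'
#' @param series_list list of [metric_series()] with identical time grids
#'   (compared with 1e-6 ps tolerance).
#' @return a [metric_series()] whose `values` are pointwise means and
#'   whose `sd` holds pointwise standard deviations.
#' @export
replica_mean_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  n <- length(series_list[[1]]$values)
  times <- series_list[[1]]$times
  for (s in series_list) {
    if (length(s$values) != n) stop("series lengths differ")
    if (max(abs(s$times - times)) > 1e-6) stop("series time grids differ")
  }
  vals <- do.call(rbind, lapply(series_list, `[[`, "values"))
  metric_series(times, colMeans(vals), units = series_list[[1]]$units,
                sd = apply(vals, 2, stats::sd),
                label = series_list[[1]]$label)
}

#' Average structure of a trajectory
#'
#' Every frame is superposed (on `selection`, uniform weights) onto the
#' first frame, the rigid motion applied to all atoms, and coordinates
#' averaged.
#'
#' @param traj a [trajectory()] with at least one frame.
#' @param selection atom selection used for the fit.
#' @return a [frame()] holding the mean coordinates (time `NA`).
#' @export
average_structure <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 1) stop("empty trajectory")
  idx <- select_atoms(traj$topology, selection)
  ref <- traj$frames[[1]]$coords[idx, , drop = FALSE]
  acc <- matrix(0, n_atoms(traj$topology), 3)
  for (f in traj$frames) {
    sup <- kabsch_superpose(f$coords[idx, , drop = FALSE], ref)
    acc <- acc + apply_superposition(f$coords, sup)
  }
  frame(acc / n_frames(traj), time = NA_real_)
}

#' Per-residue RMSF over a concatenated replica set
#'
#' All replica trajectories are concatenated, superposed onto the first
#' frame and averaged to an average structure; every frame is then
#' re-superposed onto that average (one refinement pass) and the
#' root-mean-square deviation of each selected atom about its average
#' position is reported per residue.
#'
#' @param rset a [replica_set()] (or single trajectory).
#' @param selection atom selection; the default `"calpha"` gives the
#'   conventional residue-based RMSF.
#' @return data.frame with `resid`, `resname` and `rmsf` (Angstrom, one
#'   row per protein residue).
#' @export
rmsf_profile <- function(rset, selection = "calpha") {
  trajs <- if (inherits(rset, "replica_set")) rset$replicas else list(rset)
  if (!length(trajs)) stop("empty replica set")
  cat_traj <- concat_trajectories(trajs)
  top <- cat_traj$topology
  idx <- select_atoms(top, selection)
  avg <- average_structure(cat_traj, selection)
  ref <- avg$coords[idx, , drop = FALSE]
  acc <- numeric(length(idx))
  for (f in cat_traj$frames) {
    sup <- kabsch_superpose(f$coords[idx, , drop = FALSE], ref)
    fitted <- apply_superposition(f$coords[idx, , drop = FALSE], sup)
    acc <- acc + rowSums((fitted - ref)^2)
  }
  rmsf_atom <- sqrt(acc / n_frames(cat_traj))
  res_of_atom <- top$atoms$resid[idx]
  per_res <- tapply(rmsf_atom, res_of_atom, mean)
  res <- residue_table(top, protein_only = TRUE)
  res <- res[res$resid %in% as.integer(names(per_res)), c("resid", "resname")]
  res$rmsf <- as.numeric(per_res[as.character(res$resid)])
  rownames(res) <- NULL
  res
}
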