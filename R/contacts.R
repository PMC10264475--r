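# contacts: residue-contact occupancy maps, condition difference maps,
# composite triangle packing, and protein-solvent hydrogen-bond counting.

#' Atom pairs within a distance cutoff
#'
#' Cell-list neighbour search at cutoff resolution (near-linear in atom
#' count); the brute-force all-pairs path is retained for cross-checks.
#'
#' @param coords `n x 3` coordinates.
#' @param cutoff inclusive distance cutoff (Angstrom).
#' @param method `"cell"` or `"brute"`.
#' @return 2-column integer matrix of atom index pairs (i < j) with
#'   pairwise distance `<= cutoff`.
#' @export
close_atom_pairs <- function(coords, cutoff, method = c("cell", "brute")) {
  check_coords(coords)
  method <- match.arg(method)
  n <- nrow(coords)
  c2 <- cutoff^2
  if (method == "brute" || n < 32) {
    if (n < 2) return(matrix(integer(0), ncol = 2))
    d2 <- as.matrix(stats::dist(coords))^2
    hits <- which(upper.tri(d2) & d2 <= c2, arr.ind = TRUE)
    res <- cbind(as.integer(hits[, 1]), as.integer(hits[, 2]))
    return(unname(res[order(res[, 1], res[, 2]), , drop = FALSE]))
  }
  cell <- floor(coords / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(n), key)
  cell_of <- lapply(bins, function(i) cell[i[1], ])
  # half-space of neighbour offsets so each cell pair is visited once
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[
    offsets$dx > 0 |
      (offsets$dx == 0 & offsets$dy > 0) |
      (offsets$dx == 0 & offsets$dy == 0 & offsets$dz >= 0), ]
  out <- list()
  for (b in seq_along(bins)) {
    ci <- cell_of[[b]]
    ai <- bins[[b]]
    for (o in seq_len(nrow(offsets))) {
      nk <- paste(ci[1] + offsets$dx[o], ci[2] + offsets$dy[o], ci[3] + offsets$dz[o])
      aj <- bins[[nk]]
      if (is.null(aj)) next
      same <- offsets$dx[o] == 0 && offsets$dy[o] == 0 && offsets$dz[o] == 0
      pi <- if (same) {
        if (length(ai) < 2) next
        t(utils::combn(ai, 2))
      } else {
        as.matrix(expand.grid(ai, aj))
      }
      d2 <- rowSums((coords[pi[, 1], , drop = FALSE] -
                     coords[pi[, 2], , drop = FALSE])^2)
      hit <- pi[d2 <= c2, , drop = FALSE]
      if (nrow(hit)) {
        out[[length(out) + 1]] <- cbind(pmin(hit[, 1], hit[, 2]),
                                        pmax(hit[, 1], hit[, 2]))
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  res <- unname(unique(do.call(rbind, out)))
  storage.mode(res) <- "integer"
  res[order(res[, 1], res[, 2]), , drop = FALSE]
}

#' Binary residue-contact matrix for one frame
#'
#' Two residues are in contact when the distance between at least one
#' atom of each residue (all atoms, hydrogens included) is less than or
#' equal to the cutoff; the boundary is inclusive. Diagonal entries are 1.
#'
#' @param frm a [frame()] (or coordinate matrix).
#' @param top the matching [topology()]; only protein residues enter the
#'   map.
#' @param cutoff inclusive atom-atom cutoff, default 3.5 Angstrom.
#' @param method neighbour search, `"cell"` or `"brute"`.
#' @return symmetric 0/1 matrix, one row/column per protein residue, with
#'   residue labels as dimnames.
#' @export
contact_matrix_frame <- function(frm, top, cutoff = 3.5, method = c("cell", "brute")) {
  method <- match.arg(method)
  coords <- if (inherits(frm, "frame")) frm$coords else frm
  pidx <- select_atoms(top, "protein")
  res <- residue_table(top, protein_only = TRUE)
  if (nrow(res) < 2) stop("contact maps need at least 2 protein residues")
  counts <- table(top$atoms$resid[pidx])
  if (any(counts == 0)) stop("empty residue in topology")
  xyz <- coords[pidx, , drop = FALSE]
  res_of <- match(top$atoms$resid[pidx], res$resid)
  nres <- nrow(res)
  M <- diag(1, nres)
  pairs <- close_atom_pairs(xyz, cutoff, method)
  if (nrow(pairs)) {
    ri <- res_of[pairs[, 1]]
    rj <- res_of[pairs[, 2]]
    keep <- ri != rj
    M[cbind(ri[keep], rj[keep])] <- 1
    M[cbind(rj[keep], ri[keep])] <- 1
  }
  labels <- paste0(res$resname, res$resid)
  dimnames(M) <- list(labels, labels)
  M
}

#' Contact occupancy map over a windowed replica set
#'
#' The mean of per-frame binary contact matrices, pooled over all frames
#' of all replicas inside the analysis window: entry (i, j) is the
#' fraction of pooled frames in which residues i and j touch.
#'
#' @param rset a [replica_set()].
#' @param window analysis window ([last_ps()] / [last_fraction()]), or
#'   `NULL` for all frames.
#' @param cutoff inclusive atom-atom contact cutoff (Angstrom).
#' @param method neighbour search method.
#' @return object of class `contact_map`: list with `occupancy` (matrix
#'   in `[0, 1]`, unit diagonal), `labels`, `n_frames`.
#' @export
occupancy_map <- function(rset, window = NULL, cutoff = 3.5,
                          method = c("cell", "brute")) {
  stopifnot(inherits(rset, "replica_set"))
  method <- match.arg(method)
  acc <- NULL
  nf <- 0
  for (traj in rset$replicas) {
    tw <- if (is.null(window)) traj else frames_in_window(traj, window)
    for (f in tw$frames) {
      M <- contact_matrix_frame(f, rset$topology, cutoff, method)
      acc <- if (is.null(acc)) M else acc + M
      nf <- nf + 1
    }
  }
  if (nf == 0) stop("empty frame pool")
  occ <- acc / nf
  structure(list(occupancy = occ, labels = rownames(occ), n_frames = nf),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d residues, %d pooled frames, mean occupancy %.3f\n",
              nrow(x$occupancy), x$n_frames, mean(x$occupancy)))
  invisible(x)
}

#' Difference of two occupancy maps
#'
#' Elementwise `map_a - map_b`, in `[-1, 1]`: +1 marks contacts present
#' only in `map_a`, -1 contacts present only in `map_b`; the diagonal is
#' zero and `difference_map(a, b) == -difference_map(b, a)`.
#'
#' @param map_a,map_b [occupancy_map()] results with identical residue
#'   labels.
#' @return object of class `difference_map` with fields `delta` and
#'   `labels`.
#' @export
difference_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  if (!identical(dim(map_a$occupancy), dim(map_b$occupancy)) ||
      !identical(map_a$labels, map_b$labels)) {
    stop("occupancy maps have mismatched shapes or residue labels")
  }
  structure(list(delta = map_a$occupancy - map_b$occupancy,
                 labels = map_a$labels),
            class = "difference_map")
}

#' Pack two difference maps into one lower/upper-triangle composite
#'
#' The strictly lower triangle is taken from `lower_source`, the strictly
#' upper triangle from `upper_source`, and the diagonal is zero -- the
#' two-comparisons-in-one-panel layout used for condition difference
#' figures.
#'
#' @param lower_source,upper_source [difference_map()] objects with
#'   matching labels.
#' @return numeric matrix with the composite packing.
#' @export
composite_triangle_map <- function(lower_source, upper_source) {
  stopifnot(inherits(lower_source, "difference_map"),
            inherits(upper_source, "difference_map"))
  if (!identical(lower_source$labels, upper_source$labels)) {
    stop("difference maps have mismatched residue labels")
  }
  n <- nrow(lower_source$delta)
  M <- matrix(0, n, n, dimnames = list(lower_source$labels, lower_source$labels))
  M[lower.tri(M)] <- lower_source$delta[lower.tri(M)]
  M[upper.tri(M)] <- upper_source$delta[upper.tri(M)]
  M
}

#' Geometric hydrogen-bond criterion
#'
#' @param distance_cutoff donor-acceptor distance cutoff (Angstrom,
#'   default 3.5).
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff (degrees,
#'   default 30) -- the conventional gmx-hbond style criterion.
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(distance_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

# donors: N/O atoms with at least one hydrogen within 1.2 A (covalent
# attachment by distance); returns list(donor = idx, hydrogens = list).
find_donors <- function(coords, top, candidate_idx) {
  a <- top$atoms
  h_idx <- which(a$element == "H")
  polar <- candidate_idx[a$element[candidate_idx] %in% c("N", "O")]
  if (!length(polar) || !length(h_idx)) {
    return(list(donor = integer(0), hydrogens = list()))
  }
  hyd <- lapply(polar, function(d) {
    d2 <- rowSums(sweep(coords[h_idx, , drop = FALSE], 2, coords[d, ])^2)
    h_idx[d2 < 1.2^2]
  })
  keep <- lengths(hyd) > 0
  list(donor = polar[keep], hydrogens = hyd[keep])
}

#' Count protein-solvent hydrogen bonds in one frame
#'
#' Donors are N/O atoms with an attached hydrogen (H within 1.2
#' Angstrom); acceptors are N/O atoms. A donor-acceptor pair (one side
#' protein, the other solvent, in either direction) is counted when the
#' D-A distance is within the cutoff and some attached hydrogen gives an
#' H-D-A angle within the angle cutoff.
#'
#' @param frm a [frame()].
#' @param top the matching [topology()].
#' @param criterion an [hbond_criterion()].
#' @return integer bond count; 0 with a warning when the system has no
#'   solvent.
#' @export
hbond_count_frame <- function(frm, top, criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  coords <- if (inherits(frm, "frame")) frm$coords else frm
  a <- top$atoms
  sol <- which(a$is_solvent)
  if (!length(sol)) {
    warning("no solvent in topology; hydrogen-bond count is 0")
    return(0L)
  }
  pro <- which(!a$is_solvent)
  acceptors <- function(idx) idx[a$element[idx] %in% c("N", "O")]
  count_pairs <- function(donor_side, acceptor_side) {
    dn <- find_donors(coords, top, donor_side)
    acc <- acceptors(acceptor_side)
    if (!length(dn$donor) || !length(acc)) return(0L)
    total <- 0L
    for (k in seq_along(dn$donor)) {
      d <- dn$donor[k]
      da <- sqrt(rowSums(sweep(coords[acc, , drop = FALSE], 2, coords[d, ])^2))
      near <- acc[da <= criterion$distance_cutoff]
      for (av in near) {
        v <- coords[av, ] - coords[d, ]
        ok <- FALSE
        for (hh in dn$hydrogens[[k]]) {
          u <- coords[hh, ] - coords[d, ]
          ang <- acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
          if (ang <= criterion$angle_cutoff) { ok <- TRUE; break }
        }
        if (ok) total <- total + 1L
      }
    }
    total
  }
  count_pairs(pro, sol) + count_pairs(sol, pro)
}

#' Pooled hydrogen-bond statistics over a windowed replica set
#'
#' @param rset a [replica_set()] whose topology includes solvent.
#' @param window analysis window or `NULL`.
#' @param criterion an [hbond_criterion()].
#' @return list with `mean`, `sd`, `n` over the pooled per-frame counts.
#' @export
hbond_series_mean <- function(rset, window = NULL, criterion = hbond_criterion()) {
  stopifnot(inherits(rset, "replica_set"))
  counts <- unlist(lapply(rset$replicas, function(traj) {
    tw <- if (is.null(window)) traj else frames_in_window(traj, window)
    vapply(tw$frames, hbond_count_frame, numeric(1),
           top = rset$topology, criterion = criterion)
  }))
  if (!length(counts)) stop("empty frame pool")
  list(mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0,
       n = length(counts))
}

#' Write a map as a dense text matrix with a labels sidecar
#'
#' @param map a `contact_map`, `difference_map`, or bare matrix.
#' @param path output file; labels go to `<path>.labels`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  M <- if (inherits(map, "contact_map")) map$occupancy
       else if (inherits(map, "difference_map")) map$delta
       else map
  utils::write.table(format(M, digits = 15, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  labels <- rownames(M)
  if (!is.null(labels)) writeLines(labels, paste0(path, ".labels"))
  invisible(path)
}
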