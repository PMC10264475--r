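# trajio: data model for structures, trajectories and replica sets,
# PDB readers/writers (via bio3d), atom selection and radii assignment.

SOLVENT_RESNAMES <- c("HOH", "SOL", "WAT", "TIP4", "TIP3", "TIP")

#' Default van der Waals radii (Angstrom)
#'
#' Bondi-style element radii used for SASA, envelope volume and
#' projection-approximation CCS. Override per call or via
#' [assign_radii()] with a custom table (e.g. loaded from JSON).
#'
#' @format named numeric vector, element symbol -> radius in Angstrom.
#' @export
vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, "F" = 1.47, CL = 1.75, "NA" = 2.27, K = 2.75
)

#' Construct a topology
#'
#' A topology is the per-atom bookkeeping shared by all frames of a
#' trajectory: atom names, elements, residue assignment (0-based internal
#' indices), chain, solvent flag and (once assigned) van der Waals radius.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (0-based integer residue index), `resname`, `chain`,
#'   `is_solvent` (logical) and optionally `radius` (Angstrom, `NA` until
#'   assigned).
#' @return object of class `topology`.
#' @export
topology <- function(atoms) {
  required <- c("serial", "name", "element", "resid", "resname", "chain", "is_solvent")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("topology atoms missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) {
    stop("atom serial numbers must be unique within a topology")
  }
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  atoms$name <- as.character(atoms$name)
  atoms$element <- toupper(as.character(atoms$element))
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  # protein residue atom ranges must be contiguous (residues partition atoms)
  r <- rle(atoms$resid)
  if (anyDuplicated(r$values)) {
    stop("residue atom ranges must be contiguous blocks in atom order")
  }
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<topology> %d atoms, %d residues (%d solvent atoms)\n",
    nrow(a), length(unique(a$resid[!a$is_solvent])), sum(a$is_solvent)
  ))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Residue summary of a topology
#'
#' @param top a [topology()].
#' @param protein_only drop solvent residues.
#' @return data.frame with `resid`, `resname` and the atom index range
#'   (`first`, `last`) of each residue, in sequence order.
#' @export
residue_table <- function(top, protein_only = TRUE) {
  a <- top$atoms
  idx <- seq_len(nrow(a))
  if (protein_only) idx <- idx[!a$is_solvent]
  if (!length(idx)) {
    return(data.frame(resid = integer(), resname = character(),
                      first = integer(), last = integer()))
  }
  sp <- split(idx, a$resid[idx])
  resid <- as.integer(names(sp))
  o <- order(resid)
  data.frame(
    resid = resid[o],
    resname = vapply(sp, function(i) a$resname[i[1]], character(1))[o],
    first = vapply(sp, min, integer(1))[o],
    last = vapply(sp, max, integer(1))[o],
    row.names = NULL
  )
}

#' Construct a single coordinate frame
#'
#' @param coords `n_atoms x 3` numeric matrix, Angstrom.
#' @param time time stamp in picoseconds.
#' @return object of class `frame`.
#' @export
frame <- function(coords, time = 0) {
  check_coords(coords)
  dimnames(coords) <- NULL
  structure(list(coords = coords, time = as.numeric(time)), class = "frame")
}

#' Construct a trajectory
#'
#' @param top a [topology()].
#' @param frames list of [frame()] objects with strictly increasing times
#'   and coordinate counts matching the topology.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(top, frames) {
  stopifnot(inherits(top, "topology"))
  if (!length(frames)) stop("a trajectory needs at least one frame")
  na <- n_atoms(top)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "frame")) stop("frames must be frame objects")
    if (nrow(f$coords) != na) {
      stop(sprintf("frame %d has %d atoms, topology has %d", k, nrow(f$coords), na))
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = top, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = [%g, %g] ps\n",
              length(x$frames), n_atoms(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return a [frame()].
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  traj$frames[[i]]
}

#' Concatenate trajectories sharing a topology
#'
#' Frames are appended in order and re-timed on a uniform grid so the
#' result satisfies the strictly-increasing-time invariant; used for the
#' concatenated-replica RMSF.
#'
#' @param trajs list of trajectories with identical topologies.
#' @return a [trajectory()].
#' @export
concat_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  top <- trajs[[1]]$topology
  for (t in trajs) {
    if (n_atoms(t$topology) != n_atoms(top) ||
        !identical(t$topology$atoms$name, top$atoms$name)) {
      stop("all trajectories must share one topology")
    }
  }
  frames <- unlist(lapply(trajs, function(t) t$frames), recursive = FALSE)
  frames <- lapply(seq_along(frames), function(k) frame(frames[[k]]$coords, time = k - 1))
  trajectory(top, frames)
}

#' Condition label for a replica set
#'
#' @param phase one of `"solution"`, `"vacuum"`, `"rehydration"`.
#' @param field electric-field strength in V/nm (`NA` for solution).
#' @return object of class `condition`.
#' @export
condition <- function(phase = c("solution", "vacuum", "rehydration"),
                      field = NA_real_) {
  phase <- match.arg(phase)
  if (phase != "solution" && !is.finite(field)) {
    stop("vacuum/rehydration conditions need a field strength (V/nm)")
  }
  structure(list(phase = phase, field = as.numeric(field)),
            class = "study_condition")
}

#' @export
format.study_condition <- function(x, ...) {
  if (x$phase == "solution") "solution" else sprintf("%s@%.1fV/nm", x$phase, x$field)
}

#' @export
print.study_condition <- function(x, ...) {
  cat("<condition>", format(x), "\n")
  invisible(x)
}

#' Construct a replica set
#'
#' A labelled collection of replica trajectories sharing one topology;
#' the study design uses five replicas per condition.
#'
#' @param replicas list of trajectories.
#' @param cond a [condition()].
#' @return object of class `replica_set`.
#' @export
replica_set <- function(replicas, cond) {
  stopifnot(inherits(cond, "study_condition"), length(replicas) >= 1)
  top <- replicas[[1]]$topology
  for (t in replicas) {
    if (!identical(t$topology$atoms$name, top$atoms$name) ||
        !identical(t$topology$atoms$resid, top$atoms$resid)) {
      stop("all replicas must share one topology")
    }
  }
  structure(list(replicas = replicas, condition = cond, topology = top),
            class = "replica_set")
}

#' @export
print.replica_set <- function(x, ...) {
  cat(sprintf("<replica_set> %s: %d replicas, %d atoms\n",
              format(x$condition), length(x$replicas), n_atoms(x$topology)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Element inference and radii

infer_element <- function(name, elesy = "") {
  elesy <- toupper(trimws(elesy))
  if (nzchar(elesy)) return(elesy)
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  if (!nzchar(nm)) stop("cannot infer element from atom name '", name, "'")
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN")) return(two)
  substr(nm, 1, 1)
}

#' Assign van der Waals radii to a topology
#'
#' @param top a [topology()].
#' @param table named numeric vector element -> radius (Angstrom); defaults
#'   to [vdw_radii].
#' @param overrides optional named vector merged over `table`.
#' @return the topology with its `radius` column filled; unknown elements
#'   are a hard error.
#' @export
assign_radii <- function(top, table = vdw_radii, overrides = NULL) {
  if (any(table <= 0)) stop("all radii must be positive")
  if (!is.null(overrides)) {
    if (any(overrides <= 0)) stop("all radii must be positive")
    table[names(overrides)] <- overrides
  }
  el <- top$atoms$element
  if (any(!nzchar(el))) stop("topology has atoms with empty element symbols")
  r <- unname(table[el])
  if (any(is.na(r))) {
    stop("no radius for element(s): ", paste(unique(el[is.na(r)]), collapse = ", "))
  }
  top$atoms$radius <- r
  top
}

#' Load a radii table from JSON
#'
#' @param path JSON file mapping element symbols to radii in Angstrom.
#' @return named numeric vector.
#' @export
read_radii_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- unlist(x)
  if (any(r <= 0)) stop("all radii must be positive")
  names(r) <- toupper(names(r))
  r
}

# ---------------------------------------------------------------------------
# PDB I/O (bio3d-backed, with stricter error contracts)

# Scan raw PDB lines; error with a line number on malformed ATOM/HETATM
# records, return per-MODEL atom counts.
validate_pdb_lines <- function(lines, path) {
  atom_like <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_like)) stop("no ATOM/HETATM records in '", path, "'")
  bad <- which(atom_like & nchar(lines) < 54)
  if (length(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d of '%s'", bad[1], path))
  }
  coords_txt <- substr(lines[atom_like], 31, 54)
  ok <- grepl("^[-+0-9. ]+$", coords_txt)
  if (!all(ok)) {
    stop(sprintf("malformed coordinates at line %d of '%s'",
                 which(atom_like)[!ok][1], path))
  }
  model_starts <- grepl("^MODEL", lines)
  if (!any(model_starts)) {
    return(sum(atom_like))
  }
  model_id <- cumsum(model_starts)
  counts <- tapply(atom_like[model_id > 0], model_id[model_id > 0], sum)
  as.integer(counts)
}

topology_from_bio3d <- function(pdb, solvent_names = SOLVENT_RESNAMES) {
  a <- pdb$atom
  element <- vapply(seq_len(nrow(a)), function(i) {
    infer_element(a$elety[i], if ("elesy" %in% names(a)) a$elesy[i] else "")
  }, character(1))
  # internal residue index: 0-based, in file order
  key <- paste(a$chain, a$resno, a$insert %||% "", sep = "|")
  resid <- match(key, unique(key)) - 1L
  topology(data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = element,
    resid = resid,
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    is_solvent = trimws(a$resid) %in% solvent_names,
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL if several), infers elements
#' from columns 77-78 falling back to atom-name heuristics, and flags
#' water residues (`r SOLVENT_RESNAMES`) as solvent.
#'
#' @param path PDB file.
#' @param solvent_names residue names treated as solvent.
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, solvent_names = SOLVENT_RESNAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  validate_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  top <- topology_from_bio3d(pdb, solvent_names)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(topology = top, frame = frame(xyz, time = 0))
}

#' Write a structure to a PDB file
#'
#' @param top a [topology()].
#' @param frm a [frame()] (or a bare coordinate matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, frm, path) {
  coords <- if (inherits(frm, "frame")) frm$coords else frm
  write_models(top, list(coords), path)
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL block. Frame times are synthesized from `t0` and
#' `dt` (ps) since PDB carries no time stamps.
#'
#' @param path multi-model PDB file.
#' @param top optional [topology()] the frames must match; read from the
#'   file when `NULL`.
#' @param dt frame spacing in ps.
#' @param t0 time of the first frame in ps.
#' @param solvent_names residue names treated as solvent.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top = NULL, dt = 1, t0 = 0,
                            solvent_names = SOLVENT_RESNAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  counts <- validate_pdb_lines(lines, path)
  if (length(counts) > 1 && length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("MODEL %d of '%s' has %d atoms, expected %d",
                 bad, path, counts[bad], counts[1]))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  ftop <- topology_from_bio3d(pdb, solvent_names)
  if (!is.null(top)) {
    if (n_atoms(top) != n_atoms(ftop)) {
      stop(sprintf("'%s' has %d atoms per MODEL, topology has %d",
                   path, n_atoms(ftop), n_atoms(top)))
    }
    ftop <- top
  }
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(k) {
    frame(matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE), time = t0 + (k - 1) * dt)
  })
  trajectory(ftop, frames)
}

write_models <- function(top, coord_list, path) {
  a <- top$atoms
  xyz <- do.call(rbind, lapply(coord_list, function(m) as.vector(t(m))))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(a$is_solvent, "HETATM", "ATOM"),
    resno = a$resid + 1L, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, elesy = a$element
  )
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_models(traj$topology, lapply(traj$frames, `[[`, "coords"), path)
}

# ---------------------------------------------------------------------------
# Selections

#' Resolve an atom selection
#'
#' Named predicates: `protein` (non-solvent), `calpha` (one CA per protein
#' residue -- the RMSD/RMSF selection), `heavy` (protein non-hydrogen),
#' `solvent`, `all`; or an explicit integer index vector.
#'
#' @param top a [topology()].
#' @param selection predicate name or integer indices.
#' @return sorted unique integer atom indices (1-based).
#' @export
select_atoms <- function(top, selection = "calpha") {
  a <- top$atoms
  if (is.numeric(selection)) {
    idx <- sort(unique(as.integer(selection)))
    if (length(idx) && (min(idx) < 1 || max(idx) > nrow(a))) {
      stop("explicit selection indices out of topology bounds")
    }
    return(idx)
  }
  selection <- match.arg(selection, c("protein", "calpha", "heavy", "solvent", "all"))
  idx <- switch(selection,
    all = seq_len(nrow(a)),
    protein = which(!a$is_solvent),
    solvent = which(a$is_solvent),
    heavy = which(!a$is_solvent & a$element != "H"),
    calpha = {
      ca <- which(!a$is_solvent & a$name == "CA")
      res <- residue_table(top, protein_only = TRUE)
      missing <- setdiff(res$resid, a$resid[ca])
      if (length(missing)) {
        stop("residue(s) lacking a CA atom: ",
             paste(missing, collapse = ", "))
      }
      ca
    }
  )
  sort(unique(idx))
}

# ---------------------------------------------------------------------------
# Analysis windows

#' Window: last `duration_ps` picoseconds of a trajectory
#' @param duration_ps window length in ps.
#' @return window object.
#' @export
last_ps <- function(duration_ps) {
  stopifnot(duration_ps > 0)
  structure(list(type = "last_ps", value = duration_ps), class = "traj_window")
}

#' Window: last fraction of a trajectory's frames
#' @param fraction in (0, 1]; `last_fraction(0.25)` on a 200 ns run is the
#'   conventional last-50-ns analysis window.
#' @return window object.
#' @export
last_fraction <- function(fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  structure(list(type = "last_fraction", value = fraction), class = "traj_window")
}

window_frame_indices <- function(times, window) {
  stopifnot(inherits(window, "traj_window"))
  n <- length(times)
  if (window$type == "last_ps") {
    span <- times[n] - times[1]
    if (window$value > span && n > 1) {
      stop(sprintf("window of %g ps exceeds trajectory span of %g ps",
                   window$value, span))
    }
    idx <- which(times > times[n] - window$value)
  } else {
    k <- ceiling(window$value * n)
    idx <- seq.int(n - k + 1, n)
  }
  if (!length(idx)) stop("empty analysis window")
  idx
}

#' Restrict a trajectory to an analysis window
#'
#' @param traj a [trajectory()].
#' @param window a [last_ps()] or [last_fraction()] window. Duration
#'   windows keep frames with `time > t_end - duration` and refuse windows
#'   longer than the trajectory; fraction windows keep the last
#'   `ceiling(f * n)` frames.
#' @return a [trajectory()] view over the retained frames.
#' @export
frames_in_window <- function(traj, window) {
  idx <- window_frame_indices(traj$times, window)
  trajectory(traj$topology, traj$frames[idx])
}
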