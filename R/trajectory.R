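#' Construct a trajectory
#'
#' A trajectory is the package's conformational-ensemble container: an
#' ordered atom topology plus an `F x A x 3` coordinate array in angstroms.
#' Single structures are one-frame trajectories.
#'
#' @param topology data frame with one row per atom and columns
#'   `atom_name`, `residue_number` (1-based), `residue_name`, `chain_id`,
#'   `element`, and optionally `record` (`"ATOM"` or `"HETATM"`).
#' @param coordinates numeric array `F x A x 3` (or an `A x 3` matrix for a
#'   single frame), in angstroms.
#' @param frame_spacing time between stored frames, arbitrary units;
#'   metadata only (used to convert lag times to frames).
#' @return An object of class `ens_trajectory`.
#' @export
trajectory <- function(topology, coordinates, frame_spacing = 1) {
  if (is.matrix(coordinates)) {
    coordinates <- array(coordinates, dim = c(1L, nrow(coordinates), 3L))
  }
  stopifnot(is.data.frame(topology), length(dim(coordinates)) == 3L)
  required <- c("atom_name", "residue_number", "residue_name", "chain_id", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0L) {
    ens_stop("invalid_argument",
             paste0("topology lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(topology$record)) topology$record <- "ATOM"
  if (dim(coordinates)[2] != nrow(topology)) {
    ens_stop("topology_error", sprintf(
      "coordinate array has %d atoms but topology has %d rows",
      dim(coordinates)[2], nrow(topology)))
  }
  if (dim(coordinates)[3] != 3L) {
    ens_stop("invalid_argument", "third coordinate dimension must be 3 (x, y, z)")
  }
  if (dim(coordinates)[1] < 1L) {
    ens_stop("invalid_argument", "trajectory must contain at least one frame")
  }
  if (!all(is.finite(coordinates))) {
    ens_stop("invalid_argument", "coordinates must be finite")
  }
  structure(
    list(topology = topology, coordinates = coordinates,
         frame_spacing = as.numeric(frame_spacing)),
    class = "ens_trajectory"
  )
}

#' @export
print.ens_trajectory <- function(x, ...) {
  cat(sprintf("<ens_trajectory> %d frame(s), %d atoms, %d residue(s), frame spacing %g\n",
              n_frames(x), n_atoms(x),
              length(unique(x$topology$residue_number)), x$frame_spacing))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `ens_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coordinates)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coordinates)[2]

#' Extract one frame as a single-frame trajectory
#' @param traj an `ens_trajectory`.
#' @param i frame index (1-based).
#' @return one-frame `ens_trajectory`.
#' @export
get_frame <- function(traj, i) {
  i <- check_count(i, "i")
  if (i > n_frames(traj)) {
    ens_stop("invalid_argument", sprintf("frame %d out of range (F = %d)", i, n_frames(traj)))
  }
  trajectory(traj$topology, frame_coords(traj, i), traj$frame_spacing)
}

# A x 3 coordinate matrix of frame i
frame_coords <- function(traj, i) {
  matrix(traj$coordinates[i, , ], ncol = 3L)
}

#' Subsample a trajectory by a fixed stride
#'
#' Keeps frames 1, 1+stride, 1+2*stride, ... and scales the frame-spacing
#' metadata accordingly. Mirrors the practice of striding a densely saved
#' trajectory before an O(F^2) clustering step.
#'
#' @param traj an `ens_trajectory`.
#' @param stride positive integer stride.
#' @return the subsampled `ens_trajectory`, with attribute `frame_indices`
#'   giving the kept frames' indices in the parent trajectory.
#' @export
subsample <- function(traj, stride) {
  stride <- check_count(stride, "stride")
  keep <- seq(1L, n_frames(traj), by = stride)
  out <- trajectory(traj$topology,
                    traj$coordinates[keep, , , drop = FALSE],
                    traj$frame_spacing * stride)
  attr(out, "frame_indices") <- keep
  out
}

#' Atom selection
#'
#' An ordered, strictly increasing set of 1-based atom indices with a
#' provenance label. Selections are the feature basis for clustering.
#'
#' @param indices strictly increasing 1-based atom indices.
#' @param label one of `"backbone"`, `"c-alpha"`, `"binding-atoms"`,
#'   `"custom"`.
#' @param n_total optional topology size for bounds checking.
#' @return an `ens_selection`.
#' @export
atom_selection <- function(indices, label = "custom", n_total = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) {
    ens_stop("empty_selection", "atom selection is empty")
  }
  if (any(diff(indices) <= 0L) || any(indices < 1L)) {
    ens_stop("invalid_argument", "selection indices must be strictly increasing and >= 1")
  }
  if (!is.null(n_total) && any(indices > n_total)) {
    ens_stop("invalid_argument", "selection indices exceed topology size")
  }
  label <- match.arg(label, c("backbone", "c-alpha", "binding-atoms", "custom"))
  structure(list(indices = indices, label = label), class = "ens_selection")
}

#' @export
print.ens_selection <- function(x, ...) {
  cat(sprintf("<ens_selection> %s, %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

#' Export / import an atom selection as a whitespace-separated index list
#'
#' @param sel an `ens_selection`.
#' @param path text file path; indices are written 1-based.
#' @param label label to attach on read (default `"custom"`).
#' @return `path` invisibly / the restored `ens_selection`.
#' @export
write_atom_selection <- function(sel, path) {
  stopifnot(inherits(sel, "ens_selection"))
  writeLines(paste(sel$indices, collapse = " "), path)
  invisible(path)
}

#' @rdname write_atom_selection
#' @export
read_atom_selection <- function(path, label = "custom") {
  atom_selection(as.integer(strsplit(trimws(readLines(path)[1]), "\\s+")[[1]]),
                 label = label)
}

#' Select atoms by name class
#'
#' `backbone` selects atoms named N, CA, C, O; `c-alpha` selects CA atoms.
#' Only `ATOM` records (the receptor) are considered.
#'
#' @param traj an `ens_trajectory`.
#' @param mode `"backbone"` or `"c-alpha"`.
#' @return an `ens_selection`.
#' @export
select_atoms <- function(traj, mode = c("backbone", "c-alpha")) {
  mode <- match.arg(mode)
  names_wanted <- if (mode == "backbone") c("N", "CA", "C", "O") else "CA"
  top <- traj$topology
  idx <- which(top$atom_name %in% names_wanted & top$record == "ATOM")
  if (length(idx) == 0L) {
    ens_stop("empty_selection", sprintf("no atoms match mode '%s'", mode))
  }
  atom_selection(idx, label = mode, n_total = n_atoms(traj))
}

#' Select binding-site atoms by distance to ligand poses
#'
#' Returns the union, over all ligand poses, of receptor atoms whose
#' minimum Euclidean distance to any ligand atom is at most `cutoff`
#' (inclusive). This is the "binding atoms" feature basis used to focus
#' clustering on binding-site fluctuations (CBA).
#'
#' @param structure a single-frame `ens_trajectory` (the receptor).
#' @param ligand_poses ligand coordinates: an `L x 3` matrix (one pose) or
#'   a `P x L x 3` array / list of `L x 3` matrices (several poses), in
#'   angstroms.
#' @param cutoff distance cutoff in angstroms (default 2.0, inclusive).
#' @return an `ens_selection` labelled `binding-atoms`.
#' @export
select_binding_atoms <- function(structure, ligand_poses, cutoff = 2.0) {
  cutoff <- check_number(cutoff, "cutoff")
  if (cutoff <= 0) ens_stop("invalid_argument", "`cutoff` must be > 0")
  poses <- normalize_poses(ligand_poses)
  rec <- frame_coords(structure, 1L)
  hit <- rep(FALSE, nrow(rec))
  for (pose in poses) {
    # min distance from each receptor atom to any ligand atom
    d2 <- outer(rowSums(rec^2), rowSums(pose^2), "+") - 2 * rec %*% t(pose)
    hit <- hit | (sqrt(pmax(apply(d2, 1L, min), 0)) <= cutoff + 1e-12)
  }
  if (!any(hit)) {
    ens_stop("empty_selection",
             "no receptor atom within cutoff of any ligand pose (ligand placed away from receptor?)")
  }
  atom_selection(which(hit), label = "binding-atoms", n_total = n_atoms(structure))
}

normalize_poses <- function(ligand_poses) {
  if (is.list(ligand_poses)) {
    poses <- ligand_poses
  } else if (is.matrix(ligand_poses)) {
    poses <- list(ligand_poses)
  } else if (is.array(ligand_poses) && length(dim(ligand_poses)) == 3L) {
    poses <- lapply(seq_len(dim(ligand_poses)[1]), function(p) {
      matrix(ligand_poses[p, , ], ncol = 3L)
    })
  } else {
    ens_stop("invalid_argument", "ligand_poses must be a matrix, 3-d array, or list of matrices")
  }
  if (length(poses) == 0L) ens_stop("invalid_argument", "need at least one ligand pose")
  for (pose in poses) {
    if (!is.matrix(pose) || ncol(pose) != 3L || nrow(pose) < 1L) {
      ens_stop("invalid_argument", "each ligand pose must be an L x 3 matrix")
    }
  }
  poses
}

# check that two trajectories / frames share a topology
check_same_topology <- function(a, b) {
  ta <- a$topology; tb <- b$topology
  same <- nrow(ta) == nrow(tb) &&
    identical(ta$atom_name, tb$atom_name) &&
    identical(ta$residue_number, tb$residue_number)
  if (!same) ens_stop("topology_error", "structures do not share a topology")
  invisible(TRUE)
}
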