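#' Read a multi-model PDB file as a trajectory
#'
#' Parses fixed-column `ATOM`/`HETATM` records; `MODEL`/`ENDMDL` blocks
#' become frames in file order. A file without `MODEL` records yields a
#' one-frame trajectory. All models must contain the same atoms.
#'
#' @param path path to a PDB file.
#' @param frame_spacing frame-spacing metadata attached to the result.
#' @return an `ens_trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_spacing = 1) {
  if (!file.exists(path)) {
    ens_stop("invalid_argument", sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) {
    ens_stop("format_error", sprintf("no ATOM/HETATM records in %s", path))
  }
  # assign a model id to every line; 1 if no MODEL records at all
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  mids <- model_id[atom_lines]
  if (any(mids == 0L)) {
    ens_stop("format_error", "ATOM records found before the first MODEL record")
  }
  models <- split(atom_lines, mids)
  n_per <- lengths(models)
  if (length(unique(n_per)) != 1L) {
    bad <- names(models)[which(n_per != n_per[[1]])[1]]
    ens_stop("format_error", sprintf(
      "inconsistent atom count across models: model %s has %d atoms, model %s has %d",
      names(models)[1], n_per[[1]], bad, n_per[[which(names(models) == bad)]]))
  }
  parse_block <- function(lns) {
    txt <- lines[lns]
    x <- suppressWarnings(as.numeric(substr(txt, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(txt, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(txt, 47L, 54L)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad) > 0L) {
      ens_stop("format_error", sprintf(
        "unparseable coordinates at line %d of %s", lns[bad[1]], path))
    }
    cbind(x, y, z)
  }
  coords_list <- lapply(models, parse_block)
  first <- lines[models[[1]]]
  resnum <- suppressWarnings(as.integer(substr(first, 23L, 26L)))
  if (anyNA(resnum)) {
    ens_stop("format_error", sprintf(
      "unparseable residue number at line %d of %s",
      models[[1]][which(is.na(resnum))[1]], path))
  }
  topology <- data.frame(
    atom_name = trimws(substr(first, 13L, 16L)),
    residue_number = resnum,
    residue_name = trimws(substr(first, 18L, 20L)),
    chain_id = trimws(substr(first, 22L, 22L)),
    element = trimws(substr(first, 77L, 78L)),
    record = trimws(substr(first, 1L, 6L)),
    stringsAsFactors = FALSE
  )
  # fall back to first character of the atom name when element column empty
  blank <- topology$element == ""
  topology$element[blank] <- substr(gsub("[0-9]", "", topology$atom_name[blank]), 1L, 1L)
  A <- nrow(topology)
  coords <- array(0, dim = c(length(coords_list), A, 3L))
  for (f in seq_along(coords_list)) coords[f, , ] <- coords_list[[f]]
  trajectory(topology, coords, frame_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-column `ATOM`/`HETATM` records; multi-frame trajectories are
#' wrapped in `MODEL`/`ENDMDL` blocks. Coordinates are written with three
#' decimals (PDB precision), so a write-read-write cycle is byte-stable
#' after the first write.
#'
#' @param traj an `ens_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  top <- traj$topology
  name4 <- ifelse(nchar(top$atom_name) >= 4L,
                  substr(top$atom_name, 1L, 4L),
                  sprintf(" %-3s", top$atom_name))
  fmt_frame <- function(xyz) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            top$record, seq_len(nrow(top)), name4, top$residue_name,
            top$chain_id, top$residue_number,
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element)
  }
  F <- n_frames(traj)
  out <- character(0)
  if (F == 1L) {
    out <- fmt_frame(frame_coords(traj, 1L))
  } else {
    for (f in seq_len(F)) {
      out <- c(out, sprintf("MODEL     %4d", f), fmt_frame(frame_coords(traj, f)), "ENDMDL")
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write ligand poses as a multi-model HETATM PDB file
#'
#' @param poses `L x 3` matrix, `P x L x 3` array, or list of `L x 3`
#'   matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ligand_poses <- function(poses, path) {
  poses <- normalize_poses(poses)
  L <- nrow(poses[[1]])
  top <- data.frame(
    atom_name = sprintf("C%d", seq_len(L)),
    residue_number = 1L, residue_name = "LIG", chain_id = "L",
    element = "C", record = "HETATM", stringsAsFactors = FALSE
  )
  coords <- array(0, dim = c(length(poses), L, 3L))
  for (p in seq_along(poses)) coords[p, , ] <- poses[[p]]
  write_multimodel_pdb(trajectory(top, coords), path)
}
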