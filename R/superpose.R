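# Kabsch superposition and the ensemble diagnostics built on it
# (pairwise RMSD, RMSF, aligned position features).

# Core least-squares rotation: returns list(R, mu_m, mu_r, rmsd) mapping
# row-vector coordinates x -> (x - mu_m) %*% R + mu_r, with R proper.
kabsch_core <- function(ref_fit, mob_fit, check = TRUE) {
  if (nrow(ref_fit) < 3L) {
    ens_stop("geometry_error", "superposition requires at least 3 fit atoms")
  }
  mu_r <- colMeans(ref_fit)
  mu_m <- colMeans(mob_fit)
  Q <- sweep(ref_fit, 2L, mu_r)
  P <- sweep(mob_fit, 2L, mu_m)
  if (check) {
    # collinear fit atoms leave the rotation about the common axis free
    for (M in list(Q, P)) {
      sv <- svd(M, nu = 0L, nv = 0L)$d
      if (sv[2] <= 1e-8 * max(sv[1], 1e-30)) {
        ens_stop("geometry_error", "fit atoms are (nearly) collinear; superposition is degenerate")
      }
    }
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  ssd <- sum(P^2) + sum(Q^2) - 2 * (s$d[1] + s$d[2] + d * s$d[3])
  list(R = R, mu_m = mu_m, mu_r = mu_r,
       rmsd = sqrt(max(ssd, 0) / nrow(ref_fit)))
}

#' Kabsch superposition of one structure onto another
#'
#' Finds the proper rotation and translation minimizing the RMSD over the
#' fit selection, applies the transform to all atoms of `mobile`, and
#' reports the post-fit RMSD over the selection.
#'
#' @param reference `A x 3` coordinate matrix (angstroms).
#' @param mobile `A x 3` coordinate matrix to superpose.
#' @param fit_selection an `ens_selection` or integer vector of 1-based
#'   atom indices; defaults to all atoms.
#' @return list with `coordinates` (all atoms of `mobile`, transformed),
#'   `rmsd` (angstroms, over the fit selection), `rotation` (3 x 3 proper
#'   rotation) and `translation`.
#' @export
kabsch_superpose <- function(reference, mobile, fit_selection = NULL) {
  stopifnot(is.matrix(reference), is.matrix(mobile),
            ncol(reference) == 3L, ncol(mobile) == 3L,
            nrow(reference) == nrow(mobile))
  fit <- selection_indices(fit_selection, nrow(reference))
  k <- kabsch_core(reference[fit, , drop = FALSE], mobile[fit, , drop = FALSE])
  coords <- sweep(mobile, 2L, k$mu_m) %*% k$R
  coords <- sweep(coords, 2L, k$mu_r, "+")
  list(coordinates = coords, rmsd = k$rmsd, rotation = k$R,
       translation = k$mu_r - as.vector(k$mu_m %*% k$R))
}

selection_indices <- function(selection, n_total) {
  if (is.null(selection)) return(seq_len(n_total))
  idx <- if (inherits(selection, "ens_selection")) selection$indices else as.integer(selection)
  if (length(idx) == 0L) ens_stop("empty_selection", "selection is empty")
  if (any(idx < 1L | idx > n_total)) {
    ens_stop("invalid_argument", "selection indices out of range")
  }
  idx
}

# Coerce a multi-frame trajectory or a list of single-frame trajectories
# into a list of A x 3 matrices sharing one topology.
ensemble_frames <- function(structures) {
  if (inherits(structures, "ens_trajectory")) {
    return(lapply(seq_len(n_frames(structures)), function(i) frame_coords(structures, i)))
  }
  stopifnot(is.list(structures), length(structures) >= 1L)
  for (s in structures) {
    if (!inherits(s, "ens_trajectory")) {
      ens_stop("invalid_argument", "structures must be ens_trajectory objects")
    }
    check_same_topology(structures[[1]], s)
  }
  lapply(structures, function(s) frame_coords(s, 1L))
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Entry (i, j) is the RMSD over `selection` after Kabsch superposition of
#' structure j onto structure i. The matrix is symmetric with a zero
#' diagonal.
#'
#' @param structures a multi-frame `ens_trajectory` or list of single-frame
#'   trajectories sharing a topology.
#' @param selection an `ens_selection` (default: all atoms).
#' @param structure_ids optional labels for the rows/columns.
#' @return symmetric `S x S` numeric matrix (angstroms).
#' @export
pairwise_rmsd <- function(structures, selection = NULL, structure_ids = NULL) {
  frames <- ensemble_frames(structures)
  S <- length(frames)
  if (S < 2L) ens_stop("invalid_argument", "need at least 2 structures")
  n_total <- nrow(frames[[1]])
  fit <- selection_indices(selection, n_total)
  centered <- lapply(frames, function(x) {
    xf <- x[fit, , drop = FALSE]
    sweep(xf, 2L, colMeans(xf))
  })
  norms <- vapply(centered, function(x) sum(x^2), numeric(1))
  D <- matrix(0, S, S)
  for (i in seq_len(S - 1L)) {
    Pi <- centered[[i]]
    for (j in seq(i + 1L, S)) {
      s <- svd(crossprod(centered[[j]], Pi), nu = 0L, nv = 0L)$d
      dd <- sign_det3(centered[[j]], Pi)
      ssd <- norms[i] + norms[j] - 2 * (s[1] + s[2] + dd * s[3])
      D[i, j] <- D[j, i] <- sqrt(max(ssd, 0) / length(fit))
    }
  }
  if (is.null(structure_ids)) structure_ids <- sprintf("s%d", seq_len(S))
  dimnames(D) <- list(structure_ids, structure_ids)
  D
}

# sign of det of the cross-covariance between two centered coordinate sets
sign_det3 <- function(P, Q) {
  d <- sign(det(crossprod(P, Q)))
  if (d == 0) 1 else d
}

#' Root-mean-square fluctuation per atom
#'
#' Structures are superposed (over `selection`) onto the ensemble mean,
#' obtained by one iteration starting from the first structure as the
#' reference; RMSF is then the per-atom root-mean-square deviation from
#' the mean of the aligned coordinates.
#'
#' @inheritParams pairwise_rmsd
#' @return numeric vector of per-atom RMSF values (angstroms), one per
#'   topology atom.
#' @export
rmsf <- function(structures, selection = NULL) {
  frames <- ensemble_frames(structures)
  if (length(frames) < 2L) ens_stop("invalid_argument", "need at least 2 structures")
  n_total <- nrow(frames[[1]])
  fit <- selection_indices(selection, n_total)
  align_all <- function(ref) {
    lapply(frames, function(x) {
      k <- kabsch_core(ref[fit, , drop = FALSE], x[fit, , drop = FALSE], check = FALSE)
      sweep(sweep(x, 2L, k$mu_m) %*% k$R, 2L, k$mu_r, "+")
    })
  }
  pass1 <- align_all(frames[[1]])
  mean1 <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- align_all(mean1)
  mean2 <- Reduce(`+`, pass2) / length(pass2)
  dev2 <- lapply(pass2, function(x) rowSums((x - mean2)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}

#' Aligned position features
#'
#' Superposes every frame onto a reference frame over `selection` (removing
#' rigid-body motion, so the features reflect internal motion only) and
#' flattens the selected atoms' coordinates to one row per frame
#' (x1, y1, z1, x2, ...).
#'
#' @param traj an `ens_trajectory`.
#' @param selection an `ens_selection`.
#' @param reference_frame 1-based frame index used as the alignment
#'   reference (default 1).
#' @return `F x 3|selection|` numeric matrix with attributes
#'   `frame_spacing` and `feature_labels`.
#' @export
featurize_positions <- function(traj, selection, reference_frame = 1L) {
  fit <- selection_indices(selection, n_atoms(traj))
  reference_frame <- check_count(reference_frame, "reference_frame")
  ref <- frame_coords(traj, reference_frame)[fit, , drop = FALSE]
  F <- n_frames(traj)
  X <- matrix(0, F, 3L * length(fit))
  for (f in seq_len(F)) {
    x <- frame_coords(traj, f)[fit, , drop = FALSE]
    k <- kabsch_core(ref, x, check = FALSE)
    aligned <- sweep(sweep(x, 2L, k$mu_m) %*% k$R, 2L, k$mu_r, "+")
    X[f, ] <- as.vector(t(aligned))
  }
  attr(X, "frame_spacing") <- traj$frame_spacing
  attr(X, "feature_labels") <- as.vector(t(outer(
    fit, c("x", "y", "z"), function(i, c) sprintf("atom%d_%s", i, c))))
  X
}
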