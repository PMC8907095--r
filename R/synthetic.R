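# Synthetic generators: toy proteins, Markov-switching conformational
# trajectories, and planted-affinity docking score matrices. These stand in
# for MD trajectories and docking-engine output so that every downstream
# stage (featurization, TICA/PCA, clustering, ranking) is testable offline.

#' Specification of a synthetic metastable trajectory
#'
#' The generator emulates metastable MD: a discrete Markov chain over
#' conformational states, where each state displaces a designated
#' binding-loop atom subset, plus isotropic Gaussian coordinate noise and
#' (optionally) a random rigid-body rotation/translation per frame.
#'
#' @param n_states number of metastable states (>= 1).
#' @param n_frames number of frames to simulate (>= 1).
#' @param transition_matrix row-stochastic `n_states x n_states` matrix
#'   (rows sum to 1, entries >= 0).
#' @param state_displacement displacement magnitude (angstroms) applied to
#'   the binding-loop atoms in each non-reference state.
#' @param noise_sigma isotropic per-coordinate Gaussian jitter in
#'   angstroms (non-negative).
#' @param rigid_body_jitter logical; apply a random proper rotation and
#'   translation to every frame.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return a validated `ens_trajectory_spec` list.
#' @export
trajectory_spec <- function(n_states = 3L, n_frames = 1000L,
                            transition_matrix = NULL,
                            state_displacement = 5.0, noise_sigma = 0.2,
                            rigid_body_jitter = TRUE, seed = 1L) {
  n_states <- check_count(n_states, "n_states")
  n_frames <- check_count(n_frames, "n_frames")
  if (is.null(transition_matrix)) {
    # symmetric sticky chain: stay with probability 0.9
    stay <- if (n_states == 1L) 1 else 0.9
    transition_matrix <- matrix((1 - stay) / max(n_states - 1L, 1L),
                                n_states, n_states)
    diag(transition_matrix) <- stay
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == n_states)) {
    ens_stop("invalid_spec", "transition_matrix must be n_states x n_states")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    ens_stop("invalid_spec", "transition_matrix rows must be non-negative and sum to 1 (within 1e-12)")
  }
  noise_sigma <- check_number(noise_sigma, "noise_sigma", min = 0)
  state_displacement <- check_number(state_displacement, "state_displacement", min = 0)
  structure(list(
    n_states = n_states, n_frames = n_frames,
    transition_matrix = transition_matrix,
    state_displacement = state_displacement, noise_sigma = noise_sigma,
    rigid_body_jitter = isTRUE(rigid_body_jitter), seed = as.integer(seed)
  ), class = "ens_trajectory_spec")
}

#' Build a toy protein with an adjacent ligand
#'
#' Lays four backbone atoms (N, CA, C, O) per residue along a regular
#' helical curve and places a small ligand point set within 2 angstroms of
#' atoms in the "binding loop" (the middle third of residues). Purely
#' geometric - no force field, no physics.
#'
#' @param n_residues number of residues (>= 3).
#' @return list with `structure` (one-frame `ens_trajectory`),
#'   `ligand_coords` (`L x 3` matrix), and `binding_loop_residues`
#'   (integer residue numbers of the middle third).
#' @export
build_toy_protein <- function(n_residues) {
  n_residues <- suppressWarnings(as.integer(n_residues))
  if (is.na(n_residues) || n_residues < 3L) {
    ens_stop("invalid_spec", "n_residues must be an integer >= 3")
  }
  # idealized helix: ~2.3 A radius, 1.5 A rise, 100 degrees per residue
  t <- (seq_len(n_residues) - 1L) * (100 * pi / 180)
  ca <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n_residues) - 1L))
  offsets <- list(N = c(-0.8, 0.9, -0.6), CA = c(0, 0, 0),
                  C = c(1.0, 0.6, 0.6), O = c(1.4, 1.6, 0.9))
  A <- 4L * n_residues
  coords <- matrix(0, A, 3L)
  top <- data.frame(
    atom_name = rep(c("N", "CA", "C", "O"), n_residues),
    residue_number = rep(seq_len(n_residues), each = 4L),
    residue_name = "GLY", chain_id = "A",
    element = rep(c("N", "C", "C", "O"), n_residues),
    record = "ATOM", stringsAsFactors = FALSE
  )
  for (r in seq_len(n_residues)) {
    for (a in 1:4) {
      coords[(r - 1L) * 4L + a, ] <- ca[r, ] + offsets[[a]]
    }
  }
  loop <- binding_loop_residues(n_residues)
  # ligand: points 1.5 A radially outward of the loop residues' CA atoms
  lig <- t(vapply(loop, function(r) {
    x <- ca[r, ]
    dir <- c(x[1], x[2], 0)
    dir <- dir / sqrt(sum(dir^2))
    x + 1.5 * dir
  }, numeric(3)))
  list(structure = trajectory(top, coords),
       ligand_coords = lig,
       binding_loop_residues = loop)
}

# middle third of residues (at least one), mirroring a localized
# binding-site loop
binding_loop_residues <- function(n_residues) {
  lo <- floor(n_residues / 3) + 1L
  hi <- min(n_residues, ceiling(2 * n_residues / 3))
  seq(lo, hi)
}

#' Simulate a discrete Markov chain
#'
#' Realizes `n_steps` of a Markov chain with the given row-stochastic
#' transition matrix, started from its stationary distribution (leading
#' left eigenvector), so no burn-in is needed.
#'
#' @param transition_matrix row-stochastic square matrix.
#' @param n_steps chain length.
#' @param seed integer seed.
#' @return integer vector of 1-based state indices, with the stationary
#'   distribution as attribute `stationary`.
#' @export
simulate_markov_chain <- function(transition_matrix, n_steps, seed = 1L) {
  P <- as.matrix(transition_matrix)
  n_steps <- check_count(n_steps, "n_steps")
  n <- nrow(P)
  pi0 <- stationary_distribution(P)
  with_seed(seed, {
    s <- integer(n_steps)
    s[1] <- sample.int(n, 1L, prob = pi0)
    if (n_steps > 1L) {
      for (t in 2:n_steps) s[t] <- sample.int(n, 1L, prob = P[s[t - 1L], ])
    }
    attr(s, "stationary") <- pi0
    s
  })
}

#' Stationary distribution of a Markov chain
#'
#' Leading left eigenvector of the transition matrix, normalized to sum
#' to 1.
#'
#' @param transition_matrix row-stochastic square matrix.
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(transition_matrix) {
  P <- as.matrix(transition_matrix)
  e <- eigen(t(P))
  i <- which.max(Re(e$values) - abs(Im(e$values)))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a Markov-switching conformational trajectory
#'
#' Frame t is the base structure with a state-specific deformation applied
#' to the binding-loop atoms (displacement along a fixed per-state unit
#' direction, with signs alternating residue by residue along the loop so
#' the deformation is internal motion, not a rigid shift removable by
#' superposition), plus isotropic Gaussian noise on every coordinate,
#' optionally followed by a random proper rotation and translation of the
#' whole frame. State 1 is the undeformed reference state; states `j > 1`
#' deform along fixed, well-separated unit directions. The chain starts
#' from its stationary distribution.
#'
#' Sub-streams (chain, noise, rigid jitter) are seeded independently from
#' `spec$seed`, so switching `rigid_body_jitter` does not change the noise
#' realization.
#'
#' @param base a single-frame `ens_trajectory` (e.g. from
#'   [build_toy_protein()]).
#' @param spec an `ens_trajectory_spec`.
#' @return list with `trajectory` (an `ens_trajectory`) and `state_labels`
#'   (1-based per-frame true state indices).
#' @export
simulate_markov_trajectory <- function(base, spec) {
  stopifnot(inherits(base, "ens_trajectory"), inherits(spec, "ens_trajectory_spec"))
  top <- base$topology
  loop_res <- binding_loop_residues(max(top$residue_number))
  loop_atoms <- which(top$residue_number %in% loop_res & top$record == "ATOM")
  if (length(loop_atoms) == 0L) {
    ens_stop("invalid_spec", "binding-loop displacement subset is empty")
  }
  seeds <- derive_seeds(spec$seed, 3L)
  states <- simulate_markov_chain(spec$transition_matrix, spec$n_frames, seed = seeds[1])
  dirs <- state_directions(spec$n_states)
  # alternating-sign weights along the loop make the displacement a genuine
  # internal deformation (net translation ~ 0), so rigid-body superposition
  # cannot absorb it even when fitting on the loop atoms alone
  loop_sign <- (-1)^(match(top$residue_number[loop_atoms], loop_res) - 1L)
  base_xyz <- frame_coords(base, 1L)
  A <- nrow(base_xyz)
  F <- spec$n_frames
  coords <- array(rep(as.vector(base_xyz), each = F), dim = c(F, A, 3L))
  for (f in seq_len(F)) {
    off <- outer(loop_sign, spec$state_displacement * dirs[states[f], ])
    xf <- matrix(coords[f, loop_atoms, ], ncol = 3L)
    coords[f, loop_atoms, ] <- xf + off
  }
  if (spec$noise_sigma > 0) {
    coords <- coords + with_seed(seeds[2],
      array(rnorm(F * A * 3L, sd = spec$noise_sigma), dim = c(F, A, 3L)))
  }
  if (spec$rigid_body_jitter) {
    transforms <- with_seed(seeds[3], lapply(seq_len(F), function(f) {
      list(R = random_rotation(), t = rnorm(3L, sd = 5))
    }))
    for (f in seq_len(F)) {
      xf <- matrix(coords[f, , ], ncol = 3L)
      coords[f, , ] <- sweep(xf %*% transforms[[f]]$R, 2L, transforms[[f]]$t, "+")
    }
  }
  list(trajectory = trajectory(top, coords, base$frame_spacing),
       state_labels = as.integer(states))
}

# fixed, well-separated displacement directions: state 1 undisplaced,
# states j > 1 along deterministic unit vectors
state_directions <- function(n_states) {
  dirs <- matrix(0, n_states, 3L)
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2))
  for (j in seq_len(n_states - 1L)) {
    dirs[j + 1L, ] <- if (j <= nrow(axes)) {
      axes[j, ]
    } else {
      v <- c(cos(j), sin(j), cos(2 * j)); v / sqrt(sum(v^2))
    }
  }
  dirs
}

# uniform random proper rotation via quaternion
random_rotation <- function() {
  q <- rnorm(4L)
  q <- q / sqrt(sum(q^2))
  quaternion_to_rotation(q)
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Specification of a synthetic docking score matrix
#'
#' Scores follow `s(l, i) = a_l + b_i + c_{l,i} + eps_{l,i}`: a planted
#' per-ligand affinity `a_l` uniform on `affinity_range` (lower = tighter
#' binder), a per-conformation bias `b_i`, a ligand-conformation
#' compatibility term `c_{l,i}`, and i.i.d. noise, with a stated fraction of
#' cells missing at random.
#'
#' @param n_ligands,n_conformations matrix dimensions.
#' @param affinity_range length-2 numeric interval for the planted affinity
#'   (score units, lower = better).
#' @param conformation_bias_sigma,compatibility_sigma,noise_sigma standard
#'   deviations of the bias, compatibility and noise terms (score units).
#' @param missing_fraction proportion of cells marked missing, in [0, 1).
#' @param seed integer seed.
#' @return a validated `ens_score_spec` list.
#' @export
score_spec <- function(n_ligands = 50L, n_conformations = 10L,
                       affinity_range = c(-10, -4),
                       conformation_bias_sigma = 0.5,
                       compatibility_sigma = 0.5, noise_sigma = 0.5,
                       missing_fraction = 0, seed = 1L) {
  n_ligands <- check_count(n_ligands, "n_ligands")
  n_conformations <- check_count(n_conformations, "n_conformations")
  stopifnot(length(affinity_range) == 2L, affinity_range[1] <= affinity_range[2])
  missing_fraction <- check_number(missing_fraction, "missing_fraction", min = 0)
  if (missing_fraction >= 1) {
    ens_stop("invalid_spec", "missing_fraction must be < 1")
  }
  structure(list(
    n_ligands = n_ligands, n_conformations = n_conformations,
    affinity_range = as.numeric(affinity_range),
    conformation_bias_sigma = check_number(conformation_bias_sigma, "conformation_bias_sigma", min = 0),
    compatibility_sigma = check_number(compatibility_sigma, "compatibility_sigma", min = 0),
    noise_sigma = check_number(noise_sigma, "noise_sigma", min = 0),
    missing_fraction = missing_fraction, seed = as.integer(seed)
  ), class = "ens_score_spec")
}

#' Simulate a docking score matrix with a planted affinity ordering
#'
#' @param spec an `ens_score_spec`.
#' @param conformation_ids optional conformation column labels.
#' @return list with `scores` (an [score_matrix()] with `NA` for missing
#'   cells) and `true_affinity` (named per-ligand planted affinities, score
#'   units, lower = better).
#' @export
simulate_score_matrix <- function(spec, conformation_ids = NULL) {
  stopifnot(inherits(spec, "ens_score_spec"))
  nl <- spec$n_ligands; nc <- spec$n_conformations
  with_seed(spec$seed, {
    a <- runif(nl, spec$affinity_range[1], spec$affinity_range[2])
    b <- rnorm(nc, sd = spec$conformation_bias_sigma)
    cc <- matrix(rnorm(nl * nc, sd = spec$compatibility_sigma), nl, nc)
    eps <- matrix(rnorm(nl * nc, sd = spec$noise_sigma), nl, nc)
    s <- outer(a, b, "+") + cc + eps
    if (spec$missing_fraction > 0) {
      miss <- which(runif(nl * nc) < spec$missing_fraction)
      s[miss] <- NA_real_
    }
    ligand_ids <- sprintf("L%03d", seq_len(nl))
    if (is.null(conformation_ids)) conformation_ids <- sprintf("conf%d", seq_len(nc))
    names(a) <- ligand_ids
    list(scores = score_matrix(s, ligand_ids, conformation_ids),
         true_affinity = a)
  })
}

#' Simulate experimental affinities from planted ones
#'
#' `pIC50_l = -scale * true_affinity_l + N(0, noise_sigma^2)`, so the
#' planted best binder (lowest docking-score affinity) gets the highest
#' pIC50.
#'
#' @param true_affinity named numeric vector of planted affinities (lower =
#'   better).
#' @param noise_sigma measurement noise standard deviation (pIC50 units).
#' @param seed integer seed.
#' @param scale positive scale from score units to pIC50 units (default 1).
#' @return an [affinity_table()] data frame (`ligand_id`, `pIC50`).
#' @export
simulate_experimental_affinities <- function(true_affinity, noise_sigma = 0,
                                             seed = 1L, scale = 1) {
  if (length(true_affinity) == 0L) {
    ens_stop("invalid_argument", "true_affinity must be non-empty")
  }
  noise_sigma <- check_number(noise_sigma, "noise_sigma", min = 0)
  ids <- names(true_affinity)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_along(true_affinity))
  p <- with_seed(seed,
    -scale * as.numeric(true_affinity) + rnorm(length(true_affinity), sd = noise_sigma))
  affinity_table(ids, p)
}
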