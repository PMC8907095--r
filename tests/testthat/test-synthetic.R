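# Synthetic generators: toy protein, Markov-switching trajectory,
# planted-affinity score matrices, experimental affinities.

test_that("toy protein geometry honours its contracts", {
  toy <- build_toy_protein(10)
  expect_equal(n_atoms(toy$structure), 40L)  # 4 backbone atoms per residue
  expect_true(all(table(toy$structure$topology$residue_number) == 4L))

  small <- build_toy_protein(3)
  expect_equal(n_atoms(small$structure), 12L)
  # ligand sits within 2 A of at least one binding-loop atom
  loop_atoms <- which(small$structure$topology$residue_number %in% small$binding_loop_residues)
  rec <- matrix(small$structure$coordinates[1, loop_atoms, ], ncol = 3)
  dmin <- min(sqrt(outer(rowSums(rec^2), rowSums(small$ligand_coords^2), "+") -
                     2 * rec %*% t(small$ligand_coords)))
  expect_lte(dmin, 2.0)

  expect_error(build_toy_protein(2), class = "ensdock_invalid_spec")
})

test_that("trajectory_spec validates the transition matrix", {
  bad <- matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)  # rows do not sum to 1
  expect_error(trajectory_spec(n_states = 2, transition_matrix = bad),
               class = "ensdock_invalid_spec")
  expect_error(trajectory_spec(n_states = 2,
                               transition_matrix = matrix(c(1.2, -0.2, 0, 1), 2, 2, byrow = TRUE)),
               class = "ensdock_invalid_spec")
  expect_error(trajectory_spec(noise_sigma = -1), class = "ensdock_invalid_argument")
})

test_that("identity chain stays in its initial state and generators are deterministic", {
  toy <- build_toy_protein(6)
  spec <- trajectory_spec(n_states = 2, n_frames = 100,
                          transition_matrix = diag(2), seed = 5)
  sim <- simulate_markov_trajectory(toy$structure, spec)
  expect_equal(length(unique(sim$state_labels)), 1L)

  sim2 <- simulate_markov_trajectory(toy$structure, spec)
  expect_identical(sim$trajectory$coordinates, sim2$trajectory$coordinates)
  expect_identical(sim$state_labels, sim2$state_labels)
})

test_that("empirical transition frequencies match the chain within 3 binomial SE", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  s <- simulate_markov_chain(P, 50000, seed = 21)
  for (from in 1:2) {
    at <- which(s[-length(s)] == from)
    flip_rate <- mean(s[at + 1L] != from)
    se <- sqrt(0.1 * 0.9 / length(at))
    expect_lt(abs(flip_rate - 0.1), 3 * se)
  }
})

test_that("occupancies converge to the stationary distribution", {
  P <- matrix(c(0.95, 0.04, 0.01,
                0.02, 0.95, 0.03,
                0.02, 0.03, 0.95), 3, 3, byrow = TRUE)
  pi0 <- stationary_distribution(P)
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
  expect_equal(as.numeric(pi0 %*% P), as.numeric(pi0), tolerance = 1e-10)
  s <- simulate_markov_chain(P, 50000, seed = 7)
  occ <- tabulate(s, 3) / length(s)
  # 3 sigma with the effective sample size reduced by chain autocorrelation
  # (stay probability 0.95 -> correlation time ~ (1+p)/(1-p) ~ 39)
  n_eff <- length(s) / 39
  for (i in 1:3) {
    expect_lt(abs(occ[i] - pi0[i]), 3 * sqrt(pi0[i] * (1 - pi0[i]) / n_eff))
  }
})

test_that("rigid-body jitter leaves superposed RMSD to base unchanged", {
  toy <- build_toy_protein(8)
  base_xyz <- matrix(toy$structure$coordinates[1, , ], ncol = 3)
  rmsds <- lapply(c(FALSE, TRUE), function(jit) {
    spec <- trajectory_spec(n_states = 2, n_frames = 25, state_displacement = 3,
                            noise_sigma = 0.3, rigid_body_jitter = jit, seed = 9)
    sim <- simulate_markov_trajectory(toy$structure, spec)
    vapply(seq_len(25), function(f) {
      kabsch_superpose(base_xyz, matrix(sim$trajectory$coordinates[f, , ], ncol = 3))$rmsd
    }, numeric(1))
  })
  expect_equal(rmsds[[1]], rmsds[[2]], tolerance = 1e-8)
})

test_that("noise-free score matrices reproduce the planted ordering exactly", {
  spec <- score_spec(n_ligands = 20, n_conformations = 5,
                     conformation_bias_sigma = 0, compatibility_sigma = 0,
                     noise_sigma = 0, missing_fraction = 0, seed = 3)
  sim <- simulate_score_matrix(spec)
  for (j in seq_len(5)) {
    expect_equal(unname(sim$scores[, j]), unname(sim$true_affinity))
  }
  P <- rep(0.2, 5)
  for (r in list(aggregate_min(sim$scores), aggregate_avg(sim$scores),
                 aggregate_weighted(sim$scores, P))) {
    expect_equal(kendall_tau(r$score, sim$true_affinity[r$ligand_id]), 1)
  }
})

test_that("missing cells are marked NA at the stated rate and ligands stay scorable or flagged", {
  spec <- score_spec(n_ligands = 50, n_conformations = 10,
                     missing_fraction = 0.2, seed = 11)
  sim <- simulate_score_matrix(spec)
  n_missing <- sum(is.na(sim$scores))
  expect_lt(abs(n_missing - 100), 3 * sqrt(500 * 0.2 * 0.8))
  flagged <- unscorable_ligands(sim$scores)
  scored <- setdiff(rownames(sim$scores), flagged)
  expect_true(all(rowSums(!is.na(sim$scores[scored, , drop = FALSE])) >= 1))
})

test_that("heavy score noise drives mean recovery tau to zero", {
  taus <- vapply(1:100, function(seed) {
    spec <- score_spec(n_ligands = 15, n_conformations = 4,
                       affinity_range = c(-7, -6.9),  # ~ no affinity signal
                       conformation_bias_sigma = 0, compatibility_sigma = 0,
                       noise_sigma = 5, seed = seed)
    sim <- simulate_score_matrix(spec)
    r <- aggregate_avg(sim$scores)
    kendall_tau(r$score, sim$true_affinity[r$ligand_id])
  }, numeric(1))
  expect_lt(abs(mean(taus)), 0.1)
})

test_that("experimental affinities respect the sign convention and degrade with noise", {
  a <- c(L1 = -9, L2 = -5)
  tab <- simulate_experimental_affinities(a, noise_sigma = 0, seed = 1)
  expect_gt(tab$pIC50[tab$ligand_id == "L1"], tab$pIC50[tab$ligand_id == "L2"])

  a10 <- stats::setNames(seq(-10, -5.5, by = 0.5), sprintf("L%02d", 1:10))
  tau0 <- kendall_tau(
    rank_from_scores(a10, "lower-better"),
    rank_from_scores(simulate_experimental_affinities(a10, 0, seed = 2)$pIC50,
                     "higher-better"))
  expect_equal(tau0, 1)
  mean_tau <- vapply(c(0.2, 1, 5), function(sigma) {
    mean(vapply(1:100, function(seed) {
      tab <- simulate_experimental_affinities(a10, sigma, seed = seed)
      kendall_tau(rank_from_scores(a10, "lower-better"),
                  rank_from_scores(tab$pIC50, "higher-better"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_tau) < 0))
})
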