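# Score aggregation, rank orderings, Kendall's tau, the permutation null,
# and the tau grid.

test_that("aggregation schemes reproduce the worked examples, missing cells included", {
  S <- toy_score_matrix(rbind(c(-7.2, -6.5, -8.1)))
  expect_equal(aggregate_min(S)$score, -8.1)
  S1 <- toy_score_matrix(rbind(c(NA, -5.0, NA)))
  expect_equal(aggregate_min(S1)$score, -5.0)
  expect_equal(aggregate_min(toy_score_matrix(rbind(-4.2)))$score, -4.2)

  S2 <- toy_score_matrix(rbind(c(-8, -6, -4)))
  expect_equal(aggregate_avg(S2)$score, -6.0)
  expect_equal(aggregate_avg(toy_score_matrix(rbind(c(-3, -3, -3))))$score, -3)
  expect_equal(aggregate_avg(toy_score_matrix(rbind(c(-8, NA, -4))))$score, -6.0)

  P <- c(0.6, 0.3, 0.1)
  expect_equal(aggregate_weighted(S2, P)$score, -7.0)
  # renormalization over present entries
  S3 <- toy_score_matrix(rbind(c(-8, NA, -4)))
  expect_equal(aggregate_weighted(S3, P)$score, (0.6 * -8 + 0.1 * -4) / 0.7)
  # uniform weights equal the plain average exactly
  set.seed(7)
  S4 <- toy_score_matrix(matrix(rnorm(40, -7), 10, 4))
  expect_equal(aggregate_weighted(S4, rep(0.25, 4))$score, aggregate_avg(S4)$score)

  expect_error(aggregate_weighted(S2, c(0.5, 0.5, 0.1)),
               class = "ensdock_invalid_argument")
  expect_error(aggregate_weighted(S2, c(1.2, -0.1, -0.1)),
               class = "ensdock_invalid_argument")
})

test_that("unscorable ligands are excluded and reported, never silently dropped", {
  m <- rbind(c(-8, -7), c(NA, NA), c(-5, NA))
  S <- score_matrix(m, ligand_ids = c("a", "b", "c"))
  expect_identical(unscorable_ligands(S), "b")
  expect_warning(r <- aggregate_min(S), "unscorable")
  expect_identical(r$ligand_id, c("a", "c"))
  expect_identical(attr(r, "excluded"), "b")
})

test_that("aggregation dominance holds on random matrices with missing values", {
  set.seed(20)
  for (rep in 1:20) {
    m <- matrix(rnorm(60, mean = -7, sd = 2), 12, 5)
    m[sample(60, 12)] <- NA
    keep <- rowSums(!is.na(m)) > 0
    S <- score_matrix(m[keep, , drop = FALSE])
    P <- as.numeric(cluster_populations(sample(1:10, 5, replace = TRUE)))
    w <- aggregate_weighted(S, P)
    lo <- aggregate_min(S)
    hi <- apply(S, 1, max, na.rm = TRUE)
    expect_true(all(lo$score <= w$score + 1e-12))
    expect_true(all(w$score <= hi + 1e-12))
  }
})

test_that("ranks follow the stated direction with average-rank ties", {
  expect_equal(rank_from_scores(c(-9, -7, -8), "lower-better"), c(1, 3, 2))
  expect_equal(rank_from_scores(c(8.1, 6.2, 7.0), "higher-better"), c(1, 3, 2))
  expect_equal(rank_from_scores(c(-5, -5, -3), "lower-better"), c(1.5, 1.5, 3))
})

test_that("kendall_tau reproduces the worked example and the brute-force oracle", {
  expect_equal(kendall_tau(1:5, 1:5), 1)
  expect_equal(kendall_tau(1:5, 5:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)

  set.seed(15)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    a <- sample(1:4, n, replace = TRUE)  # ties likely
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(kendall_tau(a, b), brute_kendall(a, b), tolerance = 1e-12)
  }

  expect_error(kendall_tau(1:4, 1:5), class = "ensdock_pairing_error")
  expect_error(kendall_tau(c(a = 1, b = 2), c(a = 1, z = 2)),
               class = "ensdock_pairing_error")
  # named vectors pair by id, not position
  expect_equal(kendall_tau(c(a = 1, b = 2, c = 3), c(c = 3, a = 1, b = 2)), 1)
  expect_error(kendall_tau(c(2, 2, 2), 1:3), class = "ensdock_degenerate_input")
})

test_that("negating scores and flipping direction leaves tau unchanged", {
  set.seed(27)
  for (rep in 1:10) {
    s <- rnorm(15); p <- rnorm(15)
    t1 <- kendall_tau(rank_from_scores(s, "lower-better"),
                      rank_from_scores(p, "higher-better"))
    t2 <- kendall_tau(rank_from_scores(-s, "higher-better"),
                      rank_from_scores(p, "higher-better"))
    expect_equal(t1, t2, tolerance = 1e-12)
  }
})

test_that("permutation null matches the analytic sigma across sizes", {
  for (n in c(10, 50)) {
    nd <- tau_null_distribution(n, n_samples = 4000, seed = n)
    sig <- analytic_tau_sigma(n)
    mc_se <- sig / sqrt(2 * (nd$n_samples - 1))  # SE of a sample sd
    expect_lt(abs(nd$std - sig), 3 * mc_se + 0.01)
    expect_lt(abs(nd$mean), 3 * sig / sqrt(nd$n_samples))
  }
  nd10 <- tau_null_distribution(10, n_samples = 4000, seed = 2)
  expect_lt(abs(nd10$std - 0.2485), 3 * 0.2485 / sqrt(4000) + 0.005)
})

test_that("analytic tau sigma evaluates the closed form and decreases in n", {
  expect_equal(analytic_tau_sigma(10), sqrt(2 * 25 / (9 * 10 * 9)))
  expect_equal(round(analytic_tau_sigma(459), 3), 0.031)
  sig <- vapply(c(5, 10, 50, 100, 459, 1000), analytic_tau_sigma, numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_error(analytic_tau_sigma(2), class = "ensdock_invalid_argument")
})

test_that("null summaries and observed percentiles serialize", {
  nd <- tau_null_distribution(20, n_samples = 500, seed = 3, observed = 0.5)
  expect_gt(nd$percentile, 0.99)
  f <- tempfile(fileext = ".json")
  write_null_summary(nd, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$std, nd$std, tolerance = 1e-12)
  expect_equal(back$n_items, 20)
})

test_that("pearson diagnostic matches hand computation and the null", {
  s <- c(L1 = -9, L2 = -8, L3 = -6, L4 = -5)
  tab <- affinity_table(names(s), -as.numeric(s))
  expect_equal(pearson_score_affinity(s, tab), -1)

  # textbook formula on a 4-point set, long-hand
  y <- c(7.1, 6.0, 6.5, 5.2)
  tab2 <- affinity_table(names(s), y)
  num <- sum((s - mean(s)) * (y - mean(y)))
  den <- sqrt(sum((s - mean(s))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_score_affinity(s, tab2), num / den, tolerance = 1e-12)

  set.seed(31)
  s2 <- stats::setNames(rnorm(2000), sprintf("L%04d", 1:2000))
  tab3 <- affinity_table(names(s2), rnorm(2000))
  expect_lt(abs(pearson_score_affinity(s2, tab3)), 0.1)

  expect_error(pearson_score_affinity(c(L1 = 1, L2 = 1, L3 = 1),
                                      affinity_table(c("L1", "L2", "L3"), 1:3)),
               class = "ensdock_degenerate_input")
})

test_that("the tau grid covers schemes x methods and separates schemes when compatibility dominates", {
  # noise-free planted scores: every scheme, every method gives tau = 1
  spec <- score_spec(n_ligands = 12, n_conformations = 4,
                     conformation_bias_sigma = 0, compatibility_sigma = 0,
                     noise_sigma = 0, seed = 5)
  sim <- simulate_score_matrix(spec)
  aff <- simulate_experimental_affinities(sim$true_affinity, 0, seed = 1)
  S_by <- list(tica = sim$scores, pca = sim$scores)
  P_by <- list(tica = rep(0.25, 4), pca = c(0.4, 0.3, 0.2, 0.1))
  grid <- evaluate_grid(S_by, P_by, aff)
  expect_identical(dim(grid), c(3L, 2L))
  expect_identical(rownames(grid), c("Minimum", "W. Avg.", "Avg."))
  expect_true(all(grid == 1))

  # one dominating conformation per ligand: Minimum and Average ranks differ
  m <- rbind(c(-12, -1, -1), c(-2, -11, -9), c(-3, -10, -2))
  S <- score_matrix(m, ligand_ids = c("x", "y", "z"))
  aff2 <- affinity_table(c("x", "y", "z"), c(3, 2, 1))
  g2 <- evaluate_grid(list(m1 = S), list(m1 = rep(1 / 3, 3)), aff2)
  expect_false(isTRUE(all.equal(g2["Minimum", 1], g2["Avg.", 1])))

  expect_error(evaluate_grid(list(m1 = S), list(m1 = rep(1 / 3, 3)),
                             affinity_table(c("x", "y"), c(1, 2))),
               class = "ensdock_pairing_error")
})

test_that("score matrices and affinity tables round-trip through CSV", {
  m <- matrix(c(-8.25, NA, -6.5, -7, NA, -5), 2, 3)
  S <- score_matrix(m, c("ligA", "ligB"), c("m_c0", "m_c1", "m_c2"))
  f <- tempfile(fileext = ".csv")
  write_score_matrix(S, f)
  header <- readLines(f, n = 1)
  expect_match(header, "^\"?ligand_id")
  back <- read_score_matrix(f)
  expect_equal(unclass(back), unclass(S), ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(S))

  tab <- affinity_table(c("ligA", "ligB"), c(7.25, 5.5))
  f2 <- tempfile(fileext = ".csv")
  write_affinity_table(tab, f2)
  expect_equal(read_affinity_table(f2)$pIC50, tab$pIC50)
})
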