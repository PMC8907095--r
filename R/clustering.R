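# Trajectory discretization: k-means with medoid-frame extraction, GROMOS
# neighbor-counting clustering, cutoff-selection criteria, and cluster
# populations.

new_cluster_model <- function(method, labels, k, medoids, populations,
                              centers = NULL, cutoff = NULL, seed = NULL,
                              feature = "custom", wcss_history = NULL) {
  structure(list(method = method, feature = feature,
                 labels = as.integer(labels), k = as.integer(k),
                 medoid_frames = as.integer(medoids),
                 populations = as.integer(populations),
                 centers = centers, cutoff = cutoff, seed = seed,
                 wcss_history = wcss_history),
            class = "ens_cluster_model")
}

#' @export
print.ens_cluster_model <- function(x, ...) {
  cat(sprintf("<ens_cluster_model> %s, k = %d, %d frames; populations: %s\n",
              x$method, x$k, length(x$labels),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' k-means clustering of projected features
#'
#' k-means++ initialization (seeded) followed by Lloyd iterations until the
#' center shift falls below `tol` or `max_iter` is reached. An emptied
#' cluster is reseeded to the point farthest from its assigned center, so
#' every cluster is non-empty. Clusters are relabelled by decreasing size
#' (label 0 = largest). The within-cluster sum of squares after each
#' iteration is recorded in `wcss_history`.
#'
#' @param Y `F x m` matrix of (projected) features.
#' @param k number of clusters (1 <= k <= F), default 10.
#' @param seed integer seed for the initialization.
#' @param max_iter,tol Lloyd iteration controls.
#' @param restarts number of seeded restarts; the run with the lowest final
#'   within-cluster sum of squares wins (default 1, a single clustering).
#' @return an `ens_cluster_model` with continuous `centers`, 0-based
#'   `labels`, per-cluster `populations` and medoid `medoid_frames`.
#' @export
kmeans_cluster <- function(Y, k = 10L, seed = 1L, max_iter = 500L,
                           tol = 1e-6, restarts = 1L) {
  Y <- as_feature_matrix(Y)
  k <- check_count(k, "k")
  restarts <- check_count(restarts, "restarts")
  if (nrow(Y) < k) {
    ens_stop("invalid_argument", sprintf("F = %d frames < k = %d clusters", nrow(Y), k))
  }
  run_seeds <- if (restarts == 1L) seed else derive_seeds(seed, restarts)
  best <- NULL
  for (s in run_seeds) {
    fit <- kmeans_once(Y, k, s, max_iter, tol)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  # relabel by decreasing population; ties keep the original center order
  sizes <- tabulate(best$assign, nbins = k)
  ord <- order(-sizes, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels0 <- relabel[best$assign] - 1L
  centers <- best$centers[ord, , drop = FALSE]
  model <- new_cluster_model("kmeans", labels0, k,
                             medoids = rep(NA_integer_, k),
                             populations = sizes[ord],
                             centers = centers, seed = seed,
                             wcss_history = best$history)
  model$medoid_frames <- medoid_frames(Y, model)
  model
}

kmeans_once <- function(Y, k, seed, max_iter, tol) {
  F <- nrow(Y)
  centers <- with_seed(seed, kmeanspp_init(Y, k))
  history <- numeric(0)
  assign <- integer(F)
  for (iter in seq_len(max_iter)) {
    d2 <- point_center_dist2(Y, centers)
    assign <- max.col(-d2, ties.method = "first")
    # reseed empty clusters to the farthest point from its current center
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      nearest <- d2[cbind(seq_len(F), assign)]
      far <- which.max(nearest)
      centers[empty[1], ] <- Y[far, ]
      d2[, empty[1]] <- rowSums(sweep(Y, 2L, centers[empty[1], ])^2)
      assign <- max.col(-d2, ties.method = "first")
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(Y[assign == j, , drop = FALSE])
    }
    history <- c(history, sum(point_center_dist2(Y, new_centers)[cbind(seq_len(F), assign)]))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, assign = assign,
       wcss = history[length(history)], history = history)
}

# k-means++ seeding (D^2 sampling); runs inside with_seed()
kmeanspp_init <- function(Y, k) {
  F <- nrow(Y)
  centers <- matrix(0, k, ncol(Y))
  centers[1, ] <- Y[sample.int(F, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(Y, 2L, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / F, F)
      centers[j, ] <- Y[sample.int(F, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(Y, 2L, centers[j, ])^2))
    }
  }
  centers
}

point_center_dist2 <- function(Y, centers) {
  d2 <- outer(rowSums(Y^2), rowSums(centers^2), "+") - 2 * Y %*% t(centers)
  pmax(d2, 0)
}

#' Medoid frame of each cluster
#'
#' For each cluster, the trajectory frame (among its members) closest in
#' the projected space to the continuous cluster center; ties break to the
#' lowest frame index. These are the "centroid structures" exported for
#' docking.
#'
#' @param Y the feature matrix the model was fit on.
#' @param model an `ens_cluster_model` with continuous `centers`.
#' @return integer vector of 1-based frame indices, one per cluster.
#' @export
medoid_frames <- function(Y, model) {
  stopifnot(inherits(model, "ens_cluster_model"), !is.null(model$centers))
  Y <- as_feature_matrix(Y)
  vapply(seq_len(model$k), function(j) {
    members <- which(model$labels == j - 1L)
    d2 <- rowSums(sweep(Y[members, , drop = FALSE], 2L, model$centers[j, ])^2)
    members[which.min(d2)]  # which.min takes the first (lowest index) on ties
  }, integer(1))
}

#' GROMOS (neighbor-counting) clustering of a pairwise RMSD matrix
#'
#' Iterative greedy algorithm: among unassigned frames, the frame with the
#' most unassigned neighbors within `cutoff` (inclusive) becomes the next
#' cluster center; it and its neighbors are assigned and removed; repeat
#' until all frames are assigned. Ties in neighbor count break to the
#' lowest frame index. Singleton clusters are allowed. Cluster sizes are
#' non-increasing in label order by construction; each cluster's medoid is
#' its center frame.
#'
#' @param D symmetric pairwise RMSD matrix with zero diagonal (angstroms).
#' @param cutoff neighbor cutoff in the units of `D` (> 0).
#' @return an `ens_cluster_model` (method `"gromos"`).
#' @export
gromos_cluster <- function(D, cutoff) {
  D <- as.matrix(D)
  cutoff <- check_number(cutoff, "cutoff")
  if (cutoff <= 0) ens_stop("invalid_argument", "`cutoff` must be > 0")
  F <- nrow(D)
  if (ncol(D) != F || any(D < 0) || max(abs(D - t(D))) > 1e-8 ||
      max(abs(diag(D))) > 1e-8) {
    ens_stop("invalid_argument", "D must be a symmetric non-negative matrix with zero diagonal")
  }
  adj <- D <= cutoff + 1e-12
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, F)
  labels <- integer(F)
  centers <- integer(0)
  cl <- 0L
  while (any(unassigned)) {
    counts <- as.integer(adj %*% unassigned) # neighbors among unassigned
    counts[!unassigned] <- -1L
    center <- which.max(counts)  # ties -> lowest frame index
    members <- which(unassigned & (adj[center, ] | seq_len(F) == center))
    labels[members] <- cl
    centers <- c(centers, center)
    unassigned[members] <- FALSE
    cl <- cl + 1L
  }
  pops <- tabulate(labels + 1L, nbins = cl)
  new_cluster_model("gromos", labels, cl, medoids = centers,
                    populations = pops, cutoff = cutoff)
}

#' Select a GROMOS cutoff by the population criteria
#'
#' Clusters `D` at every candidate cutoff (in the given order) and returns
#' the first candidate whose clustering satisfies all three criteria:
#' (i) the first (largest) cluster holds less than 70 percent of the
#' frames; (ii) the first 10 clusters hold at least 80 percent of the
#' frames; (iii) each of the first 10 clusters has at least 20 frames.
#' With fewer than 10 clusters, (ii) and (iii) are evaluated over all
#' existing clusters.
#'
#' @param D symmetric pairwise RMSD matrix.
#' @param candidates numeric vector of candidate cutoffs, tried in order.
#' @param first_cluster_max,coverage_min,min_frames the three criteria
#'   thresholds (defaults 0.70, 0.80, 20).
#' @return list with `cutoff` (the selected candidate), `model` (its
#'   `ens_cluster_model`) and `report` (per-candidate pass/fail table).
#'   If no candidate passes, a `selection_failure` error carrying the
#'   report (as condition element `e$report`) is raised.
#' @export
select_gromos_cutoff <- function(D, candidates, first_cluster_max = 0.70,
                                 coverage_min = 0.80, min_frames = 20L) {
  if (length(candidates) < 1L) ens_stop("invalid_argument", "need at least one candidate cutoff")
  rows <- list()
  chosen <- NULL
  for (cand in candidates) {
    model <- gromos_cluster(D, cand)
    f <- model$populations
    f_T <- sum(f)
    top <- seq_len(min(10L, model$k))
    crit_i <- f[1] / f_T < first_cluster_max
    crit_ii <- sum(f[top]) / f_T >= coverage_min
    crit_iii <- all(f[top] >= min_frames)
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = cand, n_clusters = model$k,
      first_cluster_fraction = f[1] / f_T,
      top10_coverage = sum(f[top]) / f_T,
      min_top10_frames = min(f[top]),
      pass_i = crit_i, pass_ii = crit_ii, pass_iii = crit_iii,
      pass = crit_i && crit_ii && crit_iii)
    if (is.null(chosen) && crit_i && crit_ii && crit_iii) {
      chosen <- list(cutoff = cand, model = model)
    }
  }
  report <- do.call(rbind, rows)
  if (is.null(chosen)) {
    ens_stop("selection_failure",
             "no candidate cutoff satisfies the GROMOS selection criteria",
             data = list(report = report))
  }
  c(chosen, list(report = report))
}

#' Cluster populations as probabilities
#'
#' `P_i = f_i / f_T`, the probability of observing conformation i, where
#' `f_i` is the cluster's frame count and `f_T` the total number of frames.
#' Used as the weights of the weighted-average scoring scheme.
#'
#' @param model an `ens_cluster_model` (or a bare vector of frame counts).
#' @return numeric probability vector summing to 1.
#' @export
cluster_populations <- function(model) {
  f <- if (inherits(model, "ens_cluster_model")) model$populations else as.numeric(model)
  if (length(f) == 0L || sum(f) <= 0) ens_stop("invalid_argument", "model has no frames")
  f / sum(f)
}

#' Extract centroid structures for an ensemble-docking run
#'
#' Pulls each cluster's medoid frame out of the trajectory as a
#' single-frame structure, coordinates untouched (no minimization or
#' cleanup), together with a manifest of cluster id, source frame index,
#' frame count and population probability.
#'
#' @param traj the `ens_trajectory` the clustering refers to.
#' @param model an `ens_cluster_model` with valid `medoid_frames`.
#' @param ids optional conformation ids (default `c0, c1, ...`).
#' @return list with `structures` (list of single-frame trajectories) and
#'   `manifest` (data frame: `conformation_id`, `cluster`, `frame_index`,
#'   `f_i`, `P_i`).
#' @export
extract_centroid_ensemble <- function(traj, model, ids = NULL) {
  stopifnot(inherits(traj, "ens_trajectory"), inherits(model, "ens_cluster_model"))
  if (any(is.na(model$medoid_frames)) ||
      any(model$medoid_frames < 1L | model$medoid_frames > n_frames(traj))) {
    ens_stop("invalid_argument", "medoid frame indices out of range for this trajectory")
  }
  if (is.null(ids)) ids <- sprintf("c%d", seq_len(model$k) - 1L)
  structures <- lapply(model$medoid_frames, function(i) get_frame(traj, i))
  P <- cluster_populations(model)
  manifest <- data.frame(
    conformation_id = ids,
    cluster = seq_len(model$k) - 1L,
    frame_index = model$medoid_frames,
    f_i = model$populations,
    P_i = P, stringsAsFactors = FALSE)
  list(structures = structures, manifest = manifest)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expected value for independent labelings. Used to check that clustering
#' recovers a planted state partition.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) ens_stop("invalid_argument", "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-15) return(1)
  (sum_ij - expected) / (maxi - expected)
}
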