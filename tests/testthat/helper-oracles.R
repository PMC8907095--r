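# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths of the package functions they
# verify.

# O(n^2) tie-aware Kendall tau-b by explicit pair enumeration
brute_kendall <- function(a, b) {
  n <- length(a)
  C <- D <- Ta <- Tb <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      da <- a[i] - a[j]; db <- b[i] - b[j]
      if (da == 0 && db == 0) next
      if (da == 0) { Ta <- Ta + 1; next }
      if (db == 0) { Tb <- Tb + 1; next }
      if (sign(da) == sign(db)) C <- C + 1 else D <- D + 1
    }
  }
  (C - D) / sqrt((C + D + Ta) * (C + D + Tb))
}

# direct reimplementation of the greedy neighbor-counting clustering
brute_gromos <- function(D, cutoff) {
  n <- nrow(D)
  remaining <- seq_len(n)
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  while (length(remaining) > 0) {
    counts <- vapply(remaining,
                     function(i) sum(D[i, remaining] <= cutoff + 1e-12) - 1L,
                     integer(1))
    center <- remaining[which.max(counts)]
    members <- remaining[D[center, remaining] <= cutoff + 1e-12]
    labels[members] <- cl
    centers <- c(centers, center)
    remaining <- setdiff(remaining, members)
    cl <- cl + 1L
  }
  list(labels = labels, centers = centers)
}

# axis-angle to rotation matrix (for the grid-search RMSD oracle)
axis_angle_rotation <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  a <- v / theta
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# minimum RMSD over rotations by random-quaternion grid search plus local
# refinement; independent of the SVD-based Kabsch solution
grid_rmsd_oracle <- function(ref, mob, n_grid = 4000) {
  Q <- sweep(ref, 2, colMeans(ref))
  P <- sweep(mob, 2, colMeans(mob))
  obj_rot <- function(R) sqrt(mean(rowSums((P %*% R - Q)^2)))
  best_v <- c(0, 0, 0); best <- obj_rot(diag(3))
  set.seed(42)
  for (i in seq_len(n_grid)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    val <- obj_rot(R)
    if (val < best) {
      best <- val
      ang <- acos(max(-1, min(1, w))) * 2
      ax <- c(x, y, z)
      nrm <- sqrt(sum(ax^2))
      best_v <- if (nrm < 1e-12) c(0, 0, 0) else ax / nrm * ang
    }
  }
  opt <- optim(best_v, function(v) obj_rot(axis_angle_rotation(v)),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# uniform random proper rotation for invariance checks
random_rotation_test <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a random rigid transform to every frame of a trajectory
# (skip_first keeps frame 1 in its original pose)
rigidly_transform <- function(traj, skip_first = FALSE) {
  coords <- traj$coordinates
  for (f in seq_len(dim(coords)[1])) {
    if (skip_first && f == 1) next
    R <- random_rotation_test()
    tr <- rnorm(3, sd = 10)
    xf <- matrix(coords[f, , ], ncol = 3)
    coords[f, , ] <- sweep(xf %*% R, 2, tr, "+")
  }
  trajectory(traj$topology, coords, traj$frame_spacing)
}

# tiny 3-state score fixture shared by ranking tests
toy_score_matrix <- function(scores, ligand_ids = NULL) {
  score_matrix(scores, ligand_ids = ligand_ids)
}
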