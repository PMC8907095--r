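# PCA and TICA dimensionality reduction plus the cross-validated VAMP2
# score used to choose among candidate feature sets.

new_reduction_model <- function(kind, mean_vector, basis, eigenvalues,
                                lag, variance_cutoff, retained_m) {
  structure(list(kind = kind, mean_vector = mean_vector, basis = basis,
                 eigenvalues = eigenvalues, lag = lag,
                 variance_cutoff = variance_cutoff, retained_m = retained_m),
            class = "ens_reduction_model")
}

#' @export
print.ens_reduction_model <- function(x, ...) {
  cat(sprintf("<ens_reduction_model> %s, d = %d, retained %d / %d components (cutoff %.2f)%s\n",
              toupper(x$kind), length(x$mean_vector), x$retained_m,
              length(x$eigenvalues), x$variance_cutoff,
              if (x$kind == "tica") sprintf(", lag %d frames", x$lag) else ""))
  invisible(x)
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) ens_stop("invalid_argument", "features must be finite")
  X
}

#' Principal component analysis with a variance cutoff
#'
#' Eigendecomposition of the sample covariance of the mean-free features.
#' The retained dimension is the smallest m whose cumulative explained
#' variance share reaches `variance_cutoff`.
#'
#' @param X `F x d` feature matrix (e.g. from [featurize_positions()]).
#' @param variance_cutoff cumulative explained-variance proportion in
#'   (0, 1], default 0.95.
#' @return an `ens_reduction_model` (kind `"pca"`); `basis` columns are
#'   orthonormal, `eigenvalues` are the component variances, descending.
#' @export
fit_pca <- function(X, variance_cutoff = 0.95) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) ens_stop("invalid_argument", "PCA requires at least 2 frames")
  variance_cutoff <- check_number(variance_cutoff, "variance_cutoff")
  if (variance_cutoff <= 0 || variance_cutoff > 1) {
    ens_stop("invalid_argument", "variance_cutoff must be in (0, 1]")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  if (sum(diag(C)) <= 1e-14) {
    ens_stop("degenerate_input", "features are constant; covariance is zero")
  }
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  share <- cumsum(lambda) / sum(lambda)
  m <- which(share >= variance_cutoff - 1e-12)[1]
  new_reduction_model("pca", mu, e$vectors, lambda, 0L, variance_cutoff, m)
}

# Symmetrized (reversible) covariance pair over lagged frame pairs.
# X may be one matrix or a list of matrices (independent trajectories);
# no lagged pair straddles a trajectory boundary.
tica_covariances <- function(X, lag) {
  blocks <- if (is.list(X)) lapply(X, as_feature_matrix) else list(as_feature_matrix(X))
  d <- ncol(blocks[[1]])
  usable <- vapply(blocks, function(B) nrow(B) > lag, logical(1))
  if (!any(usable)) ens_stop("invalid_argument", "lag must be smaller than the trajectory length")
  blocks <- blocks[usable]
  sum_x <- numeric(d); n_pairs <- 0
  for (B in blocks) {
    N <- nrow(B) - lag
    X0 <- B[seq_len(N), , drop = FALSE]
    Xt <- B[seq_len(N) + lag, , drop = FALSE]
    sum_x <- sum_x + colSums(X0) + colSums(Xt)
    n_pairs <- n_pairs + N
  }
  mu <- sum_x / (2 * n_pairs)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (B in blocks) {
    N <- nrow(B) - lag
    X0 <- sweep(B[seq_len(N), , drop = FALSE], 2L, mu)
    Xt <- sweep(B[seq_len(N) + lag, , drop = FALSE], 2L, mu)
    C0 <- C0 + crossprod(X0) + crossprod(Xt)
    Ct <- Ct + crossprod(X0, Xt) + crossprod(Xt, X0)
  }
  list(mu = mu, C0 = C0 / (2 * n_pairs), Ct = Ct / (2 * n_pairs), n_pairs = n_pairs)
}

# inverse square root of a symmetric PSD matrix, dropping directions with
# eigenvalue below eps * max
inv_sqrt_sym <- function(C, eps = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > eps * max(e$values, 1e-300)
  if (!any(keep)) ens_stop("degenerate_input", "covariance is numerically zero")
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

#' Time-lagged independent component analysis (TICA)
#'
#' Estimates the instantaneous covariance C0 and the symmetrized lagged
#' covariance over the F - lag frame pairs of the mean-free features, and
#' solves the generalized eigenproblem `Ctau v = lambda C0 v` (with a small
#' ridge on C0 for numerical stability). Components are sorted by
#' eigenvalue, descending; the basis is C0-orthonormal. The retained
#' dimension is the smallest m whose cumulative kinetic variance
#' (lambda^2 share, the standard convention) reaches `variance_cutoff`;
#' set `variance_kind = "lambda"` for the plain-eigenvalue alternative.
#'
#' @param X `F x d` feature matrix, or a list of such matrices (independent
#'   trajectories; lagged pairs never straddle a boundary).
#' @param lag lag time in frames (1 <= lag < F).
#' @param variance_cutoff cumulative kinetic-variance proportion, default
#'   0.95.
#' @param variance_kind `"kinetic"` (lambda^2, default) or `"lambda"`.
#' @param ridge ridge added to C0's diagonal as `ridge * trace(C0) / d`.
#' @return an `ens_reduction_model` (kind `"tica"`).
#' @export
fit_tica <- function(X, lag, variance_cutoff = 0.95,
                     variance_kind = c("kinetic", "lambda"), ridge = 1e-10) {
  lag <- check_count(lag, "lag")
  variance_kind <- match.arg(variance_kind)
  variance_cutoff <- check_number(variance_cutoff, "variance_cutoff")
  if (variance_cutoff <= 0 || variance_cutoff > 1) {
    ens_stop("invalid_argument", "variance_cutoff must be in (0, 1]")
  }
  cv <- tica_covariances(X, lag)
  d <- ncol(cv$C0)
  C0 <- cv$C0 + diag(ridge * sum(diag(cv$C0)) / d, d)
  if (sum(diag(C0)) <= 1e-14) {
    ens_stop("degenerate_input", "features are constant; covariance is zero")
  }
  W <- inv_sqrt_sym(C0)
  M <- t(W) %*% cv$Ct %*% W
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  basis <- W %*% e$vectors[, ord, drop = FALSE]  # C0-orthonormal columns
  weight <- if (variance_kind == "kinetic") lambda^2 else lambda
  share <- cumsum(weight) / sum(weight)
  m <- which(share >= variance_cutoff - 1e-12)[1]
  if (is.na(m)) m <- length(lambda)
  new_reduction_model("tica", cv$mu, basis, lambda, lag, variance_cutoff, m)
}

#' Project features into a fitted reduced basis
#'
#' @param X `F x d` feature matrix with d matching the model dimension.
#' @param model an `ens_reduction_model` from [fit_pca()] or [fit_tica()].
#' @return `F x retained_m` projected feature matrix.
#' @export
project <- function(X, model) {
  X <- as_feature_matrix(X)
  stopifnot(inherits(model, "ens_reduction_model"))
  if (ncol(X) != length(model$mean_vector)) {
    ens_stop("shape_error", sprintf(
      "feature dimension %d does not match model dimension %d",
      ncol(X), length(model$mean_vector)))
  }
  sweep(X, 2L, model$mean_vector) %*% model$basis[, seq_len(model$retained_m), drop = FALSE]
}

#' Serialize / load a reduction model as JSON
#'
#' @param model an `ens_reduction_model`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored model.
#' @export
save_reduction_model <- function(model, path) {
  stopifnot(inherits(model, "ens_reduction_model"))
  obj <- list(kind = model$kind, mean_vector = model$mean_vector,
              basis = model$basis, eigenvalues = model$eigenvalues,
              lag = model$lag, variance_cutoff = model$variance_cutoff,
              retained_m = model$retained_m)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_reduction_model
#' @export
load_reduction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_reduction_model(obj$kind, as.numeric(obj$mean_vector),
                      as.matrix(obj$basis), as.numeric(obj$eigenvalues),
                      as.integer(obj$lag), obj$variance_cutoff,
                      as.integer(obj$retained_m))
}

# VAMP covariances (not symmetrized) over lagged pairs of one block
vamp_covariances <- function(X, lag) {
  N <- nrow(X) - lag
  X0 <- X[seq_len(N), , drop = FALSE]
  Xt <- X[seq_len(N) + lag, , drop = FALSE]
  mu0 <- colMeans(X0); mut <- colMeans(Xt)
  X0c <- sweep(X0, 2L, mu0); Xtc <- sweep(Xt, 2L, mut)
  list(mu0 = mu0, mut = mut,
       C00 = crossprod(X0c) / N, Ctt = crossprod(Xtc) / N,
       C0t = crossprod(X0c, Xtc) / N, n = N)
}

#' In-sample VAMP2 score of a feature set
#'
#' Linear (feature-space) VAMP: mean-free half covariances are whitened and
#' the time-lagged propagator's singular values computed; the VAMP2 score is
#' `1 + sum of the top (k - 1) squared singular values`, the 1 coming from
#' the constant singular function. A feature set with no slow signal scores
#' about 1; a two-state chain with flip probability p scores about
#' `1 + (1 - 2p)^(2 * lag)` at full k.
#'
#' @param X `F x d` feature matrix.
#' @param lag lag in frames.
#' @param k number of singular functions, including the constant (k >= 1).
#' @return the VAMP2 score (numeric scalar).
#' @export
vamp2_score <- function(X, lag, k) {
  X <- as_feature_matrix(X)
  lag <- check_count(lag, "lag")
  k <- check_count(k, "k")
  if (nrow(X) <= lag + 1L) ens_stop("invalid_argument", "need more frames than lag + 1")
  cv <- vamp_covariances(X, lag)
  1 + sum(propagator_singular_values(cv)[seq_len(min(k - 1L, ncol(X)))]^2, na.rm = TRUE)
}

propagator_singular_values <- function(cv) {
  W0 <- inv_sqrt_sym(cv$C00)
  Wt <- inv_sqrt_sym(cv$Ctt)
  K <- t(W0) %*% cv$C0t %*% Wt
  svd(K, nu = 0L, nv = 0L)$d
}

#' Cross-validated VAMP2 score
#'
#' Splits the lagged frame pairs into `folds` contiguous blocks (shuffling
#' would break temporal correlation). Per fold, a linear VAMP model is fit
#' on the training blocks; its top k singular functions (constant included)
#' are evaluated out of sample by recomputing the covariances of the
#' projected, constant-augmented functions on the held-out block. Returns
#' the mean over folds.
#'
#' @inheritParams vamp2_score
#' @param folds number of folds (default 10).
#' @param seed unused for the contiguous split; kept so callers can treat
#'   all scoring functions uniformly.
#' @return list with `mean_score` and `fold_scores`.
#' @export
vamp2_cv_score <- function(X, lag, k, folds = 10L, seed = NULL) {
  X <- as_feature_matrix(X)
  lag <- check_count(lag, "lag")
  k <- check_count(k, "k")
  folds <- check_count(folds, "folds", min = 2L)
  N <- nrow(X) - lag
  if (N < folds * (lag + 2L)) {
    ens_stop("invalid_argument", "folds would be shorter than lag + 2 frames")
  }
  fold_id <- cut(seq_len(N), breaks = folds, labels = FALSE)
  scores <- vapply(seq_len(folds), function(f) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    cv <- vamp_pair_covariances(X, lag, train)
    W0 <- inv_sqrt_sym(cv$C00); Wt <- inv_sqrt_sym(cv$Ctt)
    K <- t(W0) %*% cv$C0t %*% Wt
    s <- svd(K)
    kk <- min(k - 1L, length(s$d))
    if (kk == 0L) return(1)
    A <- W0 %*% s$u[, seq_len(kk), drop = FALSE]
    B <- Wt %*% s$v[, seq_len(kk), drop = FALSE]
    # evaluate the training singular functions on the held-out pairs,
    # augmented with the constant function
    X0 <- sweep(X[test, , drop = FALSE], 2L, cv$mu0)
    Xt <- sweep(X[test + lag, , drop = FALSE], 2L, cv$mut)
    Y0 <- cbind(1, X0 %*% A)
    Yt <- cbind(1, Xt %*% B)
    n <- length(test)
    G00 <- crossprod(Y0) / n
    Gtt <- crossprod(Yt) / n
    G0t <- crossprod(Y0, Yt) / n
    Kt <- t(inv_sqrt_sym(G00)) %*% G0t %*% inv_sqrt_sym(Gtt)
    sum(svd(Kt, nu = 0L, nv = 0L)$d[seq_len(min(k, nrow(Kt)))]^2)
  }, numeric(1))
  list(mean_score = mean(scores), fold_scores = scores)
}

# VAMP covariances over an arbitrary subset of pair start indices
vamp_pair_covariances <- function(X, lag, pair_idx) {
  X0 <- X[pair_idx, , drop = FALSE]
  Xt <- X[pair_idx + lag, , drop = FALSE]
  mu0 <- colMeans(X0); mut <- colMeans(Xt)
  X0c <- sweep(X0, 2L, mu0); Xtc <- sweep(Xt, 2L, mut)
  n <- length(pair_idx)
  list(mu0 = mu0, mut = mut,
       C00 = crossprod(X0c) / n, Ctt = crossprod(Xtc) / n,
       C0t = crossprod(X0c, Xtc) / n)
}

#' Choose the feature set with the largest cross-validated VAMP2 score
#'
#' Scores every candidate feature matrix with [vamp2_cv_score()] and
#' returns the label of the best one (largest mean score; exact ties break
#' to the lexicographically first label). Candidates too short for the lag
#' or fold structure are skipped with a warning.
#'
#' @param candidates named list of feature matrices.
#' @param lag,k,folds,seed passed to [vamp2_cv_score()].
#' @return the winning label; the full score table is attached as attribute
#'   `score_table` and printed as a message.
#' @export
choose_feature_set <- function(candidates, lag, k, folds = 10L, seed = NULL) {
  stopifnot(is.list(candidates), length(candidates) >= 2L,
            !is.null(names(candidates)))
  labels <- sort(names(candidates))
  scores <- rep(NA_real_, length(labels))
  names(scores) <- labels
  fold_tab <- list()
  for (lab in labels) {
    res <- tryCatch(vamp2_cv_score(candidates[[lab]], lag, k, folds, seed),
                    ensdock_invalid_argument = function(e) {
                      warning(sprintf("candidate '%s' skipped: %s", lab, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) {
      scores[lab] <- res$mean_score
      fold_tab[[lab]] <- res$fold_scores
    }
  }
  if (all(is.na(scores))) ens_stop("invalid_argument", "no candidate could be scored")
  best <- labels[which.max(scores)]  # ties -> first in sorted label order
  tab <- data.frame(feature_set = labels, mean_vamp2 = as.numeric(scores))
  message(paste(utils::capture.output(print(tab, row.names = FALSE)), collapse = "\n"))
  attr(best, "score_table") <- tab
  attr(best, "fold_scores") <- fold_tab
  best
}
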