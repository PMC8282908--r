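#' Per-trial spatial covariance matrices
#'
#' Computes, for every trial, the channel-by-channel covariance
#' `X X' / trace(X X')`. Trace normalization makes the downstream whitening
#' robust to inter-trial amplitude drift and the features invariant to global
#' rescaling of the data.
#'
#' @param epochs An `epoch_set` (band-passed MI-window data), or a 3-D array
#'   `[n_trials x n_channels x n_samples]`.
#' @return Array `[n_trials x N x N]` of normalized covariances.
#' @export
trial_covariances <- function(epochs) {
  x <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  nch <- dim(x)[2]
  out <- array(0, dim = c(n, nch, nch))
  for (tr in seq_len(n)) {
    xt <- matrix(x[tr, , ], nch)
    cc <- tcrossprod(xt)
    out[tr, , ] <- cc / sum(diag(cc))
  }
  out
}

#' Average covariance matrix of one class
#'
#' The class-average of per-trial trace-normalized spatial covariances; the
#' building block `R_i` of the multiclass one-vs-rest CSP.
#'
#' @param trials Trials of one class: an `epoch_set`, a 3-D array, or an
#'   already-computed covariance stack from [trial_covariances()].
#' @return `N x N` average covariance matrix.
#' @export
class_covariance <- function(trials) {
  covs <- if (is.array(trials) && length(dim(trials)) == 3 &&
              dim(trials)[2] == dim(trials)[3] &&
              !inherits(trials, "epoch_set")) {
    # ambiguous square case is fine: covariance of covariances is not a use case
    trials
  } else {
    trial_covariances(trials)
  }
  if (dim(covs)[1] < 2) stop("class_covariance needs >= 2 trials")
  apply(covs, c(2, 3), mean)
}

#' Whitening matrix of the summed class covariance
#'
#' Eigendecomposes `R = sum_i R_i = U0 L U0'` and returns
#' `P = L^{-1/2} U0'`, so that `P R P' = I`. Directions whose eigenvalue
#' falls below `rank_tol` times the largest are dropped: common average
#' referencing removes exactly one spatial direction, so whitening restricts
#' itself to the signal subspace and returns an `r x N` matrix with
#' `P R P' = I_r` (the standard remedy for rank-deficient EEG covariances).
#' Data whose covariance collapses to fewer than two directions are
#' rejected with guidance to reduce the channel set.
#'
#' @param class_covs List of class-average covariance matrices.
#' @param rank_tol Relative eigenvalue cutoff (default 1e-8).
#' @return `r x N` whitening matrix `P` (`r = N` for full-rank data).
#' @export
csp_whitening <- function(class_covs, rank_tol = 1e-8) {
  R <- Reduce(`+`, class_covs)
  if (max(abs(R - t(R))) > 1e-8 * max(abs(R))) stop("summed covariance not symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  keep <- e$values > rank_tol * max(e$values)
  if (sum(keep) < 2) {
    stop("summed covariance is (near-)singular beyond repair; ",
         "reduce the number of channels or check for duplicated channels")
  }
  diag(1 / sqrt(e$values[keep]), nrow = sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
}

#' One-vs-rest CSP projection matrices
#'
#' For every class `c`, eigendecomposes the whitened class covariance
#' `Y_c = P R_c P'` and returns `W_c = U_c' P` with eigenvector columns
#' ordered by descending eigenvalue. Because `P (R_c + R_c') P' = I` (where
#' `R_c'` sums the remaining classes), `W_c` simultaneously diagonalizes the
#' class pair and the two diagonals sum to one per component: the first rows
#' of `W_c` capture maximal class-`c` variance share, the last rows minimal.
#'
#' Determinism: eigenvalues are sorted descending (ties keep `eigen()`'s
#' deterministic order); each filter row's sign is fixed so its
#' largest-magnitude entry is positive.
#'
#' @param class_covs Named list of class-average covariances (names are class
#'   ids).
#' @param P Whitening matrix from [csp_whitening()] (`r x N`; `r < N` when
#'   whitening dropped a null direction, e.g. after CAR).
#' @return Named list of `r x N` projection matrices `W_c`.
#' @export
ovr_projections <- function(class_covs, P) {
  lapply(class_covs, function(Rc) {
    Yc <- P %*% Rc %*% t(P)
    e <- eigen((Yc + t(Yc)) / 2, symmetric = TRUE)   # descending eigenvalues
    W <- t(e$vectors) %*% P
    fix_filter_signs(W)
  })
}

fix_filter_signs <- function(W) {
  for (j in seq_len(nrow(W))) {
    i <- which.max(abs(W[j, ]))
    if (W[j, i] < 0) W[j, ] <- -W[j, ]
  }
  W
}

#' Fit the full one-vs-rest CSP filter bank
#'
#' @param covs Covariance stack from [trial_covariances()] (or an
#'   `epoch_set`, which will be converted).
#' @param labels Class labels per trial (ignored when `covs` is an
#'   `epoch_set`).
#' @param m Filters kept from each end of the eigenvalue spectrum
#'   (default 2, giving `2m = 4` features per trial).
#' @return A list of class `spatial_filter_bank`: `whitening` (`P`),
#'   `projections` (named list class -> `W_c`), `classes`, `m`,
#'   `n_features_per_trial`.
#' @export
fit_csp_bank <- function(covs, labels = NULL, m = 2) {
  if (inherits(covs, "epoch_set")) {
    labels <- covs$labels
    covs <- trial_covariances(covs)
  }
  stopifnot(length(labels) == dim(covs)[1])
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  class_covs <- lapply(classes, function(cl) {
    class_covariance(covs[labels == cl, , , drop = FALSE])
  })
  names(class_covs) <- classes
  P <- csp_whitening(class_covs)
  W <- ovr_projections(class_covs, P)
  structure(list(whitening = P, projections = W, classes = classes,
                 m = m, n_features_per_trial = 2L * m),
            class = "spatial_filter_bank")
}

#' Log-variance-share CSP features of one trial
#'
#' Projects a trial onto the first `m` and last `m` spatial filters of `W`
#' and returns `log(var_j / sum(var))` over the `2m` selected components
#' (variance shares, so features are invariant to global amplitude).
#' Zero variances are floored at machine epsilon before the log.
#'
#' @param trial A `channels x samples` matrix, or an `N x N` trial covariance.
#' @param W Projection matrix for the target class (`N x N`).
#' @param m Filters per spectrum end (default 2).
#' @return Numeric feature vector of length `2m`.
#' @export
csp_features <- function(trial, W, m = 2) {
  r <- nrow(W)
  if (2 * m > r) stop("W has fewer than 2m rows")
  sel <- c(seq_len(m), (r - m + 1L):r)
  Ws <- W[sel, , drop = FALSE]
  v <- if (is.matrix(trial) && nrow(trial) == ncol(trial) &&
           nrow(trial) == ncol(W) &&
           isTRUE(all.equal(trial, t(trial), tolerance = 1e-6))) {
    rowSums((Ws %*% trial) * Ws)
  } else {
    y <- Ws %*% trial
    rowSums(y * y)
  }
  v <- pmax(v, .Machine$double.eps)
  log(v / sum(v))
}

# Batch feature extraction from a covariance stack: returns n x 2m matrix.
csp_features_cov <- function(covs, W, m = 2) {
  N <- ncol(W)                                       # channels
  r <- nrow(W)                                       # retained components
  n <- dim(covs)[1]
  sel <- c(seq_len(m), (r - m + 1L):r)
  Ws <- W[sel, , drop = FALSE]
  Cflat <- matrix(aperm(covs, c(2, 3, 1)), N)        # N x (N*n)
  tmp <- Ws %*% Cflat                                # 2m x (N*n)
  vars <- matrix(0, n, 2 * m)
  for (j in seq_len(2 * m)) {
    vars[, j] <- colSums(matrix(tmp[j, ], N) * Ws[j, ])
  }
  vars <- pmax(vars, .Machine$double.eps)
  log(vars / rowSums(vars))
}
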