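#' Train one user's target-vs-rest submodel
#'
#' The offline single-user pipeline: taking the target instruction's trials
#' as the positive class and the user's remaining instruction classes as the
#' negative class, fits one-vs-rest CSP filters (whitened over the subset's
#' class covariances), extracts `2m = 4` log-variance-share features, trains
#' a linear SVM, and computes the leave-one-out accuracy with the whole
#' pipeline (CSP + classifier) refitted inside every fold, so the held-out
#' trial never influences its fold's covariances. The accuracy-based weight
#' is `lambda = acc^2`.
#'
#' @param covs Covariance stack `[n x N x N]` from [trial_covariances()] of
#'   the user's training trials (already restricted to their instruction
#'   subset), or an `epoch_set`.
#' @param labels Instruction label per trial (ignored for an `epoch_set`).
#' @param target Target instruction; must occur in `labels` along with at
#'   least one other class.
#' @param user_id Optional identifier stored in the model.
#' @param m CSP filters per spectrum end (default 2).
#' @param cost SVM cost (default 1).
#' @param loo Compute the leave-one-out accuracy (default TRUE; turning it
#'   off leaves `acc`/`lambda` as `NA`, for callers that only need scores).
#' @return A list of class `submodel`: `user_id`, `target`, `subset`, `W`,
#'   `m`, `classifier`, `acc`, `lambda`.
#' @export
train_submodel <- function(covs, labels = NULL, target, user_id = NA,
                           m = 2, cost = 1, loo = TRUE) {
  if (inherits(covs, "epoch_set")) {
    labels <- covs$labels
    covs <- trial_covariances(covs)
  }
  n <- dim(covs)[1]
  N <- dim(covs)[2]
  stopifnot(length(labels) == n)
  classes <- sort(unique(labels))
  if (!(target %in% classes)) stop("target ", target, " not present in labels")
  if (length(classes) < 2) {
    stop("instruction subset of size 1: no negative class to train against")
  }
  cl_idx <- lapply(classes, function(cl) which(labels == cl))
  names(cl_idx) <- classes
  sums <- lapply(cl_idx, function(ix) {
    apply(covs[ix, , , drop = FALSE], c(2, 3), sum)
  })
  counts <- vapply(cl_idx, length, integer(1))
  if (any(counts < 2)) stop("every class needs >= 2 trials")

  fit_w <- function(drop_trial = NULL) {
    class_covs <- sums
    cnt <- counts
    if (!is.null(drop_trial)) {
      cl <- as.character(labels[drop_trial])
      class_covs[[cl]] <- class_covs[[cl]] - covs[drop_trial, , ]
      cnt[cl] <- cnt[cl] - 1L
    }
    class_covs <- Map(`/`, class_covs, as.list(cnt))
    P <- csp_whitening(class_covs)
    ovr_projections(class_covs[as.character(target)], P)[[1]]
  }

  Cflat <- matrix(aperm(covs, c(2, 3, 1)), N)     # N x (N*n)
  feats_all <- function(W) flat_features(Cflat, n, N, W, m)
  ylab <- ifelse(labels == target, "pos", "neg")

  W_full <- fit_w()
  F_full <- feats_all(W_full)
  clf <- fit_linear_classifier(F_full, ylab, cost = cost)

  acc <- NA_real_
  if (isTRUE(loo)) {
    correct <- logical(n)
    for (t in seq_len(n)) {
      Wt <- fit_w(t)
      Ft <- flat_features(Cflat, n, N, Wt, m)
      clf_t <- fit_linear_classifier(Ft[-t, , drop = FALSE], ylab[-t],
                                     cost = cost)
      pred_pos <- decision_values(clf_t, Ft[t, ]) > 0
      correct[t] <- pred_pos == (ylab[t] == "pos")
    }
    acc <- mean(correct)
  }
  structure(
    list(user_id = user_id, target = target, subset = classes, W = W_full,
         m = m, classifier = clf, acc = acc, lambda = acc^2),
    class = "submodel"
  )
}

# features for all n trials from a pre-flattened covariance stack
flat_features <- function(Cflat, n, N, W, m) {
  r <- nrow(W)
  sel <- c(seq_len(m), (r - m + 1L):r)
  Ws <- W[sel, , drop = FALSE]
  tmp <- Ws %*% Cflat
  vars <- matrix(0, n, 2 * m)
  for (j in seq_len(2 * m)) {
    vars[, j] <- colSums(matrix(tmp[j, ], N) * Ws[j, ])
  }
  vars <- pmax(vars, .Machine$double.eps)
  log(vars / rowSums(vars))
}

#' Decision value of a submodel on one trial
#'
#' @param submodel A `submodel`.
#' @param trial `channels x samples` matrix or `N x N` trial covariance.
#' @return Signed score; positive indicates the target instruction.
#' @export
submodel_score <- function(submodel, trial) {
  f <- csp_features(trial, submodel$W, submodel$m)
  decision_values(submodel$classifier, f)
}

#' Generic leave-one-out accuracy
#'
#' Evaluates a full training procedure by refitting it `n` times, each time
#' holding out one trial; no state is shared across folds, so the held-out
#' trial cannot leak into its fold's fit.
#'
#' @param labels True label per trial (length `n` = number of folds).
#' @param fit_predict Function `(train_idx, test_idx) -> predicted label`
#'   that trains on `train_idx` and predicts the single trial `test_idx`.
#' @return Fraction of held-out trials predicted correctly.
#' @export
loo_accuracy <- function(labels, fit_predict) {
  n <- length(labels)
  if (n < 2) stop("need >= 2 trials")
  correct <- vapply(seq_len(n), function(t) {
    isTRUE(fit_predict(setdiff(seq_len(n), t), t) == labels[t])
  }, logical(1))
  mean(correct)
}

#' Train the single-user six-class baseline
#'
#' The conventional single-user decoder: a full one-vs-rest CSP bank over
#' all six instructions and one linear SVM per instruction (positive: that
#' instruction's 72 training trials; negative: the remaining 360). A trial
#' is classified by the argmax of the six signed scores; ties go to the
#' lowest instruction number.
#'
#' @param covs Covariance stack `[n x N x N]` of training trials, or an
#'   `epoch_set`.
#' @param labels Instruction labels 1-6 (all six must be present).
#' @param m,cost See [train_submodel()].
#' @return A list of class `single_user_multiclass`.
#' @export
train_single_user_multiclass <- function(covs, labels = NULL, m = 2,
                                         cost = 1) {
  if (inherits(covs, "epoch_set")) {
    labels <- covs$labels
    covs <- trial_covariances(covs)
  }
  classes <- sort(unique(labels))
  if (!identical(as.integer(classes), 1:6)) {
    stop("all six instruction classes must be present; got: ",
         paste(classes, collapse = ","))
  }
  bank <- fit_csp_bank(covs, labels, m = m)
  clfs <- lapply(classes, function(cl) {
    W <- bank$projections[[as.character(cl)]]
    f <- csp_features_cov(covs, W, m)
    fit_linear_classifier(f, ifelse(labels == cl, "pos", "neg"), cost = cost)
  })
  names(clfs) <- classes
  structure(list(bank = bank, classifiers = clfs, classes = classes, m = m),
            class = "single_user_multiclass")
}

#' Predict instructions with the single-user six-class baseline
#'
#' @param model A `single_user_multiclass` model.
#' @param covs Trial covariance stack `[n x N x N]`, a single `N x N`
#'   covariance, or a `channels x samples` trial matrix.
#' @return Integer vector of predicted instruction numbers.
#' @export
predict_multiclass <- function(model, covs) {
  if (length(dim(covs)) == 2) {
    if (nrow(covs) != ncol(covs)) covs <- tcrossprod(covs) / sum(diag(tcrossprod(covs)))
    covs <- array(covs, c(1, dim(covs)))
  }
  scores <- vapply(model$classes, function(cl) {
    W <- model$bank$projections[[as.character(cl)]]
    decision_values(model$classifiers[[as.character(cl)]],
                    csp_features_cov(covs, W, model$m))
  }, numeric(dim(covs)[1]))
  scores <- matrix(scores, ncol = length(model$classes))
  apply(scores, 1, which.max)   # which.max takes the first (lowest) on ties
}
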