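#' Weighted average of member decision values
#'
#' The decision-fusion rule: `Dv = (1/5) * sum(lambda_i * dv_i)` over the
#' five members of a collaborative model.
#'
#' @param dv Numeric vector of member decision values.
#' @param lambda Accuracy-squared weights, same length.
#' @return Scalar fused decision value.
#' @export
fuse_decision_values <- function(dv, lambda) {
  if (length(dv) != length(lambda)) stop("dv and lambda lengths differ")
  sum(lambda * dv) / length(dv)
}

#' Train the fused classifier of one collaborative model (feature fusion)
#'
#' Builds the mode's fused training set: for every member user, the 4-dim
#' CSP features of their positive trials (their assigned instruction) and
#' negative trials (the other classes of their subset), scaled by the
#' member's weight `lambda_i`, are column-concatenated across the five users
#' into a 20-column matrix (72 positive / 144 negative rows at the "3 Tasks"
#' study defaults). Features are then ranked by mutual information with the
#' positive/negative label, the top `k_keep` are retained, and a linear SVM
#' is trained on them. The feature ranking, bin edges and member weights are
#' stored for pseudo-online use.
#'
#' Rows are aligned across users by index after shuffling every user's
#' positive (and negative) trials with the shared `pair_seed` - subjects were
#' recorded independently, so any pairing is exchangeable; a seeded shuffle
#' makes the convention reproducible.
#'
#' @param model A `collaborative_model` from [assemble_models()].
#' @param train_covs Named list (user -> list(`covs` trial-covariance stack,
#'   `labels`)) of each user's preprocessed training trials.
#' @param k_keep Fused features kept after MIM ranking (default 4).
#' @param n_bins Quantile bins for the MI estimate (default 10).
#' @param pair_seed Seed for the row-pairing shuffle (default 1).
#' @param cost SVM cost (default 1).
#' @return The model with `fusion` set: a list with `ranking`, `classifier`,
#'   `k_keep`, `n_fused` (20).
#' @export
train_feature_fusion <- function(model, train_covs, k_keep = 4, n_bins = 10,
                                 pair_seed = 1L, cost = 1) {
  stopifnot(inherits(model, "collaborative_model"))
  if (anyNA(model$lambda)) {
    stop("member submodels lack LOO accuracies (lambda is NA); ",
         "train them with loo = TRUE before feature fusion")
  }
  users <- names(model$members)
  rng <- local_rng(pair_seed)
  blocks_pos <- list()
  blocks_neg <- list()
  for (u in users) {
    sm <- model$members[[u]]
    dat <- train_covs[[u]]
    pos_idx <- which(dat$labels == sm$target)
    neg_idx <- which(dat$labels %in% setdiff(sm$subset, sm$target))
    pos_idx <- pos_idx[sample.int(length(pos_idx))]
    neg_idx <- neg_idx[sample.int(length(neg_idx))]
    fp <- csp_features_cov(dat$covs[pos_idx, , , drop = FALSE], sm$W, sm$m)
    fn <- csp_features_cov(dat$covs[neg_idx, , , drop = FALSE], sm$W, sm$m)
    blocks_pos[[u]] <- sm$lambda * fp
    blocks_neg[[u]] <- sm$lambda * fn
  }
  restore_rng(rng)
  npos <- unique(vapply(blocks_pos, nrow, integer(1)))
  nneg <- unique(vapply(blocks_neg, nrow, integer(1)))
  if (length(npos) != 1 || length(nneg) != 1) {
    stop("row-count mismatch across users: positive ",
         paste(vapply(blocks_pos, nrow, integer(1)), collapse = "/"),
         ", negative ",
         paste(vapply(blocks_neg, nrow, integer(1)), collapse = "/"))
  }
  fused <- rbind(do.call(cbind, blocks_pos), do.call(cbind, blocks_neg))
  ylab <- c(rep("pos", npos), rep("neg", nneg))
  ranking <- rank_and_select(fused, ylab, k = k_keep, n_bins = n_bins)
  clf <- fit_linear_classifier(fused[, ranking$selected, drop = FALSE], ylab,
                               cost = cost)
  model$fusion <- list(ranking = ranking, classifier = clf,
                       k_keep = as.integer(k_keep), n_fused = ncol(fused))
  model$method <- "feature"
  model
}

# fused 1 x (5*2m) feature row of one group trial under one model
fused_feature_row <- function(model, group_trial) {
  unlist(lapply(names(model$members), function(u) {
    sm <- model$members[[u]]
    sm$lambda * csp_features(group_trial$trials[[u]], sm$W, sm$m)
  }), use.names = FALSE)
}

#' A single multi-user group trial
#'
#' @param trials Named list (user -> `channels x samples` matrix or `N x N`
#'   trial covariance), one entry per user slot in scheme order.
#' @param true_label True input instruction (optional, for scoring).
#' @return A list of class `group_trial`.
#' @export
group_trial <- function(trials, true_label = NA_integer_) {
  if (length(trials) != 5) stop("a group trial has exactly 5 user entries")
  structure(list(trials = trials, true_label = as.integer(true_label)),
            class = "group_trial")
}

#' Pseudo-online prediction by feature fusion
#'
#' For each of the six trained collaborative models: each member's CSP
#' filters turn their user's trial into a 1x4 feature row, the rows are
#' lambda-scaled and concatenated to 1x20, reordered by that model's stored
#' feature ranking, truncated to the top 4, and scored by the model's fused
#' SVM. The predicted instruction is the argmax of the six decision values
#' (ties go to the lowest instruction number); if no value is positive the
#' argmax is still returned with `no_positive = TRUE`, since a forced-choice
#' system must output an instruction.
#'
#' @param models List of six `collaborative_model`s with trained `fusion`.
#' @param gtrial A [group_trial()].
#' @return A `decision_record`: `Dv` (named numeric, one per instruction),
#'   `predicted`, `no_positive`, `method`.
#' @export
predict_feature_fusion <- function(models, gtrial) {
  stopifnot(length(models) == 6, inherits(gtrial, "group_trial"))
  Dv <- vapply(models, function(mod) {
    if (is.null(mod$fusion)) stop("feature-fusion model not trained")
    row <- fused_feature_row(mod, gtrial)
    sel <- mod$fusion$ranking$selected
    decision_values(mod$fusion$classifier, row[sel])
  }, numeric(1))
  names(Dv) <- vapply(models, function(m) m$mode$input_instruction, integer(1))
  decision_record(Dv, method = "feature")
}

#' Pseudo-online prediction by decision fusion
#'
#' For each collaborative model, every member submodel scores its own user's
#' trial (signed SVM decision value `dv_i`); the model's fused value is
#' `Dv = (1/5) * sum(lambda_i * dv_i)`. The predicted instruction is the
#' argmax of the six `Dv` (ties to the lowest instruction; `no_positive`
#' flagged when all six are negative). The per-member decision values and
#' positive-label counts are kept in the record for audit.
#'
#' @param models List of six `collaborative_model`s (decision fusion needs
#'   no extra training beyond the member submodels).
#' @param gtrial A [group_trial()].
#' @return A `decision_record` with additional fields `dv_members`
#'   (6 x 5 matrix) and `positive_counts`.
#' @export
predict_decision_fusion <- function(models, gtrial) {
  stopifnot(length(models) == 6, inherits(gtrial, "group_trial"))
  users <- names(models[[1]]$members)
  dvm <- t(vapply(models, function(mod) {
    vapply(users, function(u) {
      submodel_score(mod$members[[u]], gtrial$trials[[u]])
    }, numeric(1))
  }, numeric(5)))
  Dv <- vapply(seq_along(models), function(i) {
    fuse_decision_values(dvm[i, ], models[[i]]$lambda)
  }, numeric(1))
  names(Dv) <- vapply(models, function(m) m$mode$input_instruction, integer(1))
  rec <- decision_record(Dv, method = "decision")
  rec$dv_members <- dvm
  rec$positive_counts <- rowSums(dvm > 0)
  rec
}

decision_record <- function(Dv, method) {
  best <- which.max(Dv)    # first (lowest instruction) wins ties
  structure(
    list(Dv = Dv, predicted = as.integer(names(Dv)[best]),
         no_positive = all(Dv <= 0), method = method),
    class = "decision_record"
  )
}

#' @export
print.decision_record <- function(x, ...) {
  cat("<decision_record> method =", x$method, "\n  Dv:",
      paste(sprintf("%s:%.3f", names(x$Dv), x$Dv), collapse = " "),
      "\n  predicted:", x$predicted,
      if (x$no_positive) "(no positive decision value)" else "", "\n")
  invisible(x)
}
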