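#' Sample random ordered five-user selections
#'
#' Draws `n_selections` distinct ordered 5-tuples (permutations of 5 out of
#' `n_subjects`) uniformly without replacement. With the cyclic allocation,
#' user order matters for `k < 6`, so selections are counted as permutations:
#' 19 subjects give `19*18*17*16*15 = 1,395,360` possible selections.
#'
#' @param n_subjects Cohort size (>= 5).
#' @param n_selections Number of distinct selections to draw.
#' @param seed Integer seed.
#' @return List of integer 5-vectors (subject indices, ordered A-E).
#' @export
sample_groups <- function(n_subjects, n_selections, seed = 1L) {
  if (n_subjects < 5) stop("n_subjects must be >= 5")
  total <- prod(n_subjects - 0:4)
  if (n_selections > total) {
    stop("n_selections (", n_selections, ") exceeds the permutation count (",
         total, ")")
  }
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  if (total <= 20000) {
    # enumerate and sample exactly
    all_perms <- perms_5(n_subjects)
    pick <- sample.int(nrow(all_perms), n_selections)
    return(lapply(pick, function(i) all_perms[i, ]))
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", n_selections)
  got <- 0L
  while (got < n_selections) {
    tup <- sample.int(n_subjects, 5)
    key <- paste(tup, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- tup
    }
  }
  out
}

# all ordered 5-tuples from n subjects (row-wise)
perms_5 <- function(n) {
  idx <- seq_len(n)
  out <- matrix(0L, 0, 5)
  grid <- expand.grid(a = idx, b = idx, c = idx, d = idx, e = idx)
  keep <- apply(grid, 1, function(r) length(unique(r)) == 5)
  as.matrix(grid[keep, 5:1, drop = FALSE]) -> m
  colnames(m) <- NULL
  m
}

#' Preprocess and split one subject for pseudo-online evaluation
#'
#' Applies the conditioning chain (CAR, 8-28 Hz zero-phase band-pass, crop
#' to the 4-s MI window), performs the stratified 72/12 train/test split,
#' and precomputes per-trial covariances so all downstream CSP work is
#' covariance-based.
#'
#' @param epochs The subject's raw `epoch_set` (e.g. from
#'   [generate_subject()]).
#' @param split_seed Seed for the train/test split.
#' @param n_train_per_class,n_test_per_class Split sizes (default 72 / all
#'   remaining).
#' @return A list of class `prepared_subject`: `train` (list `covs`,
#'   `labels`), `test` (list `covs`, `labels`, `by_class` index list),
#'   `n_channels`, `split_seed`.
#' @export
prepare_subject <- function(epochs, split_seed = 1L, n_train_per_class = 72,
                            n_test_per_class = NULL) {
  pp <- preprocess_epochs(epochs)
  sp <- split_train_test(pp, n_train_per_class, n_test_per_class, split_seed)
  test_labels <- sp$test$labels
  by_class <- lapply(sort(unique(test_labels)),
                     function(cl) which(test_labels == cl))
  names(by_class) <- sort(unique(test_labels))
  structure(
    list(train = list(covs = trial_covariances(sp$train),
                      labels = sp$train$labels),
         test = list(covs = trial_covariances(sp$test),
                     labels = test_labels, by_class = by_class),
         n_channels = length(epochs$channel_names),
         split_seed = split_seed),
    class = "prepared_subject"
  )
}

#' Submodel cache for repeated group evaluations
#'
#' Submodels depend only on (subject, subset, target), so across hundreds of
#' random group selections the same submodel recurs many times; this cache
#' trains each once. Keys combine the subject index, the subset and the
#' target instruction.
#'
#' @return An environment usable as the `cache` argument of
#'   [run_pseudo_online()] and [accuracy_curve()].
#' @export
submodel_cache <- function() new.env(hash = TRUE, parent = emptyenv())

get_submodel <- function(cache, prepared, subj_id, subset, target,
                         cost = 1, m = 2) {
  key <- paste(subj_id, paste(subset, collapse = "."), target, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  tr <- prepared$train
  keep <- tr$labels %in% subset
  sm <- train_submodel(tr$covs[keep, , , drop = FALSE], tr$labels[keep],
                       target = target, user_id = subj_id, m = m, cost = cost)
  if (!is.null(cache)) cache[[key]] <- sm
  sm
}

#' Run one pseudo-online collaborative evaluation
#'
#' For an ordered group of five prepared subjects and a k-Tasks strategy:
#' builds the allocation scheme and the six collaborative modes, trains (or
#' fetches from `cache`) the member submodels, assembles the six
#' collaborative models (training the fused classifiers for feature fusion),
#' then replays held-out trials: for each input instruction, the j-th test
#' trial of every user's assigned class forms the j-th group trial (12 per
#' instruction at defaults, 72 in total), and the fraction predicted
#' correctly is the accuracy.
#'
#' @param prepared_group List of 5 `prepared_subject`s, in user order A-E.
#' @param k Tasks per user (2-6).
#' @param method `"decision"` or `"feature"`.
#' @param subject_ids Identifiers of the five subjects (cache keys).
#' @param reference Reference instruction (default 2).
#' @param cache Optional [submodel_cache()].
#' @param pair_seed Seed for feature-fusion row pairing.
#' @param cost SVM cost.
#' @return A list: `accuracy`, `n_group_trials`, `records` (per-trial
#'   `decision_record`s), `truth`.
#' @export
run_pseudo_online <- function(prepared_group, k,
                              method = c("decision", "feature"),
                              subject_ids = seq_along(prepared_group),
                              reference = 2, cache = NULL, pair_seed = 1L,
                              cost = 1) {
  method <- match.arg(method)
  stopifnot(length(prepared_group) == 5)
  scheme <- build_scheme(k, reference = reference)
  user_models <- list()
  for (i in seq_len(5)) {
    u <- scheme$users[i]
    subset <- scheme$subsets[[u]]
    sms <- lapply(subset, function(target) {
      get_submodel(cache, prepared_group[[i]], subject_ids[i], subset, target,
                   cost = cost)
    })
    names(sms) <- subset
    user_models[[u]] <- sms
  }
  models <- assemble_models(scheme, user_models, method = method)
  if (method == "feature") {
    train_covs <- structure(lapply(seq_len(5), function(i) {
      prepared_group[[i]]$train
    }), names = scheme$users)
    models <- lapply(models, train_feature_fusion, train_covs = train_covs,
                     pair_seed = pair_seed, cost = cost)
  }
  modes <- build_modes(scheme)
  n_rep <- min(vapply(seq_len(5), function(i) {
    min(lengths(prepared_group[[i]]$test$by_class))
  }, numeric(1)))

  # batch over test trials: for every (model, user) pair, features (and for
  # decision fusion, scores) of that user's whole test set under the
  # member's filters, computed once
  per_member <- lapply(models, function(mod) {
    lapply(seq_len(5), function(i) {
      sm <- mod$members[[scheme$users[i]]]
      f <- csp_features_cov(prepared_group[[i]]$test$covs, sm$W, sm$m)
      if (method == "decision") {
        list(scores = decision_values(sm$classifier, f))
      } else {
        list(features = sm$lambda * f)
      }
    })
  })

  truth <- integer(0)
  records <- list()
  for (mode in modes) {
    instr <- mode$input_instruction
    # index of the trial each user contributes, per repetition
    idx_mat <- vapply(seq_len(5), function(i) {
      cl <- as.character(mode$assignment[[scheme$users[i]]])
      prepared_group[[i]]$test$by_class[[cl]][seq_len(n_rep)]
    }, integer(n_rep))
    idx_mat <- matrix(idx_mat, nrow = n_rep)
    for (j in seq_len(n_rep)) {
      if (method == "decision") {
        dvm <- t(vapply(seq_along(models), function(m) {
          vapply(seq_len(5), function(i) {
            per_member[[m]][[i]]$scores[idx_mat[j, i]]
          }, numeric(1))
        }, numeric(5)))
        Dv <- vapply(seq_along(models), function(m) {
          fuse_decision_values(dvm[m, ], models[[m]]$lambda)
        }, numeric(1))
        names(Dv) <- vapply(models, function(m) m$mode$input_instruction,
                            integer(1))
        rec <- decision_record(Dv, method = "decision")
        rec$dv_members <- dvm
        rec$positive_counts <- rowSums(dvm > 0)
      } else {
        Dv <- vapply(seq_along(models), function(m) {
          row <- unlist(lapply(seq_len(5), function(i) {
            per_member[[m]][[i]]$features[idx_mat[j, i], ]
          }), use.names = FALSE)
          sel <- models[[m]]$fusion$ranking$selected
          decision_values(models[[m]]$fusion$classifier, row[sel])
        }, numeric(1))
        names(Dv) <- vapply(models, function(m) m$mode$input_instruction,
                            integer(1))
        rec <- decision_record(Dv, method = "feature")
      }
      records[[length(records) + 1L]] <- rec
      truth <- c(truth, instr)
    }
  }
  pred <- vapply(records, function(r) r$predicted, integer(1))
  list(accuracy = mean(pred == truth), n_group_trials = length(truth),
       records = records, truth = truth)
}

#' Experiment configuration for the accuracy-vs-allocation sweep
#'
#' @param n_selections Random group selections (default 300, as in the
#'   original experiment; reduce for desk-scale runs).
#' @param strategies k values to sweep (default 2:6).
#' @param methods Fusion methods (default both).
#' @param master_seed Seed controlling group sampling and pairing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_selections = 300, strategies = 2:6,
                              methods = c("feature", "decision"),
                              master_seed = 1L) {
  if (n_selections < 1) stop("n_selections must be >= 1")
  if (!all(strategies %in% 2:6)) stop("strategies must be within 2..6")
  structure(list(n_selections = as.integer(n_selections),
                 strategies = as.integer(strategies),
                 methods = match.arg(methods, c("feature", "decision"),
                                     several.ok = TRUE),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Accuracy-versus-tasks-per-user curve
#'
#' The full sweep: draws the group selections once (shared across strategies
#' and methods, a paired design that lowers comparison variance), evaluates
#' every (method, k) cell by pseudo-online classification, and adds the
#' single-user six-class baseline (mean +- sd across subjects, independent
#' of k). Per-selection accuracies are aggregated to mean and sd per cell.
#'
#' @param prepared_cohort List of `prepared_subject`s (the whole cohort).
#' @param config An [experiment_config()].
#' @param reference Reference instruction (default 2).
#' @param cache Optional [submodel_cache()] reused across cells.
#' @param verbose Print progress (default FALSE).
#' @return A list of class `result_table`: `table` (data.frame with columns
#'   method, k, mean_accuracy, sd_accuracy, n_selections), `per_selection`
#'   (list of per-cell accuracy vectors), `baseline` (list mean, sd,
#'   per_subject).
#' @export
accuracy_curve <- function(prepared_cohort, config = experiment_config(),
                           reference = 2, cache = submodel_cache(),
                           verbose = FALSE) {
  groups <- sample_groups(length(prepared_cohort), config$n_selections,
                          seed = config$master_seed)
  rows <- list()
  per_sel <- list()
  for (method in config$methods) {
    for (k in config$strategies) {
      accs <- vapply(seq_along(groups), function(g) {
        run_pseudo_online(prepared_cohort[groups[[g]]], k, method,
                          subject_ids = groups[[g]], reference = reference,
                          cache = cache,
                          pair_seed = config$master_seed + g)$accuracy
      }, numeric(1))
      cell <- paste(method, k, sep = "_")
      per_sel[[cell]] <- accs
      rows[[cell]] <- data.frame(
        method = method, k = k, mean_accuracy = mean(accs),
        sd_accuracy = stats::sd(accs), n_selections = length(accs)
      )
      if (verbose) {
        message(sprintf("%s k=%d: %.1f%% +- %.1f%%", method, k,
                        100 * mean(accs), 100 * stats::sd(accs)))
      }
    }
  }
  base_acc <- vapply(prepared_cohort, function(ps) {
    model <- train_single_user_multiclass(ps$train$covs, ps$train$labels)
    mean(predict_multiclass(model, ps$test$covs) == ps$test$labels)
  }, numeric(1))
  structure(
    list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
         per_selection = per_sel,
         baseline = list(mean = mean(base_acc), sd = stats::sd(base_acc),
                         per_subject = base_acc)),
    class = "result_table"
  )
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table> collaborative accuracy by strategy\n")
  tab <- x$table
  tab$mean_accuracy <- sprintf("%.1f%%", 100 * tab$mean_accuracy)
  tab$sd_accuracy <- sprintf("%.1f%%", 100 * tab$sd_accuracy)
  print(tab, row.names = FALSE)
  cat(sprintf("single-user baseline: %.1f%% +- %.1f%%\n",
              100 * x$baseline$mean, 100 * x$baseline$sd))
  invisible(x)
}

#' Shuffle the labels of an epoch set
#'
#' Null-calibration helper: randomly permutes trial labels, destroying the
#' label-signal association while keeping the signal statistics.
#'
#' @param epochs An `epoch_set`.
#' @param seed Integer seed.
#' @return The `epoch_set` with permuted labels.
#' @export
shuffle_labels <- function(epochs, seed = 1L) {
  rng <- local_rng(seed)
  epochs$labels <- epochs$labels[sample.int(length(epochs$labels))]
  restore_rng(rng)
  epochs
}
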