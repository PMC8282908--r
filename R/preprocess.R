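#' Common average reference
#'
#' Re-references every sample to the instantaneous mean across channels, so
#' that at every time point the channel mean is zero. CAR is linear and
#' idempotent.
#'
#' @param epochs An `epoch_set` with at least two channels.
#' @return The re-referenced `epoch_set`.
#' @export
common_average_reference <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2] < 2) stop("common average reference needs >= 2 channels")
  x <- epochs$data
  # mean over channels for every (trial, sample)
  m <- colMeans(aperm(x, c(2, 1, 3)))          # n_trials x n_samples
  x <- x - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs$data <- x
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 8-28 Hz, order 4) to every trial
#' and channel. Filtering is zero-phase (forward-backward, `signal::filtfilt`)
#' so the MI window is not delayed; the effective magnitude order is twice the
#' design order.
#'
#' @param epochs An `epoch_set`.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#' @return The filtered `epoch_set`.
#' @export
bandpass_epochs <- function(epochs, low = 8, high = 28, order = 4) {
  fs <- epochs$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid band: need 0 < low < high < fs/2 = ", fs / 2)
  }
  bf <- butter_ba(order, c(low, high) / (fs / 2), type = "pass")
  d <- dim(epochs$data)
  x <- epochs$data
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x[tr, ch, ] <- iir_filtfilt(bf$b, bf$a, x[tr, ch, ])
    }
  }
  epochs$data <- x
  epochs
}

#' Stratified train/test split of one subject's trials
#'
#' Randomly assigns `n_train_per_class` trials of every class to the training
#' set and all remaining trials of that class to the test set (72/12 at the
#' study design of 84 trials per class). The split is stratified: the stated
#' per-class counts force it.
#'
#' @param epochs An `epoch_set`.
#' @param n_train_per_class Training trials per class (default 72).
#' @param n_test_per_class Test trials per class; defaults to all remaining.
#' @param seed Integer seed making the split reproducible.
#' @return A list of class `train_test_split` with elements `train`, `test`
#'   (both `epoch_set`), `train_idx`, `test_idx`, `seed`.
#' @export
split_train_test <- function(epochs, n_train_per_class = 72,
                             n_test_per_class = NULL, seed = 1L) {
  labs <- epochs$labels
  classes <- sort(unique(labs))
  counts <- table(labs)
  need <- n_train_per_class + max(1L, if (is.null(n_test_per_class)) 1L else n_test_per_class)
  for (cl in classes) {
    if (counts[[as.character(cl)]] < need) {
      stop("class ", cl, " has only ", counts[[as.character(cl)]],
           " trials; need at least ", need)
    }
  }
  rng <- local_rng(seed)
  train_idx <- integer(0)
  test_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labs == cl)
    perm <- idx[sample.int(length(idx))]
    tr <- perm[seq_len(n_train_per_class)]
    te <- perm[-seq_len(n_train_per_class)]
    if (!is.null(n_test_per_class)) te <- te[seq_len(n_test_per_class)]
    train_idx <- c(train_idx, tr)
    test_idx <- c(test_idx, te)
  }
  restore_rng(rng)
  train_idx <- sort(train_idx)
  test_idx <- sort(test_idx)
  structure(
    list(train = subset_trials(epochs, train_idx),
         test = subset_trials(epochs, test_idx),
         train_idx = train_idx, test_idx = test_idx, seed = seed),
    class = "train_test_split"
  )
}

#' Standard preprocessing chain
#'
#' Convenience wrapper reproducing the offline conditioning: common average
#' reference, zero-phase 8-28 Hz Butterworth band-pass, and cropping to the
#' 4-s MI window `[0, 4)` (800 samples at 200 Hz).
#'
#' @param epochs An `epoch_set` (typically from [generate_subject()]).
#' @param low,high,order Band-pass parameters, see [bandpass_epochs()].
#' @param mi_window MI window to crop to; `NULL` keeps the full epoch.
#' @return A preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, low = 8, high = 28, order = 4,
                              mi_window = c(0, 4)) {
  out <- bandpass_epochs(common_average_reference(epochs), low, high, order)
  if (!is.null(mi_window)) out <- crop_epochs(out, mi_window)
  out
}

# Seed scoping: run a block under a given seed without clobbering the
# caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
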