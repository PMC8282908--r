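#' Construct an epoched EEG set
#'
#' The universal exchange object of the package: a stack of labelled EEG
#' trials from one subject. Trials are stored as a numeric array
#' `[n_trials x n_channels x n_samples]`; labels are instruction numbers 1-6
#' (1 both hands, 2 both feet, 3 left hand, 4 right hand, 5 right hand + left
#' foot, 6 left hand + right foot).
#'
#' @param data Numeric array `[n_trials x n_channels x n_samples]`.
#' @param labels Integer vector of instruction numbers, one per trial.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one unique name per channel.
#' @param epoch_window Length-2 numeric, `(start_s, end_s)` of the stored
#'   samples relative to instruction onset; the MI window is `[0, 4)`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_names,
                      epoch_window = c(0, dim(data)[3] / fs)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  n_channels <- dim(data)[2]
  n_samples <- dim(data)[3]
  labels <- as.integer(labels)
  if (length(labels) != n_trials) {
    stop("labels length (", length(labels), ") != n_trials (", n_trials, ")")
  }
  if (anyNA(labels) || any(labels < 1L)) stop("labels must be positive integers")
  if (length(channel_names) != n_channels) {
    stop("channel_names length != n_channels")
  }
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  epoch_window <- as.numeric(epoch_window)
  if (length(epoch_window) != 2 || diff(epoch_window) <= 0) {
    stop("epoch_window must be (start_s, end_s) with end > start")
  }
  expected <- round(diff(epoch_window) * fs)
  if (expected != n_samples) {
    stop("n_samples (", n_samples, ") does not equal (end_s - start_s) * fs (",
         expected, ")")
  }
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names),
         epoch_window = epoch_window),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  window [", x$epoch_window[1], ", ", x$epoch_window[2],
      ") s; classes: ", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset trials of an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param idx Trial indices (integer or logical).
#' @return An `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
            epochs$fs, epochs$channel_names, epochs$epoch_window)
}

#' Crop an epoch set to a time window
#'
#' Times are relative to instruction onset; the window is half-open
#' `[start, end)`, so cropping a 200 Hz set to `c(0, 4)` keeps exactly 800
#' samples.
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 numeric `(start_s, end_s)`; must lie inside the
#'   stored `epoch_window`.
#' @return A cropped `epoch_set`.
#' @export
crop_epochs <- function(epochs, window = c(0, 4)) {
  w0 <- epochs$epoch_window
  if (window[1] < w0[1] - 1e-9 || window[2] > w0[2] + 1e-9) {
    stop("requested window [", window[1], ", ", window[2],
         ") outside stored window [", w0[1], ", ", w0[2], ")")
  }
  i0 <- round((window[1] - w0[1]) * epochs$fs) + 1L
  i1 <- round((window[2] - w0[1]) * epochs$fs)
  epoch_set(epochs$data[, , i0:i1, drop = FALSE], epochs$labels, epochs$fs,
            epochs$channel_names, window)
}

#' Index of a channel by name
#' @param epochs An `epoch_set`.
#' @param channel Channel name.
#' @return Integer index.
#' @export
channel_index <- function(epochs, channel) {
  i <- match(channel, epochs$channel_names)
  if (is.na(i)) stop("channel '", channel, "' not in epoch set")
  i
}
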