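#' Event-related spectral perturbation map for one channel
#'
#' Trial-averaged, baseline-normalized time-frequency power: per trial the
#' squared magnitude of a short-time Fourier estimate (0.5-s Hann window,
#' 90% overlap) is computed, averaged over trials, and expressed in dB
#' relative to the per-frequency mean power of the baseline window
#' (`10 * log10(P / P_baseline)`; negative values are ERD, positive ERS).
#'
#' @param trials An `epoch_set` whose `epoch_window` covers the baseline
#'   (e.g. `(-1, 4)`); typically restricted to one class, or pooled.
#' @param channel Channel name.
#' @param freqs Frequencies (Hz) to keep, mapped to the nearest FFT bin
#'   (2 Hz resolution at the default window); default `seq(8, 28, 2)`.
#' @param baseline_window Length-2 numeric, baseline period in seconds
#'   relative to MI onset (default `c(-1, 0)`, the 1 s before the epoch);
#'   must end at or before 0 and lie inside the stored window.
#' @param window_s STFT window length in seconds (default 0.5).
#' @param overlap Fractional window overlap (default 0.9).
#' @return A list of class `tf_map`: `values` (dB matrix
#'   `[n_freqs x n_times]`), `freqs`, `times` (window centers, s relative to
#'   onset), `channel`, `n_trials`.
#' @export
compute_ersp <- function(trials, channel, freqs = seq(8, 28, 2),
                         baseline_window = c(-1, 0), window_s = 0.5,
                         overlap = 0.9) {
  stopifnot(inherits(trials, "epoch_set"))
  fs <- trials$fs
  ch <- channel_index(trials, channel)
  w0 <- trials$epoch_window
  if (baseline_window[1] < w0[1] - 1e-9 || baseline_window[2] > w0[2] + 1e-9) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         "] outside available data [", w0[1], ", ", w0[2], "]")
  }
  if (baseline_window[2] > 0) stop("baseline window must precede MI onset")
  nwin <- round(window_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  nsamp <- dim(trials$data)[3]
  starts <- seq(1L, nsamp - nwin + 1L, by = hop)
  times <- w0[1] + (starts - 1L + (nwin - 1) / 2) / fs
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  fbin <- round(freqs * nwin / fs) + 1L
  if (any(fbin > floor(nwin / 2) + 1L)) stop("requested frequency above Nyquist")
  n <- n_trials(trials)
  P <- matrix(0, length(freqs), length(starts))
  for (tr in seq_len(n)) {
    x <- trials$data[tr, ch, ]
    segs <- vapply(starts, function(s) x[s:(s + nwin - 1L)] * han,
                   numeric(nwin))
    sp <- stats::mvfft(segs)
    P <- P + abs(sp[fbin, , drop = FALSE])^2
  }
  P <- P / n
  in_base <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(in_base)) stop("no STFT windows fall inside the baseline window")
  Pb <- rowMeans(P[, in_base, drop = FALSE])
  vals <- 10 * log10(sweep(P, 1, Pb, "/"))
  structure(list(values = vals, freqs = freqs, times = times,
                 channel = channel, n_trials = n),
            class = "tf_map")
}

#' Scalar ERD value of a time-frequency map
#'
#' The arithmetic mean of the baseline-normalized map over a frequency band
#' and time window (the 4-s MI task period by default); negative values
#' indicate ERD.
#'
#' @param map A `tf_map` from [compute_ersp()].
#' @param band Length-2 numeric, frequency band in Hz (alpha `c(8, 13)` or
#'   beta `c(14, 25)`).
#' @param window Length-2 numeric, time window in seconds (default the MI
#'   period `c(0, 4)`).
#' @return Scalar mean dB value over the selected bins.
#' @export
erd_value <- function(map, band = c(8, 13), window = c(0, 4)) {
  fi <- map$freqs >= band[1] & map$freqs <= band[2]
  ti <- map$times >= window[1] & map$times <= window[2]
  if (!any(fi) || !any(ti)) {
    stop("empty band/window selection: band [", band[1], ", ", band[2],
         "] Hz, window [", window[1], ", ", window[2], "] s")
  }
  mean(map$values[fi, ti])
}

#' Per-channel ERD topography of a cohort
#'
#' For one instruction class, computes the scalar ERD value (band x MI
#' window mean of the baseline-normalized ERSP) at every channel, averaged
#' over trials within subject and then over subjects.
#'
#' @param cohort List of `epoch_set`s with baseline (e.g. raw generator
#'   output, optionally CAR-referenced; band-pass filtering would remove the
#'   out-of-band reference and is not applied here).
#' @param class_id Instruction class 1-6.
#' @param band Frequency band in Hz (default alpha `c(8, 13)`).
#' @param window MI window (default `c(0, 4)`).
#' @return A data.frame with columns `channel`, `erd` (mean dB).
#' @export
erd_topography <- function(cohort, class_id, band = c(8, 13),
                           window = c(0, 4)) {
  if (length(cohort) == 0) stop("cohort is empty")
  channels <- cohort[[1]]$channel_names
  vals <- matrix(0, length(cohort), length(channels))
  for (s in seq_along(cohort)) {
    es <- cohort[[s]]
    cls <- subset_trials(es, es$labels == class_id)
    for (ci in seq_along(channels)) {
      m <- compute_ersp(cls, channels[ci])
      vals[s, ci] <- erd_value(m, band = band, window = window)
    }
  }
  data.frame(channel = channels, erd = colMeans(vals),
             stringsAsFactors = FALSE)
}
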