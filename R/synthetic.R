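#' Simulation configuration for the synthetic ERD-EEG generator
#'
#' Bundles the design constants of the simulated motor-imagery study: a
#' session of `n_blocks` blocks, each holding `trials_per_class_per_block`
#' trials of every one of the six instructions in random order, recorded at
#' `fs_raw` and decimated to `fs_target`, with a 4-s MI epoch preceded by a
#' 1-s baseline. The defaults reproduce the study design: 14 blocks x 36
#' trials = 84 trials per class, 60 channels, 1000 Hz acquisition downsampled
#' to 200 Hz.
#'
#' `erd_depth` gives, per class, the fractional attenuation of sensorimotor
#' rhythm amplitude at the most involved channel during the MI window
#' (0 = no ERD). `snr` is the ratio of rhythm amplitude (standard deviation)
#' to broadband noise amplitude per channel. `subject_variability` is the
#' standard deviation of a per-subject multiplicative gain applied to
#' `erd_depth`.
#'
#' @param n_channels Montage size (see [bci_montage()]); default 60.
#' @param fs_raw Acquisition sampling rate in Hz (default 1000).
#' @param fs_target Analysis sampling rate in Hz (default 200); must divide
#'   `fs_raw`.
#' @param n_blocks Blocks per session (default 14).
#' @param trials_per_class_per_block Trials of each class in a block
#'   (default 6).
#' @param epoch_seconds MI epoch duration in s (default 4).
#' @param baseline_seconds Pre-task baseline carried with each trial (default 1).
#' @param erd_depth Named numeric of length 6 (classes "1".."6"), each in
#'   `[0, 1)`.
#' @param snr Rhythm-to-noise amplitude ratio (default 0.7).
#' @param subject_variability Std of per-subject gain on `erd_depth`
#'   (default 0.2).
#' @param focus_jitter Std (head-radius units) of the per-trial spatial
#'   wander of the ERD focus (default 0.3); the main source of
#'   between-class confusion, mimicking the trial-to-trial variability of
#'   real sensorimotor ERD.
#' @param erd_trial_variability Lognormal std of the per-trial ERD depth
#'   gain (default 0.3).
#' @param seed Integer base seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 60, fs_raw = 1000, fs_target = 200,
                       n_blocks = 14, trials_per_class_per_block = 6,
                       epoch_seconds = 4, baseline_seconds = 1,
                       erd_depth = c("1" = 0.55, "2" = 0.40, "3" = 0.55,
                                     "4" = 0.55, "5" = 0.55, "6" = 0.55),
                       snr = 0.7, subject_variability = 0.2,
                       focus_jitter = 0.3, erd_trial_variability = 0.3,
                       seed = 1L) {
  if (fs_raw %% fs_target != 0) stop("fs_raw must be divisible by fs_target")
  erd_depth <- erd_depth[as.character(1:6)]
  if (anyNA(erd_depth)) stop("erd_depth must name all classes 1..6")
  if (any(erd_depth < 0 | erd_depth >= 1)) stop("erd_depth values must be in [0, 1)")
  if (snr < 0) stop("snr must be non-negative")
  structure(
    list(n_channels = as.integer(n_channels), fs_raw = fs_raw,
         fs_target = fs_target, n_blocks = as.integer(n_blocks),
         trials_per_class_per_block = as.integer(trials_per_class_per_block),
         epoch_seconds = epoch_seconds, baseline_seconds = baseline_seconds,
         erd_depth = erd_depth, snr = snr,
         subject_variability = subject_variability,
         focus_jitter = focus_jitter,
         erd_trial_variability = erd_trial_variability,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Planted ERD scalp topography for one instruction
#'
#' Returns the per-channel attenuation map (weights in `[0, 1]`) describing
#' where the generator plants event-related desynchronization for a class.
#' Maps follow the motor homunculus as seen in sensorimotor EEG: unilateral
#' hand imagery attenuates the contralateral hand area (left hand -> C4
#' cluster, right hand -> C3 cluster), both hands attenuate both, both feet
#' get a small midline patch near Cz (foot cortex is mesial, so its scalp ERD
#' is the weakest of the six classes), and the hand-plus-opposite-foot
#' compounds combine one hand cluster with the midline foot weight.
#'
#' @param class_id Instruction number 1-6 (1 BH, 2 BF, 3 LH, 4 RH, 5 RHLF,
#'   6 LHRF).
#' @param channel_names 10/20 channel names; must include C3, C4 and Cz.
#' @return A list of class `spatial_topography` with fields `class_id` and
#'   `attenuation_map` (named numeric, one weight per channel).
#' @export
planted_topography <- function(class_id, channel_names) {
  if (!is.numeric(class_id) || length(class_id) != 1 ||
      !(class_id %in% 1:6)) {
    stop("class_id must be a single instruction number in 1..6, got: ",
         paste(class_id, collapse = ","))
  }
  if (!all(c("C3", "C4", "Cz") %in% channel_names)) {
    stop("channel_names must include C3, C4 and Cz")
  }
  w <- topo_map(class_id, channel_coords(channel_names))
  names(w) <- channel_names
  structure(list(class_id = as.integer(class_id), attenuation_map = w),
            class = "spatial_topography")
}

# Attenuation map evaluated at channel positions `xy`, optionally with the
# whole pattern shifted by `shift` (trial-to-trial wandering of the ERD
# focus).  Gaussian bumps centered on the hand areas (under C3/C4) and the
# mesial foot area (under Cz).
topo_map <- function(class_id, xy, shift = c(0, 0)) {
  bump <- function(center, amp, sigma) {
    c0 <- drop(channel_coords(center)) + shift
    d2 <- (xy[, 1] - c0[1])^2 + (xy[, 2] - c0[2])^2
    amp * exp(-d2 / (2 * sigma^2))
  }
  hand_sig <- 0.6
  foot_sig <- 0.18
  w <- switch(as.character(class_id),
    "1" = bump("C3", 1, hand_sig) + bump("C4", 1, hand_sig),
    "2" = bump("Cz", 0.45, foot_sig),
    "3" = bump("C4", 1, hand_sig),
    "4" = bump("C3", 1, hand_sig),
    "5" = bump("C3", 1, hand_sig) + bump("Cz", 0.35, 0.25),
    "6" = bump("C4", 1, hand_sig) + bump("Cz", 0.35, 0.25)
  )
  if (class_id != 2) {
    # equalize total attenuation mass across the five non-reference classes:
    # real MI classes differ by spatial pattern far more than by overall
    # band-power change, and an unequalized mass is a give-away cue that
    # makes the six-class problem unrealistically easy
    w <- w * (sum(bump("C4", 1, hand_sig)) / sum(w))
  }
  pmin(w, 0.97)
}

# Schematic 2-D coordinates for arbitrary 10/20-style names (delegates to the
# montage table; errors on names outside the shipped montage).
channel_coords <- function(names) {
  tab <- montage_table()
  i <- match(names, tab$name)
  if (anyNA(i)) {
    stop("unknown channel name(s): ", paste(names[is.na(i)], collapse = ", "))
  }
  cbind(x = tab$x[i], y = tab$y[i])
}

# 1/f ("pink") shaping filter coefficients (Kellet's IIR approximation).
pink_coef <- function() {
  list(b = c(0.049922035, -0.095993537, 0.050612699, -0.004408786),
       a = c(1, -2.494956002, 2.017265875, -0.522189400))
}

#' Generate one subject's synthetic MI-EEG session
#'
#' Simulates a full session for a single subject under `config`: per block,
#' a random order of `6 x trials_per_class_per_block` trials; per trial,
#' spatially correlated pink (1/f) broadband noise on all channels plus
#' narrowband alpha (8-13 Hz) and beta (14-28 Hz) sensorimotor rhythm whose
#' amplitude during the 4-s MI window is multiplied by
#' `1 - depth * attenuation_map[ch] * gain_subject` for the trial's class.
#' The 1-s pre-task baseline carries the unattenuated rhythm. Signals are
#' synthesized at `fs_raw`, anti-alias filtered and decimated to `fs_target`.
#'
#' Rhythms are amplitude-modulated narrowband filtered noise, not pure tones,
#' so trial covariances have full rank; noise is spatially mixed by a fixed
#' per-subject smoothing matrix as a volume-conduction surrogate; beta ERD is
#' planted at 70% of the alpha depth.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's gains, noise and trial
#'   order.
#' @return An [epoch_set()] with window `(-baseline_seconds, epoch_seconds)`
#'   at `fs_target`; at defaults 504 trials (84 per class) of 60 channels x
#'   1000 samples.
#' @export
generate_subject <- function(config, subject_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(subject_seed)
  on.exit(restore_rng(rng))

  mont <- bci_montage(config$n_channels)
  nch <- nrow(mont)
  xy <- channel_coords(mont$name)

  # per-subject ERD gain and mixing matrix
  gain <- max(0, stats::rnorm(1, 1, config$subject_variability))
  depth <- pmin(config$erd_depth * gain, 0.98)        # per class
  D2 <- as.matrix(stats::dist(cbind(mont$x, mont$y)))^2
  M <- exp(-D2 / (2 * 0.3^2)) +
    0.15 * matrix(stats::rnorm(nch * nch), nch, nch)
  M <- M / sqrt(rowSums(M^2))                         # unit-power rows

  q <- config$fs_raw / config$fs_target
  trial_s <- config$baseline_seconds + config$epoch_seconds
  n_raw <- round(trial_s * config$fs_raw)
  n_tgt <- round(trial_s * config$fs_target)
  base_raw <- round(config$baseline_seconds * config$fs_raw)
  tpb <- 6L * config$trials_per_class_per_block
  n_total <- config$n_blocks * tpb

  nyq <- config$fs_raw / 2
  bf_a <- butter_ba(4, c(8, 13) / nyq, type = "pass")
  bf_b <- butter_ba(4, c(14, 28) / nyq, type = "pass")
  pk <- pink_coef()
  if (q > 1) bf_aa <- butter_ba(8, 0.9 / q, type = "low")

  # MI-window envelope ramp (100 ms raised cosine) applied to the planted
  # attenuation so the rhythm amplitude does not step discontinuously
  ramp_n <- round(0.1 * config$fs_raw)
  onoff <- numeric(n_raw)
  mi_idx <- (base_raw + 1):n_raw
  onoff[mi_idx] <- 1
  onoff[base_raw + seq_len(ramp_n)] <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2

  alpha_w <- 1 / sqrt(1 + 0.6^2)                     # alpha:beta amplitude 1:0.6
  beta_w <- 0.6 / sqrt(1 + 0.6^2)

  labels <- integer(n_total)
  out <- array(0, dim = c(n_total, nch, n_tgt))

  for (blk in seq_len(config$n_blocks)) {
    blk_labels <- sample(rep(1:6, config$trials_per_class_per_block))
    labels[(blk - 1L) * tpb + seq_len(tpb)] <- blk_labels
    len <- tpb * n_raw
    # per-trial attenuation maps: the planted topography with its focus
    # shifted by a random trial-specific offset and its depth scaled by a
    # lognormal trial gain (trial-to-trial ERD variability)
    att_mat <- vapply(seq_len(tpb), function(tr) {
      cl <- blk_labels[tr]
      shift <- stats::rnorm(2, 0, config$focus_jitter)
      tg <- exp(stats::rnorm(1, 0, config$erd_trial_variability))
      pmin(depth[cl] * tg * topo_map(cl, xy, shift), 0.98)
    }, numeric(nch))                                   # nch x tpb
    # broadband pink noise, spatially mixed
    noise <- matrix(stats::rnorm(nch * len), nch, len)
    for (ch in seq_len(nch)) {
      v <- iir_filter(pk$b, pk$a, noise[ch, ])
      noise[ch, ] <- v / stats::sd(v)
    }
    noise <- M %*% noise
    # rhythms with per-trial, per-channel ERD envelope
    for (ch in seq_len(nch)) {
      al <- iir_filter(bf_a$b, bf_a$a, stats::rnorm(len))
      be <- iir_filter(bf_b$b, bf_b$a, stats::rnorm(len))
      al <- al / stats::sd(al)
      be <- be / stats::sd(be)
      env <- 1 - as.vector(outer(onoff, att_mat[ch, ]))      # len vector
      noise[ch, ] <- noise[ch, ] +
        config$snr * env * (alpha_w * al + beta_w * be)
    }
    # anti-alias (zero-phase, whole block) and decimate to fs_target
    if (q > 1) {
      for (ch in seq_len(nch)) {
        noise[ch, ] <- iir_filtfilt(bf_aa$b, bf_aa$a, noise[ch, ])
      }
      noise <- noise[, seq(1, len, by = q), drop = FALSE]
    }
    n_blk_tgt <- tpb * n_tgt
    for (tr in seq_len(tpb)) {
      out[(blk - 1L) * tpb + tr, , ] <-
        noise[, (tr - 1L) * n_tgt + seq_len(n_tgt), drop = FALSE]
    }
  }
  epoch_set(out, labels, config$fs_target, mont$name,
            c(-config$baseline_seconds, config$epoch_seconds))
}

#' Generate a cohort of synthetic subjects
#'
#' Subjects share the design in `config` and differ only in their per-subject
#' ERD gain draw, noise mixing matrix, noise realization and trial order.
#' Reproducible: the same `master_seed` yields an identical cohort.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects (>= 5: a collaborative group needs
#'   five users).
#' @param master_seed Integer seed from which per-subject seeds are derived.
#' @return A list of `n_subjects` [epoch_set()] objects.
#' @export
generate_cohort <- function(config, n_subjects = 19,
                            master_seed = config$seed) {
  if (n_subjects < 5) {
    stop("n_subjects must be >= 5 (a collaborative group has five users)")
  }
  rng <- local_rng(master_seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  restore_rng(rng)
  lapply(subject_seeds, function(s) generate_subject(config, s))
}
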