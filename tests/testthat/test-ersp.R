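noise_epochs <- function(n = 30, fs = 200, seed = 50) {
  set.seed(seed)
  epoch_set(array(rnorm(n * 2 * 5 * fs), c(n, 2, 5 * fs)),
            labels = rep(1, n), fs = fs, channel_names = c("C3", "C4"),
            epoch_window = c(-1, 4))
}

test_that("stationary noise gives a near-zero dB map and single trials are identities", {
  es <- noise_epochs()
  m <- compute_ersp(es, "C3")
  expect_s3_class(m, "tf_map")
  expect_equal(dim(m$values), c(length(m$freqs), length(m$times)))
  expect_lt(max(abs(m$values)), 5)          # single-bin noise stays bounded
  expect_lt(abs(mean(m$values)), 0.5)       # no systematic deviation from 0 dB

  one <- subset_trials(es, 1)
  m1 <- compute_ersp(one, "C3")
  expect_equal(m1$n_trials, 1)

  expect_error(compute_ersp(es, "C3", baseline_window = c(-3, 0)), "outside")
  expect_error(compute_ersp(es, "C3", baseline_window = c(0, 1)), "precede")
})

test_that("baseline normalization zeroes the baseline rows themselves", {
  es <- noise_epochs(n = 60)
  m <- compute_ersp(es, "C4")
  in_base <- m$times >= -1 & m$times <= 0
  # per-frequency mean over the baseline bins is 0 dB by construction
  base_means <- rowMeans(10^(m$values[, in_base] / 10))
  expect_equal(base_means, rep(1, length(m$freqs)), tolerance = 1e-12)
})

test_that("erd_value averages selected bins and is linear in the map", {
  m <- structure(list(values = matrix(0, 5, 4), freqs = 8:12,
                      times = c(0.5, 1.5, 2.5, 3.5), channel = "C3",
                      n_trials = 1), class = "tf_map")
  expect_equal(erd_value(m, band = c(8, 12), window = c(0, 4)), 0)
  m$values[] <- -3
  expect_equal(erd_value(m, band = c(8, 12), window = c(0, 4)), -3)
  # 2x2 sub-grid [-1, -2; -3, -4] -> -2.5
  m$values[] <- 0
  m$values[1:2, 1:2] <- matrix(c(-1, -3, -2, -4), 2)
  expect_equal(erd_value(m, band = c(8, 9), window = c(0, 2)), -2.5)
  # linearity
  m2 <- m; m2$values <- 2 * m$values + 1
  expect_equal(erd_value(m2, band = c(8, 9), window = c(0, 2)),
               2 * (-2.5) + 1)
  expect_error(erd_value(m, band = c(40, 50)), "empty")
})

test_that("planted alpha ERD shows as negative dB at the attenuated channel", {
  es <- tiny_subject()
  lh <- subset_trials(es, es$labels == 3)   # left hand -> C4 attenuation
  m <- compute_ersp(lh, "C4")
  expect_lt(erd_value(m, band = c(8, 13), window = c(0.5, 4)), -1)
})

test_that("ERD topography localizes classes and is weakest for both feet", {
  cfg <- tiny_cfg(n_blocks = 2, focus_jitter = 0, erd_trial_variability = 0,
                  subject_variability = 0)
  coh <- generate_cohort(cfg, 5, master_seed = 33L)
  topo3 <- erd_topography(coh, 3)
  topo4 <- erd_topography(coh, 4)
  ch3 <- topo3$channel[which.min(topo3$erd)]
  ch4 <- topo4$channel[which.min(topo4$erd)]
  xy <- cbind(bci_montage(21)$x)[, 1]
  names(xy) <- bci_montage(21)$name
  expect_gt(xy[[ch3]], 0)   # LH minimum on the right hemisphere
  expect_lt(xy[[ch4]], 0)   # RH minimum on the left hemisphere
  # both feet: smallest total ERD magnitude of the six classes
  mass <- vapply(1:6, function(cl) {
    sum(abs(pmin(erd_topography(coh, cl)$erd, 0)))
  }, numeric(1))
  expect_true(all(mass[2] < mass[-2]))
})

test_that("a no-ERD cohort has channel ERD values near zero", {
  zero <- c("1" = 0, "2" = 0, "3" = 0, "4" = 0, "5" = 0, "6" = 0)
  cfg <- tiny_cfg(n_blocks = 2, erd_depth = zero, subject_variability = 0)
  coh <- generate_cohort(cfg, 5, master_seed = 44L)
  topo <- erd_topography(coh, 1)
  expect_lt(max(abs(topo$erd)), 1)          # within band-averaged noise of 0 dB
  expect_lt(abs(mean(topo$erd)), 0.3)
})
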