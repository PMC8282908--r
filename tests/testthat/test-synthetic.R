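test_that("simulation config validates its invariants", {
  cfg <- sim_config()
  expect_equal(cfg$n_blocks * cfg$trials_per_class_per_block, 84)
  expect_error(sim_config(fs_raw = 1000, fs_target = 300), "divisible")
  expect_error(sim_config(erd_depth = c("1" = 1.0, "2" = 0.1, "3" = 0.1,
                                        "4" = 0.1, "5" = 0.1, "6" = 0.1)),
               "\\[0, 1\\)")
  expect_error(sim_config(erd_depth = c("1" = 0.5)), "all classes")
})

test_that("planted topographies are contralateral, foot-weakest and mirror-symmetric", {
  ch <- bci_montage(60)$name
  lh <- planted_topography(3, ch)$attenuation_map
  rh <- planted_topography(4, ch)$attenuation_map
  # left-hand imagery -> attenuation concentrated at C4, near-zero at C3
  expect_equal(names(which.max(lh)), "C4")
  expect_equal(names(which.max(rh)), "C3")
  expect_lt(lh[["C3"]] / lh[["C4"]], 0.4)
  # mirror property: map(LH) equals map(RH) with left/right labels swapped
  expect_equal(unname(lh[mirror_channels(ch)]), unname(rh[ch]))
  # both feet: strictly smallest total attenuation mass of the six classes
  masses <- vapply(1:6, function(cl) {
    sum(planted_topography(cl, ch)$attenuation_map)
  }, numeric(1))
  expect_true(all(masses[2] < masses[-2]))
  expect_true(all(vapply(1:6, function(cl) {
    w <- planted_topography(cl, ch)$attenuation_map
    all(w >= 0 & w <= 1)
  }, logical(1))))
  expect_error(planted_topography(7, ch), "1..6")
  expect_error(planted_topography(3, c("C3", "C4")), "Cz")
})

test_that("generated sessions have balanced randomized classes and exact shapes", {
  es <- tiny_subject()
  cfg <- tiny_cfg()
  expect_equal(n_trials(es), cfg$n_blocks * 36)
  expect_equal(as.integer(table(es$labels)),
               rep(cfg$n_blocks * cfg$trials_per_class_per_block, 6L))
  expect_equal(dim(es$data)[2], 21)
  expect_equal(dim(es$data)[3], (4 + 1) * 200)
  expect_equal(es$epoch_window, c(-1, 4))
  # within-block class balance
  blk <- rep(seq_len(cfg$n_blocks), each = 36)
  for (b in seq_len(cfg$n_blocks)) {
    expect_equal(as.integer(table(es$labels[blk == b])), rep(6L, 6))
  }
})

test_that("generation is bitwise reproducible from its seed", {
  cfg <- tiny_cfg(n_blocks = 1)
  a <- generate_subject(cfg, 5L)
  b <- generate_subject(cfg, 5L)
  expect_identical(a, b)
  d <- generate_subject(cfg, 6L)
  expect_false(identical(a$data, d$data))
  # cohort determinism
  c1 <- generate_cohort(cfg, 5, master_seed = 11L)
  c2 <- generate_cohort(cfg, 5, master_seed = 11L)
  expect_identical(c1, c2)
  expect_error(generate_cohort(cfg, 4), ">= 5")
})

test_that("zero ERD depth leaves MI-window band power at baseline level", {
  zero <- c("1" = 0, "2" = 0, "3" = 0, "4" = 0, "5" = 0, "6" = 0)
  cfg <- tiny_cfg(n_blocks = 2, erd_depth = zero,
                  subject_variability = 0, erd_trial_variability = 0)
  es <- generate_subject(cfg, 8L)
  bp <- bandpass_epochs(es, 8, 13)
  base <- crop_epochs(bp, c(-0.75, -0.05))
  task <- crop_epochs(bp, c(0.3, 4))
  i3 <- channel_index(es, "C3")
  vb <- mean(apply(base$data[, i3, ], 1, var))
  vt <- mean(apply(task$data[, i3, ], 1, var))
  expect_equal(vt / vb, 1, tolerance = 0.1)
})

test_that("planted ERD lowers alpha-band variance on attenuated channels", {
  es <- tiny_subject()
  bp <- crop_epochs(bandpass_epochs(es, 8, 13), c(0, 4))
  i3 <- channel_index(bp, "C3")
  v <- apply(bp$data[, i3, ], 1, var)
  # class 4 (right hand) attenuates C3; class 2 (both feet) barely does
  p <- wilcox.test(v[bp$labels == 4], v[bp$labels == 2],
                   alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("deeper planted ERD strictly lowers expected alpha variance", {
  mk <- function(depth) {
    d <- c("1" = 0, "2" = 0, "3" = depth, "4" = 0, "5" = 0, "6" = 0)
    cfg <- tiny_cfg(n_blocks = 2, erd_depth = d, subject_variability = 0,
                    erd_trial_variability = 0, focus_jitter = 0)
    es <- generate_subject(cfg, 13L)
    bp <- crop_epochs(bandpass_epochs(es, 8, 13), c(0, 4))
    i4 <- channel_index(bp, "C4")
    mean(apply(bp$data[bp$labels == 3, i4, ], 1, var))
  }
  v <- vapply(c(0, 0.4, 0.8), mk, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("cohort subjects share shapes and differ only in their draws", {
  cfg <- tiny_cfg(n_blocks = 1)
  coh <- generate_cohort(cfg, 5, master_seed = 21L)
  expect_length(coh, 5)
  dims <- vapply(coh, function(es) dim(es$data), numeric(3))
  expect_true(all(dims == dims[, 1]))
  expect_false(identical(coh[[1]]$data, coh[[2]]$data))
})
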