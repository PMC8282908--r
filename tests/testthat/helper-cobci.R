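# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Reduced-scale study design used by most tests: 21-channel sensorimotor
# montage (a pair-complete prefix of the full one), 3 blocks -> 18 trials
# per class, split 15/3.
tiny_cfg <- function(...) {
  args <- list(...)
  if (is.null(args$n_channels)) args$n_channels <- 21
  if (is.null(args$n_blocks)) args$n_blocks <- 3
  do.call(sim_config, args)
}

tiny_subject <- function() {
  fixture("tiny_subject", function() generate_subject(tiny_cfg(), 42L))
}

tiny_prepared <- function() {
  fixture("tiny_prepared", function() {
    prepare_subject(tiny_subject(), split_seed = 9L, n_train_per_class = 15)
  })
}

# Five-subject cohort at the same scale, prepared for group evaluation.
tiny_cohort_prepared <- function() {
  fixture("tiny_cohort_prepared", function() {
    cfg <- tiny_cfg()
    coh <- generate_cohort(cfg, 5, master_seed = 7L)
    lapply(seq_along(coh), function(i) {
      prepare_subject(coh[[i]], split_seed = 100L + i, n_train_per_class = 15)
    })
  })
}

# Analytic toy: N "channels", class c trials put extra variance on channel
# c; perfectly separable covariance stacks for fusion/evaluation tests.
toy_cov_stack <- function(n_per_class, classes, nch = 6, boost = 25,
                          noise = 0.01, seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- rep(classes, each = n_per_class)
  covs <- array(0, c(n, nch, nch))
  for (t in seq_len(n)) {
    d <- rep(1, nch)
    d[labels[t]] <- boost
    C <- diag(d + stats::runif(nch, 0, noise * boost))
    covs[t, , ] <- C / sum(diag(C))
  }
  list(covs = covs, labels = labels)
}

# Brute-force generalized-eigenproblem CSP oracle for (R_c, R_c + R_rest):
# solve R_c v = mu (R_c + R_rest) v directly.
csp_oracle <- function(Rc, Rrest) {
  S <- Rc + Rrest
  E <- eigen(solve(S, Rc))
  ord <- order(-Re(E$values))
  V <- Re(E$vectors[, ord, drop = FALSE])   # generalized eigenvectors
  list(values = Re(E$values)[ord], vectors = V)
}

# Plug-in MI oracle from an explicit joint count/probability table.
mi_oracle <- function(joint) {
  joint <- joint / sum(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(rowSums(joint)) + h(colSums(joint)) - h(joint)
}
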