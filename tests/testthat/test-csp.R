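test_that("class covariance matches a hand-computed trace-normalized average", {
  set.seed(3)
  x <- array(rnorm(2 * 3 * 50), c(2, 3, 50))
  expected <- matrix(0, 3, 3)
  for (tr in 1:2) {
    xt <- matrix(x[tr, , ], 3)
    cc <- tcrossprod(xt)
    expected <- expected + cc / sum(diag(cc)) / 2
  }
  expect_equal(class_covariance(x), expected, tolerance = 1e-12)
  expect_error(class_covariance(x[1, , , drop = FALSE]), ">= 2 trials")
})

test_that("white-noise class covariance approaches identity/N", {
  set.seed(4)
  x <- array(rnorm(200 * 4 * 500), c(200, 4, 500))
  R <- class_covariance(x)
  expect_equal(R, diag(4) / 4, tolerance = 0.02)
})

test_that("whitening satisfies P R P' = I, including the closed-form diagonal case", {
  # R = diag(4, 1): P R P' = I via Lambda^{-1/2} = diag(1/2, 1)
  P <- csp_whitening(list(diag(c(2, 0.5)), diag(c(2, 0.5))))
  expect_equal(P %*% diag(c(4, 1)) %*% t(P), diag(2), tolerance = 1e-12)

  set.seed(5)
  covs <- lapply(1:6, function(i) crossprod(matrix(rnorm(25), 5)) + diag(5))
  P <- csp_whitening(covs)
  expect_equal(P %*% Reduce(`+`, covs) %*% t(P), diag(5), tolerance = 1e-10)

  # rank-deficient beyond repair
  expect_error(csp_whitening(list(matrix(1, 3, 3))), "singular")
})

test_that("rank-restricted whitening handles common-average-referenced data", {
  set.seed(6)
  x <- matrix(rnorm(5 * 300), 5)
  x <- sweep(x, 2, colMeans(x))        # CAR: rank 4
  R <- tcrossprod(x) / 300
  P <- csp_whitening(list(R))
  expect_equal(nrow(P), 4)
  expect_equal(P %*% R %*% t(P), diag(4), tolerance = 1e-8)
})

test_that("one-vs-rest projections jointly diagonalize with complementary eigenvalues", {
  set.seed(7)
  covs <- lapply(1:3, function(i) {
    C <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    C / sum(diag(C))
  })
  names(covs) <- 1:3
  P <- csp_whitening(covs)
  W <- ovr_projections(covs, P)
  for (cl in names(covs)) {
    Rc <- covs[[cl]]
    Rrest <- Reduce(`+`, covs[names(covs) != cl])
    D1 <- W[[cl]] %*% Rc %*% t(W[[cl]])
    D2 <- W[[cl]] %*% Rrest %*% t(W[[cl]])
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-10)   # diagonal
    expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-10)
    expect_equal(diag(D1) + diag(D2), rep(1, 4), tolerance = 1e-10)
    expect_true(all(diff(diag(D1)) <= 1e-10))          # descending order
  }
})

test_that("identical class covariances give eigenvalue one half", {
  C <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  covs <- list("1" = C, "2" = C)
  P <- csp_whitening(covs)
  W <- ovr_projections(covs, P)
  D <- diag(W[["1"]] %*% C %*% t(W[["1"]]))
  expect_equal(D, rep(0.5, 3), tolerance = 1e-10)
})

test_that("planted two-channel toy: top filter isolates the discriminative channel", {
  R1 <- diag(c(0.9, 0.1))   # class 1: variance in channel 1
  R2 <- diag(c(0.1, 0.9))
  covs <- list("1" = R1, "2" = R2)
  W <- ovr_projections(covs, csp_whitening(covs))[["1"]]
  top <- W[1, ] / sqrt(sum(W[1, ]^2))
  expect_gt(abs(top[1]), 0.99)
  expect_lt(abs(top[2]), 0.1)
})

test_that("filters match the brute-force generalized eigenproblem oracle", {
  set.seed(8)
  for (rep in 1:20) {
    covs <- lapply(1:3, function(i) {
      C <- crossprod(matrix(rnorm(16), 4)) + 0.5 * diag(4)
      C / sum(diag(C))
    })
    names(covs) <- 1:3
    P <- csp_whitening(covs)
    W <- ovr_projections(covs, P)
    for (cl in names(covs)) {
      Rrest <- Reduce(`+`, covs[names(covs) != cl])
      orc <- csp_oracle(covs[[cl]], Rrest)
      # eigenvalues of whitened class covariance = generalized eigenvalues
      lam <- diag(W[[cl]] %*% covs[[cl]] %*% t(W[[cl]]))
      expect_equal(lam, orc$values, tolerance = 1e-8)
      # filters equal oracle eigenvectors up to per-row scale/sign
      for (j in 1:4) {
        v1 <- W[[cl]][j, ] / sqrt(sum(W[[cl]][j, ]^2))
        v2 <- orc$vectors[, j] / sqrt(sum(orc$vectors[, j]^2))
        expect_equal(abs(sum(v1 * v2)), 1, tolerance = 1e-6)
      }
    }
  }
})

test_that("features are normalized log variance shares of length 2m", {
  set.seed(9)
  W <- matrix(rnorm(16), 4)
  x <- matrix(rnorm(4 * 100), 4)
  f <- csp_features(x, W, m = 2)
  expect_length(f, 4)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  # covariance input gives the same features as the raw trial
  C <- tcrossprod(x) / sum(diag(tcrossprod(x)))
  expect_equal(csp_features(C, W, m = 2), f, tolerance = 1e-12)
  # batch path agrees
  covs <- array(C, c(1, 4, 4))
  expect_equal(drop(cobci:::csp_features_cov(covs, W, 2)), f, tolerance = 1e-12)
})

test_that("features are invariant to global amplitude scaling", {
  set.seed(10)
  x <- array(rnorm(8 * 5 * 60), c(8, 5, 60))
  labels <- rep(1:2, 4)
  b1 <- fit_csp_bank(trial_covariances(x), labels)
  b2 <- fit_csp_bank(trial_covariances(x * 37), labels)
  f1 <- csp_features(matrix(x[1, , ], 5), b1$projections[["1"]])
  f2 <- csp_features(matrix(x[1, , ] * 37, 5), b2$projections[["1"]])
  expect_equal(f1, f2, tolerance = 1e-8)
})
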