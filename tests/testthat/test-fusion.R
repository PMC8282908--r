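# five-user toy world: crafted covariance stacks where class c loads
# variance on "channel" c, so submodels and fusion are exactly decodable
toy_world <- function(k = 3, n_train = 12, n_test = 4, seed = 30) {
  sc <- build_scheme(k)
  train <- list()
  test <- list()
  user_models <- list()
  for (i in seq_along(sc$users)) {
    u <- sc$users[i]
    s <- sc$subsets[[u]]
    tr <- toy_cov_stack(n_train, classes = s, seed = seed + i)
    te <- toy_cov_stack(n_test, classes = 1:6, seed = seed + 50 + i)
    train[[u]] <- tr
    test[[u]] <- te
    sms <- lapply(s, function(tg) {
      train_submodel(tr$covs, tr$labels, target = tg, user_id = u)
    })
    names(sms) <- s
    user_models[[u]] <- sms
  }
  list(scheme = sc, train = train, test = test, user_models = user_models)
}

toy_group_trial <- function(world, input, j = 1) {
  modes <- build_modes(world$scheme)
  mode <- modes[[input]]
  trials <- lapply(world$scheme$users, function(u) {
    cl <- mode$assignment[[u]]
    idx <- which(world$test[[u]]$labels == cl)[j]
    world$test[[u]]$covs[idx, , ]
  })
  names(trials) <- world$scheme$users
  group_trial(trials, true_label = input)
}

test_that("fuse_decision_values matches hand arithmetic", {
  expect_equal(fuse_decision_values(rep(2, 5), rep(1, 5)), 2)
  expect_equal(fuse_decision_values(rep(0, 5), runif(5)), 0)
  expect_equal(
    fuse_decision_values(c(1, -1, 0.5, 0.5, 0.5), c(0.81, 0.64, 1, 1, 1)),
    0.334
  )
  expect_error(fuse_decision_values(1:3, 1:2), "lengths differ")
})

test_that("decision fusion with equal members reduces to the common score", {
  dv <- 1.7
  expect_equal(fuse_decision_values(rep(dv, 5), rep(1, 5)), dv)
})

test_that("feature fusion builds 20 fused columns and keeps the top 4", {
  world <- toy_world(k = 3)
  models <- assemble_models(world$scheme, world$user_models, "feature")
  mod <- train_feature_fusion(models[[1]], world$train, pair_seed = 4)
  expect_equal(mod$fusion$n_fused, 20)
  expect_equal(mod$fusion$k_keep, 4)
  expect_length(mod$fusion$ranking$order, 20)
  expect_length(mod$fusion$ranking$selected, 4)
  # positive rows = n_train per class, negative rows = (k-1) * n_train
  # is implied by the subset structure; a mismatch must be caught:
  broken <- world$train
  broken[["B"]]$covs <- broken[["B"]]$covs[1:10, , , drop = FALSE]
  broken[["B"]]$labels <- broken[["B"]]$labels[1:10]
  expect_error(train_feature_fusion(models[[1]], broken), "mismatch")
})

test_that("both fusion methods decode the toy world perfectly", {
  world <- toy_world(k = 3)
  dec_models <- assemble_models(world$scheme, world$user_models, "decision")
  fea_models <- assemble_models(world$scheme, world$user_models, "feature")
  fea_models <- lapply(fea_models, train_feature_fusion,
                       train_covs = world$train, pair_seed = 4)
  for (input in 1:6) {
    gt <- toy_group_trial(world, input)
    rd <- predict_decision_fusion(dec_models, gt)
    rf <- predict_feature_fusion(fea_models, gt)
    expect_equal(rd$predicted, input)
    expect_equal(rf$predicted, input)
    expect_length(rd$Dv, 6)
    expect_length(rf$Dv, 6)
    expect_equal(dim(rd$dv_members), c(6, 5))
  }
})

test_that("argmax ties break to the lowest instruction and no_positive is flagged", {
  rec <- cobci:::decision_record(
    structure(c(0.5, 0.2, 0.5, 0.1, 0, -1), names = 1:6), "decision")
  expect_equal(rec$predicted, 1L)
  expect_false(rec$no_positive)
  rec2 <- cobci:::decision_record(
    structure(c(-3, -1, -2, -1, -5, -4), names = 1:6), "decision")
  expect_equal(rec2$predicted, 2L)
  expect_true(rec2$no_positive)
})

test_that("permuting users together with their trials leaves predictions unchanged", {
  world <- toy_world(k = 6)   # common work: subsets identical, so user
                              # slots are exchangeable end to end
  models <- assemble_models(world$scheme, world$user_models, "decision")
  gt <- toy_group_trial(world, input = 3)
  base <- predict_decision_fusion(models, gt)
  perm <- c("C", "A", "E", "B", "D")
  models_p <- lapply(models, function(mod) {
    mod$members <- mod$members[perm]
    mod$lambda <- mod$lambda[perm]
    mod
  })
  gt_p <- group_trial(gt$trials[perm], gt$true_label)
  out <- predict_decision_fusion(models_p, gt_p)
  expect_equal(out$predicted, base$predicted)
  expect_equal(unname(out$Dv), unname(base$Dv))
})
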