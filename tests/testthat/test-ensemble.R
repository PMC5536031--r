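# small but learnable training set for ensemble protocol tests
ensemble_fixture <- function(n = 240, d = 12, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), times = c(n - n %/% 4, n %/% 4))
  x <- matrix(rnorm(n * d), n, d) + outer(y, rep(2, d))
  list(x = x, y = y)
}

test_that("fold assignment partitions instances with stratified class balance", {
  y <- c(rep(1L, 54), rep(0L, 2895))
  folds <- stratified_folds(y, 10L, seed = 3L)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(max(table(folds)) - min(table(folds)) <= 1)
  pos_per_fold <- table(folds[y == 1L])
  expect_true(all(pos_per_fold %in% c(5L, 6L)))   # 54 positives over 10 folds
  # determinism
  expect_identical(folds, stratified_folds(y, 10L, seed = 3L))
  expect_error(stratified_folds(y, 1L), class = "hotspotRP_config_error")
})

test_that("training ranks all candidate projections by validation F1 with seed tie-break", {
  fix <- ensemble_fixture()
  model <- train_ensemble(fix$x, fix$y, n_projections = 5L, top_n = 5L,
                          target_dim = 3L, master_seed = 17L)
  expect_s3_class(model, "rp_ensemble")
  f1s <- model$ranking$train_f1
  expect_equal(f1s, sort(f1s, decreasing = TRUE))
  expect_equal(nrow(model$ranking), 5L)
  member_f1 <- vapply(model$members, `[[`, numeric(1), "train_f1")
  expect_equal(member_f1, f1s)
  # ties broken by ascending projection seed
  tied <- model$ranking[model$ranking$train_f1 == max(f1s), ]
  expect_equal(tied$seed, sort(tied$seed))

  expect_error(train_ensemble(fix$x, fix$y, n_projections = 3L, top_n = 4L),
               class = "hotspotRP_config_error")
  expect_error(train_ensemble(fix$x, rep(0L, nrow(fix$x)), n_projections = 2L,
                              top_n = 1L),
               class = "hotspotRP_data_error")
})

test_that("a K = N = 1 ensemble equals its single base classifier", {
  fix <- ensemble_fixture()
  model <- train_ensemble(fix$x, fix$y, n_projections = 1L, top_n = 1L,
                          target_dim = 3L, master_seed = 4L)
  queries <- fix$x[1:40, ]
  ens <- predict(model, queries)
  m <- model$members[[1]]
  single <- predict(m$model, project(queries, m$projection))
  expect_identical(ens$label, single$label)
  expect_equal(ens$fraction, as.numeric(single$label))
})

test_that("majority vote labels positive at >= half the member votes", {
  fix <- ensemble_fixture()
  model <- train_ensemble(fix$x, fix$y, n_projections = 6L, top_n = 3L,
                          target_dim = 3L, master_seed = 2L)
  pred <- predict(model, fix$x[c(1:20, 221:240), ])
  votes <- vapply(model$members, function(m)
    predict(m$model, project(fix$x[c(1:20, 221:240), ], m$projection))$label,
    integer(40))
  pos <- rowSums(votes)
  expect_identical(pred$label, as.integer(pos >= 2))   # ceil(3/2) = 2 of 3
  expect_equal(pred$fraction, pos / 3)
  # an instance with votes from every member is positive for any N
  unanimous <- pos == 3L
  if (any(unanimous)) expect_true(all(pred$label[unanimous] == 1L))
  # even N: 1 of 2 votes is enough under the ">= half" rule
  model2 <- model
  model2$members <- model$members[1:2]
  model2$top_n <- 2L
  pred2 <- predict(model2, fix$x[c(1:20, 221:240), ])
  pos2 <- rowSums(votes[, 1:2])
  expect_identical(pred2$label, as.integer(pos2 >= 1))
})

test_that("the whole training protocol is reproducible from one master seed", {
  fix <- ensemble_fixture()
  a <- train_ensemble(fix$x, fix$y, n_projections = 8L, top_n = 3L,
                      target_dim = 4L, master_seed = 99L)
  b <- train_ensemble(fix$x, fix$y, n_projections = 8L, top_n = 3L,
                      target_dim = 4L, master_seed = 99L)
  expect_identical(a$ranking, b$ranking)
  expect_identical(vapply(a$members, function(m) m$projection$seed, integer(1)),
                   vapply(b$members, function(m) m$projection$seed, integer(1)))
  expect_identical(predict(a, fix$x[1:10, ]), predict(b, fix$x[1:10, ]))
})

test_that("cross-validation predicts every instance exactly once, deterministically", {
  fix <- ensemble_fixture(n = 120, d = 6)
  res <- cross_validate(fix$x, fix$y, n_projections = 4L, top_n = 1L,
                        target_dim = 2L, n_folds = 10L, master_seed = 21L)
  expect_equal(nrow(res$predictions), 120L)
  expect_equal(sort(unique(res$predictions$fold)), 1:10)
  expect_equal(table(res$predictions$fold)[[1]], 12L)
  expect_equal(with(res$confusion, tp + fp + tn + fn), 120)
  res2 <- cross_validate(fix$x, fix$y, n_projections = 4L, top_n = 1L,
                         target_dim = 2L, n_folds = 10L, master_seed = 21L)
  expect_identical(res$predictions, res2$predictions)
})

test_that("ensembles persist to JSON and restore to identical predictions", {
  fix <- ensemble_fixture(n = 80, d = 6)
  model <- train_ensemble(fix$x, fix$y, n_projections = 4L, top_n = 2L,
                          target_dim = 3L, master_seed = 6L)
  path <- tempfile(fileext = ".json")
  save_ensemble(model, path)
  back <- load_ensemble(path)
  expect_equal(back$top_n, model$top_n)
  expect_identical(predict(back, fix$x[1:25, ]), predict(model, fix$x[1:25, ]))
})
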