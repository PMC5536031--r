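# End-to-end parameter-recovery runs shared by several acceptance tests.
# One run: generate a ~3000-residue corpus, split chains 13 train / 7 test,
# encode at window 13, train the K = 20 / N = 3 / L2 = 5 ensemble, predict
# the held-out chains. Computed once per session and cached.

.recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function(seed, effect_size) {
  corpus <- generate_corpus(effect_size = effect_size, seed = seed)
  train <- encode_dataset(corpus$sequences[1:13], corpus$properties, 13L)
  test <- encode_dataset(corpus$sequences[14:20], corpus$properties, 13L)
  if (sum(train$y) == 0L || sum(test$y) == 0L) {
    return(list(f1 = NA_real_, baseline_f1 = NA_real_,
                member_f1 = NA_real_))
  }
  model <- train_ensemble(train$x, train$y, n_projections = 20L, top_n = 3L,
                          target_dim = 5L, k = 1L,
                          master_seed = seed + 1000L)
  pred <- predict(model, test$x)
  f1 <- metrics(confusion(test$y, pred$label))$f1
  # baseline: truth-independent predictor matched to the ensemble's
  # positive-call rate, averaged over 200 replicates
  rate <- mean(pred$label)
  baseline <- if (rate > 0) {
    random_predictor(test$y, rate, n_runs = 200L, seed = seed)$f1
  } else {
    0
  }
  # every candidate projection's own test F1 (individual classifiers)
  member_f1 <- vapply(seq_len(model$n_projections), function(i) {
    proj <- make_projection(ncol(train$x), model$target_dim,
                            derive_seed(model$master_seed, "projection", i))
    folds <- stratified_folds(train$y, model$n_folds,
                              derive_seed(model$master_seed, "folds"))
    rb <- rebalance(project(train$x, proj)[folds != 1L, , drop = FALSE],
                    train$y[folds != 1L],
                    derive_seed(model$master_seed, "resample", i))
    m <- fit_knn(rb$x, rb$y, model$k)
    p <- predict(m, project(test$x, proj))
    v <- metrics(confusion(test$y, p$label))$f1
    if (is.na(v)) 0 else v
  }, numeric(1))
  list(f1 = f1, baseline_f1 = baseline, member_f1 = member_f1)
}

recovery_runs <- function(effect_size) {
  key <- paste0("effect_", effect_size)
  if (!exists(key, envir = .recovery_cache)) {
    assign(key, lapply(1:10, recovery_run, effect_size = effect_size),
           envir = .recovery_cache)
  }
  get(key, envir = .recovery_cache)
}
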