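#' Assign instances to cross-validation folds
#'
#' Folds partition the instances with sizes differing by at most one. With
#' `stratify = TRUE` (the default) the assignment cycles fold numbers across
#' the shuffled instances class by class, so each fold also receives an equal
#' share (±1) of each class — essential at ~1.8% prevalence, where
#' unstratified folds can lack positives entirely.
#'
#' @param y Integer 0/1 targets.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @param stratify Stratify fold assignment by class (default TRUE).
#' @return Integer vector of fold ids in `1:n_folds`, one per instance.
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 1L, stratify = TRUE) {
  n <- length(y)
  if (n_folds < 2L || n_folds > n) {
    stop_config("stratified_folds: need 2 <= n_folds <= n (n_folds = ",
                n_folds, ", n = ", n, ")")
  }
  folds <- integer(n)
  with_seed(seed, {
    ord <- if (stratify) {
      unlist(lapply(sort(unique(y)), function(cl) sample(which(y == cl))),
             use.names = FALSE)
    } else {
      sample.int(n)
    }
    # one running cycle across classes keeps overall fold sizes within 1
    folds[ord] <- rep_len(seq_len(n_folds), n)
  })
  folds
}

#' Train a random-projection k-NN ensemble
#'
#' The training protocol: draw `n_projections` seeded random projections of
#' the instance space down to `target_dim`; for each, project the training
#' data, hold out a stratified validation subset (one fold of an inner
#' `n_folds`-fold plan shared by all projections), rebalance the remaining
#' training subset to a 1:1 class ratio, fit a k-nearest-neighbour learner,
#' and score it by F1 on the (unbalanced) validation subset. All
#' `n_projections` members are then ranked by that validation F1 (ties broken
#' by projection seed, ascending) and the top `top_n` are retained; at
#' prediction time the retained members vote by majority.
#'
#' Selection F1 is computed on the unbalanced validation subset because
#' selection on a rebalanced subset would inflate every member's F1
#' uniformly. A validation F1 that is undefined (no true or no predicted
#' positives) ranks as 0.
#'
#' @param x Instance matrix (N x L1), e.g. `encoded_set$x`.
#' @param y Integer 0/1 targets.
#' @param n_projections Number of random projections K (default 100).
#' @param top_n Ensemble size N, `1 <= top_n <= n_projections` (default 3).
#' @param target_dim Reduced dimension L2 (default 5).
#' @param k Neighbours for each base learner (default 1).
#' @param n_folds Inner split granularity; fold 1 is the validation subset
#'   (default 10, i.e. a 90/10 split).
#' @param master_seed One integer reproducing the whole ensemble: projection,
#'   resampling and fold seeds are derived from it via [derive_seed()].
#' @return An `rp_ensemble`: list with `members` (each holding `projection`,
#'   `model`, `train_f1`, `rank`), `ranking` (data frame over all K
#'   candidates), and the resolved configuration.
#' @export
train_ensemble <- function(x, y, n_projections = 100L, top_n = 3L,
                           target_dim = 5L, k = 1L, n_folds = 10L,
                           master_seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_dim("train_ensemble: nrow(x) != length(y)")
  if (length(unique(y)) < 2L) {
    stop_data("train_ensemble: training data holds a single class")
  }
  if (top_n < 1L || top_n > n_projections) {
    stop_config("train_ensemble: need 1 <= top_n <= n_projections (top_n = ",
                top_n, ", n_projections = ", n_projections, ")")
  }
  folds <- stratified_folds(y, n_folds, derive_seed(master_seed, "folds"))
  val <- folds == 1L
  candidates <- vector("list", n_projections)
  for (i in seq_len(n_projections)) {
    proj <- make_projection(ncol(x), target_dim,
                            derive_seed(master_seed, "projection", i))
    xp <- project(x, proj)
    rb <- rebalance(xp[!val, , drop = FALSE], y[!val],
                    derive_seed(master_seed, "resample", i))
    model <- fit_knn(rb$x, rb$y, k)
    pred <- predict(model, xp[val, , drop = FALSE])
    f1 <- metrics(confusion(y[val], pred$label))$f1
    candidates[[i]] <- list(projection = proj, model = model,
                            train_f1 = if (is.na(f1)) 0 else f1)
  }
  f1s <- vapply(candidates, `[[`, numeric(1), "train_f1")
  seeds <- vapply(candidates, function(m) m$projection$seed, integer(1))
  ord <- order(-f1s, seeds)
  members <- candidates[ord[seq_len(top_n)]]
  for (r in seq_along(members)) members[[r]]$rank <- r
  structure(list(members = members,
                 ranking = data.frame(rank = seq_len(n_projections),
                                      seed = seeds[ord],
                                      train_f1 = f1s[ord]),
                 n_projections = as.integer(n_projections),
                 top_n = as.integer(top_n),
                 target_dim = as.integer(target_dim), k = as.integer(k),
                 n_folds = as.integer(n_folds),
                 master_seed = as.integer(master_seed)),
            class = "rp_ensemble")
}

#' Predict hotspot labels with a trained ensemble
#'
#' Each retained member projects the queries with its own matrix and casts a
#' 0/1 vote; an instance is predicted a hotspot when at least half of the N
#' members vote positive (`votes >= ceiling(N/2)`, so 2 of 3, and 1 of 2 for
#' even N — the tie goes positive under the "if half predict it" rule).
#'
#' @param object An `rp_ensemble`.
#' @param newdata Instance matrix with the training width L1.
#' @param ... Unused.
#' @return Data frame with `label` (0/1) and `fraction` (positive votes / N).
#' @export
predict.rp_ensemble <- function(object, newdata, ...) {
  if (length(object$members) == 0L) {
    stop_data("predict.rp_ensemble: empty ensemble")
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  votes <- vapply(object$members, function(m) {
    predict(m$model, project(newdata, m$projection))$label
  }, integer(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  pos <- rowSums(votes)
  n <- length(object$members)
  data.frame(label = as.integer(pos >= ceiling(n / 2)), fraction = pos / n)
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat(sprintf("rp_ensemble: top %d of %d projections (L2 = %d, k = %d)\n",
              x$top_n, x$n_projections, x$target_dim, x$k))
  cat("member validation F1:",
      paste(sprintf("%.3f", vapply(x$members, `[[`, numeric(1), "train_f1")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated ensemble evaluation
#'
#' Outer stratified `n_folds`-fold loop: each fold is held out in turn, an
#' ensemble is trained on the remaining folds via [train_ensemble()] (with a
#' fold-specific master seed derived from `master_seed`), and the held-out
#' instances are predicted. Every instance is predicted exactly once; the
#' pooled confusion counts and metrics are returned. A test fold without
#' positives is evaluated with a warning (its sensitivity contribution is
#' vacuous).
#'
#' @inheritParams train_ensemble
#' @param n_folds Outer folds (default 10).
#' @param stratify Stratify the outer folds by class (default TRUE).
#' @return List with `predictions` (data frame: instance index, fold, truth,
#'   label, fraction), pooled `confusion` and `metrics`.
#' @export
cross_validate <- function(x, y, n_projections = 100L, top_n = 3L,
                           target_dim = 5L, k = 1L, n_folds = 10L,
                           master_seed = 1L, stratify = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  folds <- stratified_folds(y, n_folds, derive_seed(master_seed, "folds", 1L),
                            stratify = stratify)
  label <- integer(length(y))
  fraction <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    ts <- folds == f
    if (!any(y[ts] == 1L)) {
      warning("cross_validate: fold ", f, " holds no positive instances")
    }
    model <- train_ensemble(x[!ts, , drop = FALSE], y[!ts],
                            n_projections = n_projections, top_n = top_n,
                            target_dim = target_dim, k = k,
                            master_seed = derive_seed(master_seed, "folds",
                                                      100L + f))
    pred <- predict(model, x[ts, , drop = FALSE])
    label[ts] <- pred$label
    fraction[ts] <- pred$fraction
  }
  cc <- confusion(y, label)
  list(predictions = data.frame(index = seq_along(y), fold = folds,
                                truth = y, label = label,
                                fraction = fraction),
       confusion = cc, metrics = metrics(cc))
}

#' Transfer evaluation: train on one corpus, test on another
#'
#' Mirrors the benchmark design in which one curated corpus is the training
#' set and a disjoint corpus is the test set (no outer cross-validation).
#'
#' @param train An `encoded_set` used for training.
#' @param test An `encoded_set` evaluated with the trained ensemble.
#' @inheritParams train_ensemble
#' @return List with the fitted `model`, test `predictions`, `confusion` and
#'   `metrics`.
#' @export
evaluate_transfer <- function(train, test, n_projections = 100L, top_n = 3L,
                              target_dim = 5L, k = 1L, master_seed = 1L) {
  model <- train_ensemble(train$x, train$y, n_projections = n_projections,
                          top_n = top_n, target_dim = target_dim, k = k,
                          master_seed = master_seed)
  pred <- predict(model, test$x)
  cc <- confusion(test$y, pred$label)
  list(model = model,
       predictions = cbind(test$origin, vote_fraction = pred$fraction,
                           label = pred$label),
       confusion = cc, metrics = metrics(cc))
}

#' Persist / restore a trained ensemble
#'
#' The ensemble is stored as plain JSON: configuration, the ranking table,
#' and per retained member its projection *descriptor* (l1, l2, seed — the
#' dense matrix is regenerated on load) plus the rebalanced projected
#' training instances of its k-NN model (small: ~2x the positive count rows
#' of `target_dim` columns).
#'
#' @param model An `rp_ensemble`.
#' @param path Output JSON path.
#' @return `path` invisibly (save); an `rp_ensemble` (load).
#' @export
save_ensemble <- function(model, path) {
  members <- lapply(model$members, function(m) {
    list(l1 = m$projection$l1, l2 = m$projection$l2,
         seed = m$projection$seed, train_f1 = m$train_f1, rank = m$rank,
         train_x = unname(m$model$x), train_y = m$model$y)
  })
  obj <- list(package = "hotspotRP", class = "rp_ensemble",
              n_projections = model$n_projections, top_n = model$top_n,
              target_dim = model$target_dim, k = model$k,
              n_folds = model$n_folds, master_seed = model$master_seed,
              ranking = model$ranking, members = members)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$class, "rp_ensemble")) {
    stop_data("not a saved rp_ensemble: ", path)
  }
  members <- lapply(obj$members, function(m) {
    tx <- do.call(rbind, lapply(m$train_x, function(row)
      as.numeric(unlist(row))))
    list(projection = make_projection(m$l1, m$l2, m$seed),
         model = fit_knn(tx, as.integer(unlist(m$train_y)), obj$k),
         train_f1 = m$train_f1, rank = m$rank)
  })
  ranking <- do.call(rbind, lapply(obj$ranking, as.data.frame))
  structure(list(members = members, ranking = ranking,
                 n_projections = as.integer(obj$n_projections),
                 top_n = as.integer(obj$top_n),
                 target_dim = as.integer(obj$target_dim),
                 k = as.integer(obj$k), n_folds = as.integer(obj$n_folds),
                 master_seed = as.integer(obj$master_seed)),
            class = "rp_ensemble")
}
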