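#' Rebalance a training set by undersampling the majority class
#'
#' Hotspot corpora are extremely imbalanced (under 2% positives), so the
#' training subset is rebalanced before fitting each base learner: every
#' instance of the minority class is kept and an equal number of
#' majority-class instances is drawn uniformly without replacement, yielding
#' a 1:1 class ratio. Undersampling (rather than oversampling) avoids
#' duplicated coordinates, which degenerate k-nearest-neighbour voting. The
#' output order is shuffled deterministically by `seed`.
#'
#' @param x Numeric instance matrix (N x d).
#' @param y Integer 0/1 targets of length N.
#' @param seed Integer seed for the draw.
#' @return List with the rebalanced `x`, `y` and the row indices `kept`
#'   (into the input) — always a subset of the input, never fabricated rows.
#' @export
rebalance <- function(x, y, seed) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_dim("rebalance: nrow(x) != length(y)")
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0L) {
    stop_data("rebalance: degenerate input, no positive instances")
  }
  if (length(neg) == 0L) {
    stop_data("rebalance: degenerate input, no negative instances")
  }
  kept <- with_seed(seed, {
    if (length(pos) <= length(neg)) {
      idx <- c(pos, sample(neg, length(pos)))
    } else {
      idx <- c(sample(pos, length(neg)), neg)
    }
    sample(idx)
  })
  list(x = x[kept, , drop = FALSE], y = y[kept], kept = kept)
}

#' Fit an instance-based (k-nearest-neighbour) classifier
#'
#' Lazy learner in the IBk style: training just stores the instances; all
#' computation is deferred to prediction.
#'
#' @param x Numeric instance matrix (N x d).
#' @param y Integer 0/1 targets of length N.
#' @param k Number of neighbours (default 1, the simplest instance-based
#'   learner).
#' @return A `knn_model`.
#' @seealso [predict.knn_model()]
#' @export
fit_knn <- function(x, y, k = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_dim("fit_knn: nrow(x) != length(y)")
  if (!is_binary(y)) stop_data("fit_knn: targets must be 0/1")
  if (k < 1L || k > nrow(x)) {
    stop_config("fit_knn: k must satisfy 1 <= k <= n (k = ", k, ", n = ",
                nrow(x), ")")
  }
  structure(list(x = x, y = as.integer(y), k = as.integer(k)),
            class = "knn_model")
}

#' Predict with a k-nearest-neighbour model
#'
#' For each query, the `k` nearest stored instances by Euclidean distance
#' vote by majority. Instances tied with the k-th distance are all included
#' and the vote is taken over the expanded neighbour set, which makes the
#' prediction independent of stored-instance order. A tied vote (positive
#' fraction exactly 1/2) predicts 0, the majority class of hotspot data.
#'
#' @param object A `knn_model`.
#' @param newdata Query matrix (M x d) or a single numeric vector.
#' @param ... Unused.
#' @return Data frame with `label` (0/1) and `fraction` (positive share of
#'   the effective neighbour set) per query.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  x <- object$x
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(x)) {
    stop_dim("predict.knn_model: query width ", ncol(newdata),
             " does not match stored width ", ncol(x))
  }
  # squared Euclidean distances, M x N, via the expansion |q|^2 - 2 q.x + |x|^2
  d2 <- outer(rowSums(newdata^2), rowSums(x^2), "+") -
    2 * tcrossprod(newdata, x)
  d2[d2 < 0] <- 0
  k <- object$k
  frac <- vapply(seq_len(nrow(newdata)), function(i) {
    d <- d2[i, ]
    kth <- sort(d, partial = k)[k]
    nb <- which(d <= kth + 1e-12 * max(kth, 1))
    mean(object$y[nb])
  }, numeric(1))
  data.frame(label = as.integer(frac > 0.5), fraction = frac)
}
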