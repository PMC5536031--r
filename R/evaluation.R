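#' Confusion counts for binary hotspot predictions
#'
#' @param truth Integer 0/1 vector of true labels (1 = hotspot).
#' @param predicted Integer 0/1 vector of predicted labels, same length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`; the four
#'   counts always sum to the number of evaluated instances.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_dim("confusion: truth and predicted lengths differ (",
             length(truth), " vs ", length(predicted), ")")
  }
  if (!is_binary(truth) || !is_binary(predicted)) {
    stop_data("confusion: labels must be 0/1")
  }
  structure(list(tp = sum(truth == 1 & predicted == 1),
                 fp = sum(truth == 0 & predicted == 1),
                 tn = sum(truth == 0 & predicted == 0),
                 fn = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Sensitivity, precision, F1 and MCC from confusion counts
#'
#' Computes the four standard measures
#' \deqn{Sen = TP/(TP+FN), \quad Prec = TP/(TP+FP),}
#' \deqn{F1 = 2 \cdot Prec \cdot Sen / (Prec + Sen),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}.}
#'
#' A metric whose denominator is zero is undefined and returned as `NA`
#' (explicit marker, never a silent 0) — except MCC, which by the standard
#' convention is 0 when its denominator vanishes. F1 is `NA` whenever
#' sensitivity or precision is undefined or both are zero.
#'
#' @param cc A `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return A `metric_set` list with `sen`, `prec`, `f1`, `mcc` and the
#'   input counts.
#' @export
metrics <- function(cc) {
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- f1_score(sen, prec)
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(sen = sen, prec = prec, f1 = f1, mcc = mcc,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metric_set")
}

#' Harmonic-mean F1 from sensitivity and precision
#'
#' @param sen Sensitivity (recall).
#' @param prec Precision.
#' @return `2 * prec * sen / (prec + sen)`, or `NA` when either input is
#'   `NA` or both are zero.
#' @export
f1_score <- function(sen, prec) {
  if (is.na(sen) || is.na(prec) || sen + prec == 0) return(NA_real_)
  2 * prec * sen / (prec + sen)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sen = %.3f  Prec = %.3f  F1 = %.3f  MCC = %.3f\n",
              x$sen, x$prec, x$f1, x$mcc))
  invisible(x)
}

#' Truth-independent random-predictor baseline
#'
#' Each run labels every instance positive with probability `positive_rate`,
#' independently of the truth; metrics are computed per run and the *metrics*
#' (not the counts) are averaged over runs. For such a predictor the expected
#' precision equals the class prevalence and the expected MCC is zero, which
#' makes it the floor any sequence-based hotspot predictor must clear.
#'
#' @param truth Integer 0/1 vector of true labels.
#' @param positive_rate Probability of a positive call per instance,
#'   in (0, 1].
#' @param n_runs Number of replicate runs to average (default 100).
#' @param seed Integer seed.
#' @return A `metric_set` of run-averaged values (undefined per-run values
#'   are dropped from the average; if every run is undefined the average is
#'   `NA`), with attribute `per_run` holding the run-level data frame.
#' @export
random_predictor <- function(truth, positive_rate, n_runs = 100L, seed = 1L) {
  if (positive_rate <= 0 || positive_rate > 1) {
    stop_config("random_predictor: positive_rate must be in (0, 1]")
  }
  n <- length(truth)
  runs <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      m <- metrics(confusion(truth, stats::rbinom(n, 1L, positive_rate)))
      data.frame(run = r, sen = m$sen, prec = m$prec, f1 = m$f1,
                 mcc = m$mcc)
    }))
  })
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(sen = avg(runs$sen), prec = avg(runs$prec),
                 f1 = avg(runs$f1), mcc = avg(runs$mcc),
                 counts = NULL),
            per_run = runs, class = "metric_set")
}

#' Performance sweep over reduced dimensions and window lengths
#'
#' Runs one full encode / train / transfer-test cycle per grid cell
#' (optionally repeated over derived seeds) and reports the mean of each
#' metric plus the standard deviation of F1 across repeats — the error-bar
#' summary used when comparing window lengths or projection dimensions.
#'
#' @param train_corpus,test_corpus Corpora (lists with `sequences`), e.g.
#'   from [generate_corpus()].
#' @param props A `property_table` shared by both corpora.
#' @param target_dims Integer vector of reduced dimensions L2 to sweep.
#' @param window_lengths Odd integer vector of window lengths to sweep.
#' @param n_repeats Repeated runs per cell with distinct derived seeds
#'   (default 1).
#' @inheritParams train_ensemble
#' @return Data frame with one row per (window, dimension) cell: mean `sen`,
#'   `prec`, `f1`, `mcc` and `f1_sd` over repeats.
#' @export
sweep_performance <- function(train_corpus, test_corpus, props,
                              target_dims = 5L, window_lengths = 13L,
                              n_repeats = 1L, n_projections = 20L,
                              top_n = 3L, k = 1L, master_seed = 1L) {
  if (length(target_dims) == 0L || length(window_lengths) == 0L) {
    stop_config("sweep_performance: empty sweep grid")
  }
  grid <- expand.grid(window = as.integer(window_lengths),
                      dimension = as.integer(target_dims))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    w <- grid$window[g]
    d <- grid$dimension[g]
    enc_tr <- encode_dataset(train_corpus, props, w)
    enc_ts <- encode_dataset(test_corpus, props, w)
    reps <- lapply(seq_len(n_repeats), function(r) {
      res <- evaluate_transfer(enc_tr, enc_ts, n_projections = n_projections,
                               top_n = top_n, target_dim = d, k = k,
                               master_seed = derive_seed(master_seed, "sweep",
                                                         1000L * g + r))
      with(res$metrics, data.frame(sen = sen, prec = prec, f1 = f1,
                                   mcc = mcc))
    })
    reps <- do.call(rbind, reps)
    data.frame(window = w, dimension = d,
               sen = mean(reps$sen, na.rm = TRUE),
               prec = mean(reps$prec, na.rm = TRUE),
               f1 = mean(reps$f1, na.rm = TRUE),
               mcc = mean(reps$mcc, na.rm = TRUE),
               f1_sd = if (n_repeats > 1L) stats::sd(reps$f1) else NA_real_)
  })
  do.call(rbind, rows)
}

#' ROC points from vote fractions
#'
#' Sweeps a threshold over the ensemble vote fractions used as scores and
#' returns (false positive rate, sensitivity) pairs. This goes beyond the
#' bare majority-vote decision rule; it is provided as a natural extension
#' for inspecting the score distribution.
#'
#' @param truth Integer 0/1 vector.
#' @param score Numeric scores (higher = more hotspot-like).
#' @return Data frame with `threshold`, `fpr`, `sen`, ordered by descending
#'   threshold.
#' @export
roc_points <- function(truth, score) {
  if (length(truth) != length(score)) {
    stop_dim("roc_points: truth and score lengths differ")
  }
  th <- sort(unique(c(score, Inf)), decreasing = TRUE)
  do.call(rbind, lapply(th, function(t) {
    pred <- as.integer(score >= t)
    cc <- confusion(truth, pred)
    data.frame(threshold = t,
               fpr = if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else 0,
               sen = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0)
  }))
}
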