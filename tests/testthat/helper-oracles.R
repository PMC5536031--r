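# Independent oracles and programmatic fixtures shared across test files.
# Oracles are deliberately naive (loops, explicit formulas) and never call
# the code paths they check.

# population standard deviation of the 20 elementwise products, by loop
oracle_std <- function(profile, property) {
  prod <- numeric(20)
  for (a in 1:20) prod[a] <- profile[a] * property[a]
  m <- sum(prod) / 20
  sqrt(sum((prod - m)^2) / 20)
}

# exhaustive k-NN scan: majority vote over the k nearest (ties at the k-th
# distance included), tie vote -> 0
oracle_knn <- function(train_x, train_y, query, k = 1) {
  d <- apply(train_x, 1, function(r) sqrt(sum((r - query)^2)))
  kth <- sort(d)[k]
  nb <- which(d <= kth + 1e-12 * max(kth, 1))
  frac <- mean(train_y[nb])
  as.integer(frac > 0.5)
}

# Eq.-style projection oracle: per output cell, explicit sum over source
# features of x_i * r_i
oracle_project <- function(x, r) {
  out <- matrix(0, nrow(x), ncol(r))
  for (n in seq_len(nrow(x))) {
    for (j in seq_len(ncol(r))) {
      s <- 0
      for (i in seq_len(ncol(x))) s <- s + x[n, i] * r[i, j]
      out[n, j] <- s
    }
  }
  out
}

# direct-formula MCC in extended precision via log-space denominator
oracle_mcc <- function(tp, fp, tn, fn) {
  num <- tp * tn - fp * fn
  ld <- 0.5 * (log(tp + fn) + log(tp + fp) + log(tn + fp) + log(tn + fn))
  num * exp(-ld)
}

# --- fixture builders (written to tempfiles at test time) -----------------

aaindex_record <- function(accession, values, desc = "test record") {
  v <- format(values, trim = TRUE, scientific = FALSE)
  c(paste("H", accession),
    paste("D", desc),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("    ", paste(v[1:10], collapse = "  ")),
    paste0("    ", paste(v[11:20], collapse = "  ")),
    "//")
}

write_aaindex_fixture <- function(records, path = tempfile(fileext = ".txt")) {
  writeLines(unlist(records), path)
  path
}

pssm_row <- function(pos, wt, percentages, logodds = rep(0L, 20)) {
  sprintf("%5d %s  %s  %s  0.50 1.00", pos, wt,
          paste(logodds, collapse = "  "),
          paste(percentages, collapse = "  "))
}

write_pssm_fixture <- function(rows, path = tempfile(fileext = ".pssm")) {
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("    ", paste(hotspotRP::AA_ORDER, collapse = "   ")))
  writeLines(c(header, rows), path)
  path
}

write_labels_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  if (nrow(df) == 0) file.create(path)
  else write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
  path
}

# a small separable 2-class cloud for classifier tests
make_cloud <- function(n_per_class, d = 2, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  y <- rep(c(0L, 1L), each = n_per_class)
  list(x = x, y = y)
}
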