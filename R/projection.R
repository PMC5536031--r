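#' Generate a seeded random projection matrix
#'
#' Entries are drawn independently from Uniform[0,1) and each column is then
#' divided by its Euclidean norm, giving an `l1 x l2` matrix of unit columns.
#' The uniform (all non-negative) draw is deliberate: it follows the random
#' mapping construction in which matrix elements range over 0-1 and columns
#' are normalised to unity; the columns are used as-is, without centering.
#'
#' @param l1 Source dimension (instance width).
#' @param l2 Target dimension, `1 <= l2 <= l1`.
#' @param seed Integer seed; the same seed always reproduces the same matrix.
#' @return A `projection_matrix`: list with `matrix` (l1 x l2), `l1`, `l2`,
#'   `seed`. The (l1, l2, seed) triple is a complete persistable descriptor.
#' @export
make_projection <- function(l1, l2, seed) {
  if (l2 < 1L) stop_config("make_projection: l2 must be >= 1, got ", l2)
  if (l2 > l1) {
    stop_dim("make_projection: target dimension l2 (", l2,
             ") exceeds source dimension l1 (", l1, ")")
  }
  m <- with_seed(seed, matrix(stats::runif(l1 * l2), l1, l2))
  norms <- sqrt(colSums(m^2))
  m <- m / rep(norms, each = l1)
  structure(list(matrix = m, l1 = as.integer(l1), l2 = as.integer(l2),
                 seed = as.integer(seed)),
            class = "projection_matrix")
}

#' Apply a random projection to an instance matrix
#'
#' Plain matrix product `X R`: each projected coordinate is the sum over
#' source features of `x_i * r_i` with `r_i` the i-th column entry, reducing
#' each instance from width `l1` to width `l2` while leaving the row count
#' (and any targets kept alongside) untouched.
#'
#' @param x Numeric instance matrix, N x l1.
#' @param proj A `projection_matrix` from [make_projection()].
#' @return N x l2 numeric matrix.
#' @export
project <- function(x, proj) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != proj$l1) {
    stop_dim("project: instance width ", ncol(x), " does not match ",
             "projection source dimension ", proj$l1)
  }
  unname(x %*% proj$matrix)
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("projection_matrix: %d -> %d (seed %d)\n", x$l1, x$l2, x$seed))
  invisible(x)
}
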