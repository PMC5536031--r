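#' Physicochemical evolution features for one residue
#'
#' The encoding multiplies the residue's sequence profile `SP` (20
#' substitution frequencies) elementwise with each amino-acid property `AAP`
#' (20 per-residue values) and summarises the 20 products by their standard
#' deviation, one value per property. The population form (divisor 20) is
#' used because the 20 products are the complete set of values, not a sample;
#' the alternative sample form only rescales every feature by a constant.
#'
#' @param profile Numeric 20-vector of profile frequencies in [AA_ORDER]
#'   order (non-negative, summing to 1).
#' @param props A `property_table` (J x 20 matrix).
#' @return Numeric vector of J non-negative standard deviations, named by
#'   property accession.
#' @export
residue_features <- function(profile, props) {
  if (length(profile) != 20L || ncol(props) != 20L) {
    stop_dim("residue_features: profile and properties must have 20 ",
             "amino-acid entries")
  }
  drop(std_features(matrix(profile, 1L, 20L), props))
}

# Vectorised core: profiles is L x 20, props is J x 20; returns the L x J
# matrix of population standard deviations of the elementwise products.
# For row i, property j: mean = (1/20) sum_a sp_ia p_ja and
# meansq = (1/20) sum_a sp_ia^2 p_ja^2, so sd = sqrt(meansq - mean^2).
std_features <- function(profiles, props) {
  m1 <- (profiles %*% t(props)) / 20
  m2 <- ((profiles^2) %*% t(props^2)) / 20
  out <- sqrt(pmax(m2 - m1^2, 0))
  colnames(out) <- rownames(props)
  out
}

#' Encode one residue with its sliding-window context
#'
#' Concatenates the per-residue feature vectors of the `window` positions
#' centred on `position`, in sequence order. Positions falling outside the
#' sequence contribute an all-zero block (zero padding keeps the instance
#' dimension constant and marks missing context without inventing
#' evolutionary signal).
#'
#' @param seq A `labeled_sequence` (list with `id`, `residues`, `profiles`,
#'   `labels`; see [generate_corpus()]).
#' @param position 1-based residue position to encode.
#' @param props A `property_table`.
#' @param window Odd window length (default 13).
#' @return List with `vector` (length `window * J`), `target` (0/1) and
#'   `origin` (id, position).
#' @export
encode_window <- function(seq, position, props, window = 13L) {
  check_window(window)
  L <- nchar(seq$residues)
  if (position < 1L || position > L) {
    stop_dim("encode_window: position ", position, " outside sequence of ",
             "length ", L)
  }
  J <- nrow(props)
  half <- (window - 1L) %/% 2L
  feats <- std_features(seq$profiles, props)
  v <- numeric(window * J)
  for (w in seq_len(window)) {
    p <- position - half + (w - 1L)
    if (p >= 1L && p <= L) {
      v[((w - 1L) * J + 1L):(w * J)] <- feats[p, ]
    }
  }
  list(vector = v, target = seq$labels[position],
       origin = list(id = seq$id, position = position))
}

#' Encode every residue of a corpus into windowed feature instances
#'
#' Computes each sequence's residue features once and assembles one instance
#' per residue by stacking the window offsets, so no feature is recomputed
#' per window placement.
#'
#' @param seqs List of `labeled_sequence` objects (or a corpus list holding
#'   `$sequences`).
#' @param props A `property_table`.
#' @param window Odd window length (default 13).
#' @return An `encoded_set`: list with `x` (N x window*J instance matrix,
#'   columns named `accession@offset`), `y` (integer 0/1 targets),
#'   `origin` (data frame of id, position, wild type), `window`.
#' @export
encode_dataset <- function(seqs, props, window = 13L) {
  check_window(window)
  if (!is.null(seqs$sequences)) seqs <- seqs$sequences
  J <- nrow(props)
  half <- (window - 1L) %/% 2L
  offs <- -half:half
  xs <- vector("list", length(seqs))
  ys <- vector("list", length(seqs))
  origins <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    sq <- seqs[[s]]
    L <- nchar(sq$residues)
    stopifnot(nrow(sq$profiles) == L, length(sq$labels) == L)
    feats <- std_features(sq$profiles, props)
    x <- matrix(0, L, window * J)
    for (w in seq_along(offs)) {
      src <- seq_len(L) + offs[w]
      ok <- src >= 1L & src <= L
      x[ok, ((w - 1L) * J + 1L):(w * J)] <- feats[src[ok], , drop = FALSE]
    }
    xs[[s]] <- x
    ys[[s]] <- as.integer(sq$labels)
    origins[[s]] <- data.frame(id = sq$id, position = seq_len(L),
                               wild_type = strsplit(sq$residues, "")[[1L]])
  }
  x <- do.call(rbind, xs)
  if (is.null(x)) x <- matrix(0, 0L, window * J)
  colnames(x) <- paste0(rep(rownames(props), times = window), "@",
                        rep(offs, each = J))
  structure(list(x = x, y = unlist(ys, use.names = FALSE) %||% integer(0),
                 origin = do.call(rbind, origins) %||%
                   data.frame(id = character(0), position = integer(0),
                              wild_type = character(0)),
                 window = as.integer(window)),
            class = "encoded_set")
}

check_window <- function(window) {
  if (length(window) != 1L || is.na(window) || window < 1L ||
      window %% 2L == 0L) {
    stop_config("window length must be a positive odd integer, got: ",
                paste(window, collapse = ","))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.encoded_set <- function(x, ...) {
  cat(sprintf("encoded_set: %d instances x %d features (window %d), %d positive\n",
              nrow(x$x), ncol(x$x), x$window, sum(x$y == 1L)))
  invisible(x)
}

#' Write / read an encoded instance matrix as TSV
#'
#' Dense numeric TSV with a header of `accession@offset` feature names plus
#' leading `id`, `position`, `wild_type`, `target` columns.
#'
#' @param enc An `encoded_set`.
#' @param path Output TSV path.
#' @return `path` invisibly (writer); an `encoded_set` (reader).
#' @export
write_features <- function(enc, path) {
  df <- cbind(enc$origin, target = enc$y, as.data.frame(enc$x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param window Window length recorded in the file's feature names; inferred
#'   from the header when `NULL`.
#' @export
read_features <- function(path, window = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE)
  meta <- c("id", "position", "wild_type", "target")
  featcols <- setdiff(names(df), meta)
  if (is.null(window)) {
    offs <- unique(sub("^.*@", "", featcols))
    window <- length(offs)
  }
  structure(list(x = as.matrix(df[, featcols, drop = FALSE]),
                 y = as.integer(df$target),
                 origin = df[, c("id", "position", "wild_type")],
                 window = as.integer(window)),
            class = "encoded_set")
}
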