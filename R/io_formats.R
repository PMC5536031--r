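#' Read an AAindex1 flat-file of amino-acid indices
#'
#' Parses the AAindex1 record layout: each record starts with an `H` accession
#' line, carries a `D` description, and stores its 20 per-residue values on
#' the two lines following the `I` header (ten values each, in the canonical
#' A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/Y/V order). Records are delimited
#' by `//`.
#'
#' Records containing any missing cell (`NA` in the file) are dropped, so the
#' number of usable properties is a property of the input file, not a
#' constant; the full release contemporaneous with the method carries 544
#' usable indices. Dropped accessions are recorded in the `"dropped"`
#' attribute.
#'
#' @param path Path to an AAindex1 flat-file.
#' @return A `property_table`: numeric matrix with one row per usable index
#'   (rownames = accessions, sorted), 20 columns in [AA_ORDER] order, and
#'   attributes `descriptions` (named character) and `dropped` (accessions
#'   removed by the missing-value policy).
#' @seealso [write_aaindex1()], [residue_features()]
#' @export
read_aaindex1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) {
    stop_data("empty AAindex1 file: ", path)
  }
  rec_end <- grep("^//", lines)
  if (length(rec_end) == 0L) {
    stop_data("no '//' record delimiters in AAindex1 file: ", path)
  }
  starts <- c(1L, head(rec_end, -1L) + 1L)
  acc <- character(0)
  desc <- character(0)
  vals <- list()
  dropped <- character(0)
  for (r in seq_along(rec_end)) {
    rec <- lines[starts[r]:(rec_end[r] - 1L)]
    if (all(!nzchar(trimws(rec)))) next
    h <- grep("^H ", rec, value = TRUE)
    accession <- if (length(h)) trimws(sub("^H ", "", h[1L])) else
      sprintf("RECORD%04d", r)
    d <- grep("^D ", rec, value = TRUE)
    i_at <- grep("^I[ ]", rec)
    if (length(i_at) == 0L) {
      stop_data("AAindex1 record ", accession, ": no 'I' value block")
    }
    if (i_at[1L] + 2L > length(rec)) {
      stop_data("AAindex1 record ", accession, ": truncated 'I' value block")
    }
    cells <- unlist(strsplit(trimws(paste(rec[i_at[1L] + 1L],
                                          rec[i_at[1L] + 2L])), "\\s+"))
    if (length(cells) != 20L) {
      stop_data("AAindex1 record ", accession, ": expected 20 value cells, ",
                "found ", length(cells))
    }
    v <- suppressWarnings(as.numeric(ifelse(cells %in% c("NA", "-"), NA,
                                            cells)))
    bad <- !is.na(cells) & !(cells %in% c("NA", "-")) & is.na(v)
    if (any(bad)) {
      stop_data("AAindex1 record ", accession, ": unparsable value cell(s): ",
                paste(cells[bad], collapse = " "))
    }
    if (anyNA(v)) {
      dropped <- c(dropped, accession)
      next
    }
    acc <- c(acc, accession)
    desc <- c(desc, if (length(d)) trimws(sub("^D ", "", d[1L])) else "")
    vals[[length(vals) + 1L]] <- v
  }
  if (length(vals) == 0L) {
    stop_data("AAindex1 file holds no usable (complete) records: ", path)
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(acc, AA_ORDER)
  ord <- order(acc)
  m <- m[ord, , drop = FALSE]
  structure(m, descriptions = stats::setNames(desc, acc)[rownames(m)],
            dropped = dropped, class = c("property_table", class(m)))
}

#' Write a property table in AAindex1 flat-file layout
#'
#' Serialises values with up to 15 significant digits so that a parse →
#' write → parse round trip reproduces the numbers exactly for values that
#' originated as decimal text.
#'
#' @param props A `property_table` from [read_aaindex1()] or
#'   [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(props, path) {
  desc <- attr(props, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (a in rownames(props)) {
    v <- format(unname(props[a, ]), trim = TRUE, digits = 15,
                scientific = FALSE)
    writeLines(c(paste("H", a),
                 paste("D", if (!is.null(desc)) desc[[a]] else ""),
                 "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
                 paste0("    ", paste(v[1:10], collapse = "  ")),
                 paste0("    ", paste(v[11:20], collapse = "  ")),
                 "//"), con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM into per-residue frequency profiles
#'
#' Expects the PSI-BLAST ASCII dialect: header lines, then one row per
#' residue holding the 1-based position, the wild-type letter, 20 log-odds
#' columns and 20 percentage columns (optionally followed by the information
#' and weight columns, which are ignored). Only the percentage block is used:
#' it is divided by 100 and renormalised to sum exactly 1, matching the
#' reading of the profile as substitution *frequencies*. Rows whose 20
#' percentages are all zero are replaced by the uniform background (1/20
#' each); their positions are recorded in the `"uniform_rows"` attribute.
#'
#' @param path Path to a PSI-BLAST ASCII PSSM file.
#' @return A numeric matrix with one row per residue position and 20 columns
#'   in [AA_ORDER] order, each row non-negative and summing to 1 (±1e-9);
#'   attributes `wild_type` (character vector of residue letters) and
#'   `uniform_rows` (positions replaced by the background policy).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_at <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (length(data_at) == 0L) {
    stop_data("no PSSM data rows found in: ", path)
  }
  n <- length(data_at)
  freqs <- matrix(0, n, 20L, dimnames = list(NULL, AA_ORDER))
  wt <- character(n)
  pos <- integer(n)
  uniform_rows <- integer(0)
  for (i in seq_len(n)) {
    ln <- data_at[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    pos[i] <- as.integer(tok[1L])
    wt[i] <- tok[2L]
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(nums) || !(length(nums) %in% c(40L, 42L))) {
      stop_data("PSSM parse error at line ", ln, " of ", path,
                ": expected 40 numeric columns (plus optional information/",
                "weight), found ", sum(!is.na(nums)))
    }
    p <- nums[21:40] / 100
    if (all(p == 0)) {
      p <- rep(1 / 20, 20L)
      uniform_rows <- c(uniform_rows, pos[i])
    } else {
      p <- p / sum(p)
    }
    freqs[i, ] <- p
  }
  rownames(freqs) <- pos
  structure(freqs, wild_type = wt, uniform_rows = uniform_rows,
            class = c("residue_profiles", class(freqs)))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences (names = record ids up to the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read per-residue hotspot labels
#'
#' Labels are supplied as a headerless tab-separated table with columns
#' sequence id, 1-based residue position, label (1 = hotspot, 0 =
#' non-hotspot). Following the whole-sequence convention, every residue not
#' listed in the file is a non-hotspot, so the reader needs the sequence
#' lengths to materialise full label vectors. Duplicate rows are tolerated
#' when consistent and rejected when conflicting; row order is immaterial.
#'
#' @param path Path to the labels TSV.
#' @param lengths Named integer vector of sequence lengths (names = sequence
#'   ids). Ids present in the file but absent here are an error, as are
#'   positions outside `[1, length]`.
#' @return Named list of integer 0/1 vectors, one per entry of `lengths`
#'   (positions are 1-based externally; vectors are plain R vectors indexed
#'   from 1).
#' @seealso [label_summary()]
#' @export
read_labels <- function(path, lengths) {
  if (is.null(names(lengths)) || anyNA(names(lengths))) {
    stop_config("read_labels: 'lengths' must be a named integer vector")
  }
  out <- lapply(lengths, function(L) integer(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("id", "position", "label"),
                            colClasses = c("character", "integer", "integer"),
                            quote = "", comment.char = "")
    if (!all(df$label %in% c(0L, 1L))) {
      stop_data("labels must be 0 or 1 in: ", path)
    }
    df <- unique(df)
    key <- paste(df$id, df$position)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop_data("conflicting duplicate label rows for (id, position) = (",
                dup, ") in: ", path)
    }
    for (j in seq_len(nrow(df))) {
      id <- df$id[j]
      p <- df$position[j]
      if (!id %in% names(out)) {
        stop_data("label row for unknown sequence id '", id, "' in: ", path)
      }
      if (p < 1L || p > lengths[[id]]) {
        stop_data("label position ", p, " outside sequence '", id,
                  "' (length ", lengths[[id]], ") in: ", path)
      }
      out[[id]][p] <- df$label[j]
    }
  }
  out
}

#' Summarise a label set
#'
#' @param labels Named list of 0/1 vectors, as returned by [read_labels()].
#' @return One-row data frame with `n_hotspot`, `n_other`, `n_total` and
#'   `ratio_pct` (hotspot percentage of all residues).
#' @export
label_summary <- function(labels) {
  v <- unlist(labels, use.names = FALSE)
  data.frame(n_hotspot = sum(v == 1L), n_other = sum(v == 0L),
             n_total = length(v), ratio_pct = 100 * mean(v == 1L))
}

#' Write per-residue predictions
#'
#' One row per residue: sequence id, 1-based position, wild-type letter,
#' ensemble positive-vote fraction and predicted 0/1 label. Vote fractions
#' are serialised with enough digits (up to 10 significant) to round-trip
#' through [read_predictions()].
#'
#' @param records Data frame with columns `id`, `position`, `wild_type`,
#'   `vote_fraction`, `label`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  need <- c("id", "position", "wild_type", "vote_fraction", "label")
  if (!all(need %in% names(records))) {
    stop_config("write_predictions: records must have columns ",
                paste(need, collapse = ", "))
  }
  df <- records[, need]
  df$vote_fraction <- vapply(df$vote_fraction, function(x)
    format(x, digits = 10, scientific = FALSE, trim = TRUE), character(1))
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop_data("cannot write predictions to '", path,
                                  "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#'
#' @param path Predictions TSV path.
#' @return Data frame with columns `id`, `position`, `wild_type`,
#'   `vote_fraction`, `label`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "numeric", "integer"),
                    quote = "", comment.char = "")
}
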