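#' Generate a synthetic whole-sequence hotspot corpus
#'
#' Emulates the statistical shape of a curated whole-sequence hotspot
#' benchmark without any external downloads: a handful of protein chains
#' whose residues carry PSSM-like frequency profiles, a sparse per-residue
#' hotspot labelling at realistic prevalence (~1.8% by default, the BID0
#' ratio), and an AAindex-like property table. Defaults give ~3000 residues,
#' the scale of the smaller benchmark corpus.
#'
#' Background profiles are Dirichlet draws concentrated on the wild-type
#' residue (concentration `alpha_wt` on the wild type, `alpha_bg` on the
#' remaining 19), which produces peaked, PSSM-like rows. Hotspot labels are
#' independent Bernoulli(`prevalence`) draws. The plantable signal acts on
#' the *profiles* of hotspot residues: their Dirichlet concentration is
#' raised by `2 * effect_size` on a fixed signal subset (Trp, Tyr, Arg — the
#' residues classically enriched at interaction hotspots), so hotspot
#' profiles spread substitution mass over that subset and their
#' product-standard-deviation features differ in expectation. Because real
#' hotspots cluster in hot regions whose physicochemical environment is
#' itself distinctive, the tilt extends over the hotspot's neighbourhood
#' with linearly decaying strength (full at the hotspot, zero beyond
#' `signal_span` residues); overlapping neighbourhoods add. `effect_size =
#' 0` is an exact null: hotspot and background profiles are identically
#' distributed. Properties are i.i.d. standard normal per amino acid.
#'
#' @param n_sequences Number of chains (default 20).
#' @param length_range Min/max chain length, drawn uniformly (default
#'   c(80, 220)).
#' @param prevalence Per-residue hotspot probability (default 0.018).
#' @param effect_size Signal strength, >= 0 (default 2).
#' @param signal_span Neighbourhood half-width over which the hotspot tilt
#'   decays to zero (default 6, matching the default window half-width).
#' @param n_properties Number of synthetic amino-acid indices (default 40).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param allow_empty Permit a corpus whose expected positive count is below
#'   one without warning (default FALSE).
#' @return A corpus list: `sequences` (list of `labeled_sequence`: `id`,
#'   `residues`, `profiles` L x 20 matrix, `labels` 0/1), `properties` (a
#'   `property_table`), `signal_aa` (the tilted subset), and the generating
#'   parameters.
#' @export
generate_corpus <- function(n_sequences = 20L, length_range = c(80L, 220L),
                            prevalence = 0.018, effect_size = 2,
                            signal_span = 6L, n_properties = 40L, seed = 1L,
                            allow_empty = FALSE) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop_config("generate_corpus: prevalence must be in (0, 1)")
  }
  if (effect_size < 0) stop_config("generate_corpus: effect_size must be >= 0")
  signal_aa <- c("W", "Y", "R")
  alpha_wt <- 10
  alpha_bg <- 0.5
  out <- with_seed(seed, {
    props <- matrix(stats::rnorm(n_properties * 20L), n_properties, 20L,
                    dimnames = list(sprintf("SYN%04d", seq_len(n_properties)),
                                    AA_ORDER))
    lens <- sample(length_range[1]:length_range[2], n_sequences,
                   replace = TRUE)
    sig <- match(signal_aa, AA_ORDER)
    seqs <- vector("list", n_sequences)
    for (s in seq_len(n_sequences)) {
      L <- lens[s]
      aa_idx <- sample.int(20L, L, replace = TRUE)
      labels <- stats::rbinom(L, 1L, prevalence)
      # concentration tilt decays linearly from each hotspot to zero at
      # signal_span + 1; overlapping hot regions add
      tilt <- numeric(L)
      if (effect_size > 0) {
        for (i in which(labels == 1L)) {
          o <- max(1L, i - signal_span):min(L, i + signal_span)
          tilt[o] <- tilt[o] + 2 * effect_size *
            (1 - abs(o - i) / (signal_span + 1))
        }
      }
      profiles <- matrix(0, L, 20L, dimnames = list(NULL, AA_ORDER))
      for (i in seq_len(L)) {
        alpha <- rep(alpha_bg, 20L)
        alpha[aa_idx[i]] <- alpha_wt
        alpha[sig] <- alpha[sig] + tilt[i]
        profiles[i, ] <- rdirichlet1(alpha)
      }
      seqs[[s]] <- list(id = sprintf("SYNSEQ%03d", s),
                        residues = paste(AA_ORDER[aa_idx], collapse = ""),
                        profiles = profiles, labels = as.integer(labels))
    }
    list(seqs = seqs, props = props)
  })
  total <- sum(vapply(out$seqs, function(s) nchar(s$residues), integer(1)))
  if (!allow_empty && prevalence * total < 1) {
    warning("generate_corpus: expected positive count below 1 (",
            signif(prevalence * total, 3), "); corpus may hold no hotspots")
  }
  props <- structure(out$props,
                     descriptions = stats::setNames(
                       rep("synthetic standard-normal index",
                           n_properties), rownames(out$props)),
                     dropped = character(0),
                     class = c("property_table", class(out$props)))
  list(sequences = out$seqs, properties = props, signal_aa = signal_aa,
       prevalence = prevalence, effect_size = effect_size,
       signal_span = as.integer(signal_span), seed = seed)
}

# one Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Write a corpus to standard on-disk formats
#'
#' Emits the corpus through the same external formats the package reads:
#' `sequences.fasta`, one PSI-BLAST-dialect ASCII PSSM per chain
#' (`<id>.pssm`, log-odds block zeroed, percentages as integers summing to
#' 100 by largest remainder), `labels.tsv` (hotspot rows only, per the
#' whole-sequence convention) and `aaindex.txt` (AAindex1 layout, marked
#' synthetic by its SYN accessions). Reading the files back exercises the
#' real parsers; integer percentage rounding means reread profiles match the
#' generated ones to ~1/200 per cell, not bit-exactly.
#'
#' @param corpus A corpus from [generate_corpus()] or [worked_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_corpus()]
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(corpus$sequences, `[[`, character(1), "residues")
  names(seqs) <- vapply(corpus$sequences, `[[`, character(1), "id")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              file.path(dir, "sequences.fasta"))
  lab <- NULL
  for (sq in corpus$sequences) {
    write_pssm(sq, file.path(dir, paste0(sq$id, ".pssm")))
    hp <- which(sq$labels == 1L)
    if (length(hp)) {
      lab <- rbind(lab, data.frame(id = sq$id, position = hp, label = 1L))
    }
  }
  labfile <- file.path(dir, "labels.tsv")
  if (is.null(lab)) {
    file.create(labfile)
  } else {
    utils::write.table(lab, labfile, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_aaindex1(corpus$properties, file.path(dir, "aaindex.txt"))
  invisible(dir)
}

# integer percentages summing to 100 by largest remainder
integer_percentages <- function(p) {
  raw <- p * 100
  fl <- floor(raw)
  rem <- 100L - sum(fl)
  if (rem > 0) {
    up <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[up] <- fl[up] + 1
  }
  as.integer(fl)
}

write_pssm <- function(sq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("    ", paste(AA_ORDER, collapse = "   "), "   ",
                      paste(AA_ORDER, collapse = "   "))), con)
  wt <- strsplit(sq$residues, "")[[1L]]
  for (i in seq_len(nrow(sq$profiles))) {
    pct <- integer_percentages(sq$profiles[i, ])
    writeLines(sprintf("%5d %s  %s  %s  0.00 0.00", i, wt[i],
                       paste(rep("0", 20L), collapse = "  "),
                       paste(pct, collapse = "  ")), con)
  }
}

#' Read a corpus directory written by [write_corpus()]
#'
#' Assembles `labeled_sequence` objects by running the real FASTA, PSSM and
#' label readers over the directory.
#'
#' @param dir Corpus directory.
#' @param aaindex Optional path to the AAindex1 file (default
#'   `dir/aaindex.txt`).
#' @return A corpus list with `sequences` and `properties`.
#' @export
read_corpus <- function(dir, aaindex = file.path(dir, "aaindex.txt")) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  labels <- read_labels(file.path(dir, "labels.tsv"),
                        stats::setNames(nchar(seqs), names(seqs)))
  sequences <- lapply(names(seqs), function(id) {
    prof <- read_pssm(file.path(dir, paste0(id, ".pssm")))
    list(id = id, residues = seqs[[id]],
         profiles = unclass(prof)[, , drop = FALSE], labels = labels[[id]])
  })
  props <- if (file.exists(aaindex)) read_aaindex1(aaindex) else NULL
  list(sequences = sequences, properties = props)
}

#' Tiny deterministic corpus with hand-checkable numbers
#'
#' Two 15-residue chains, three properties, every profile and property value
#' a small integer (profiles in twentieths), built for by-hand verification
#' of the encoding arithmetic: the wild type carries 16/20 of the profile
#' mass and the next four amino acids in canonical order 1/20 each. The
#' properties are the integers 1..20, a constant 2 (zero-variance check) and
#' a one-hot 5 on valine.
#'
#' @return A corpus list with `sequences` and `properties` (30 residues, 2
#'   hotspots: chain 1 position 8, chain 2 position 3).
#' @export
worked_fixture <- function() {
  mk_profile <- function(aa_idx) {
    p <- numeric(20L)
    p[aa_idx] <- 16 / 20
    p[(aa_idx + 0:3) %% 20L + 1L] <- 1 / 20
    p / sum(p)
  }
  mk_seq <- function(id, aa_idx, hot_pos) {
    profiles <- t(vapply(aa_idx, mk_profile, numeric(20L)))
    colnames(profiles) <- AA_ORDER
    labels <- integer(length(aa_idx))
    labels[hot_pos] <- 1L
    list(id = id, residues = paste(AA_ORDER[aa_idx], collapse = ""),
         profiles = profiles, labels = labels)
  }
  props <- rbind(FIX00001 = 1:20,
                 FIX00002 = rep(2, 20L),
                 FIX00003 = c(rep(0, 19L), 5))
  colnames(props) <- AA_ORDER
  props <- structure(props,
                     descriptions = c(FIX00001 = "integers 1..20",
                                      FIX00002 = "constant 2",
                                      FIX00003 = "one-hot valine 5"),
                     dropped = character(0),
                     class = c("property_table", class(props)))
  list(sequences = list(mk_seq("FIXA", c(1:15), 8L),
                        mk_seq("FIXB", c(16:20, 1:10), 3L)),
       properties = props)
}
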