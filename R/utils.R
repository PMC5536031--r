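#' Canonical amino-acid order
#'
#' The 20 standard amino acids in the canonical PSI-BLAST / AAindex1 column
#' order (A R N D C Q E G H I L K M F P S T W Y V). Every 20-vector in the
#' package — profile rows, property rows, elementwise products — is indexed in
#' this order.
#'
#' @format Character vector of length 20 (one-letter codes).
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# condition helpers: config errors (bad parameters), data errors (bad input
# content), dimension errors (mismatched widths/lengths)
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("hotspotRP_config_error",
                                             "hotspotRP_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("hotspotRP_data_error",
                                             "hotspotRP_error")))
}

stop_dim <- function(...) {
  stop(errorCondition(paste0(...), class = c("hotspotRP_dim_error",
                                             "hotspotRP_error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package internals never perturb the user's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a role-specific seed from a master seed
#'
#' One master integer reproduces a whole experiment: every internal source of
#' randomness (projection draws, resampling, fold assignment, simulated
#' predictors, corpus generation) uses a seed derived as
#' `(master + role_offset + index) mod (2^31 - 1)`. The role offsets are
#' fixed constants, so streams for different roles never collide for the
#' master seeds in ordinary use.
#'
#' @param master Master seed (integer).
#' @param role One of `"projection"`, `"resample"`, `"folds"`, `"predictor"`,
#'   `"corpus"`, `"sweep"`.
#' @param index Optional non-negative index within the role (e.g. the
#'   projection number).
#' @return An integer seed.
#' @export
derive_seed <- function(master, role, index = 0L) {
  offsets <- c(projection = 100000, resample = 200000, folds = 300000,
               predictor = 400000, corpus = 500000, sweep = 600000)
  if (!role %in% names(offsets)) {
    stop_config("unknown seed role: ", role)
  }
  as.integer((as.double(master) + offsets[[role]] + as.double(index)) %%
               2147483647)
}

is_binary <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}
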