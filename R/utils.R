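# RNG hygiene: run code under a given seed and restore the caller's
# RNG state afterwards, so generator calls are reproducible without
# clobbering the session stream.
with_rng_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed reproduces the whole pipeline: each stage draws its
#' own seed through a fixed Lehmer-style multiplicative hash, so stages
#' are decoupled (re-running one stage never shifts another's stream).
#' Results stay below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (or a stage name from the fixed
#'   pipeline stage list).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(
    "simulate" = 1, "transcripts" = 2, "prep" = 3, "screen_features" = 4,
    "screen_contrasts" = 5, "risk_amci" = 6, "risk_namci" = 7,
    "risk_mci" = 8, "risk_multinomial" = 9
  )
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else {
    as.integer(stage)
  }
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(seed) %% m + k * 2654435.0) %% m
  out <- (48271 * (s + 1)) %% m
  as.integer(max(out, 1))
}

code_gender <- function(gender) {
  if (is.numeric(gender)) return(gender)
  out <- ifelse(tolower(gender) %in% c("male", "m"), 1,
    ifelse(tolower(gender) %in% c("female", "f"), 0, NA_real_)
  )
  if (anyNA(out)) stop("gender must be 'female' or 'male' (or numeric 0/1)")
  out
}

# Stratified fold assignment: within each class, participants are
# shuffled and dealt round-robin into folds, so every fold keeps the
# class balance. Small case groups make unstratified folds degenerate.
make_stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}
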