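#' Default feature registry
#'
#' The registry is the package's authoritative list of the quantitative
#' features the pipeline operates on: 44 acoustic features computed from
#' the recorded response and 47 language features computed from the
#' transcript, 91 in total. Six acoustic vocal-tremor measures (`ATrP`,
#' `FTrP`, `ATrI`, `FTrI`, `ATrF`, `FTrF`) are the only features allowed
#' to carry missing values; tremor estimation fails on some recordings.
#'
#' Beyond the columns every registry must have (`name`, `modality`,
#' `may_be_missing`), the default registry flags which language features
#' are verbosity-linked counts (`is_count`). Count features (words,
#' syllables, content-unit mentions, lexical-category counts) all grow
#' with how much a participant says, so the synthetic generator gives
#' them a shared latent "verbosity" factor.
#'
#' The acoustic feature names follow standard voice-analysis quantities
#' (F0 statistics, jitter, shimmer, harmonics-to-noise, intensity,
#' formants, timing, spectral balance, tremor). They are registry entries
#' only: this package never computes acoustics from audio; acoustic
#' columns enter the pipeline as externally supplied or synthetic data.
#'
#' @param n_language,n_acoustic Optional reduced sizes for the registry
#'   (first `n` features of each modality are kept); used mainly by tests.
#'   Defaults keep all 47 language and 44 acoustic entries.
#'
#' @return A tibble with columns `name` (unique feature name), `modality`
#'   (`"language"` or `"acoustic"`), `may_be_missing` (logical) and
#'   `is_count` (logical; verbosity-linked count feature).
#' @export
#' @examples
#' reg <- feature_registry()
#' dplyr::count(reg, modality)
feature_registry <- function(n_language = NULL, n_acoustic = NULL) {
  lang <- tibble::tibble(
    name = c(
      # content-unit features
      "Count of DISTINCT RELATED content units",
      "Count of RELATED content units",
      "Count of ALL content units",
      "Count of ALL DISTINCT content units",
      "Count of content units on RIGHT side of picture",
      "Count of DISTINCT content units on RIGHT side of picture",
      "Count of content units on LEFT side of picture",
      "Count of DISTINCT content units on LEFT side of picture",
      "Both Sides Total Content Units",
      "Both Sides Total Content Units DISTINCT",
      # lexical-category counts
      "Count of nouns",
      "Count of prepositions",
      "Count of indefinite articles",
      "Count of modals",
      "Count of all function words",
      "Pro-sentences",
      "Count of verbs",
      "Count of adjectives",
      "Count of adverbs",
      "Count of personal pronouns",
      "Count of determiners",
      "Count of conjunctions",
      "Count of cardinal numbers",
      "Count of interjections",
      "Count of particles",
      "Count of wh-words",
      "Count of proper nouns",
      "Count of plural nouns",
      "Count of past tense verbs",
      "Count of gerunds",
      "Count of third person singular verbs",
      "Count of base form verbs",
      "Count of comparative adjectives",
      "Count of superlative adjectives",
      # length and derived measures
      "Count of words",
      "Count of Syllables",
      "Count of sentences",
      "Count of complete sentences",
      "Count of phrases",
      "Syllables per word min",
      "Count of unique words",
      "Type token ratio",
      "Mean words per sentence",
      "Mean syllables per word",
      "Max words per sentence",
      "Mean word length",
      "Count of filler words"
    ),
    modality = "language",
    may_be_missing = FALSE
  )
  lang$is_count <- !(lang$name %in% c(
    "Syllables per word min", "Type token ratio", "Mean words per sentence",
    "Mean syllables per word", "Max words per sentence", "Mean word length"
  ))

  ac <- tibble::tibble(
    name = c(
      "Acoustics mean of F0", "Acoustics standard deviation of F0",
      "Acoustics minimum of F0", "Acoustics maximum of F0",
      "Acoustics median of F0",
      "Acoustics jitter local", "Acoustics jitter local absolute",
      "Acoustics jitter rap", "Acoustics jitter ppq5", "Acoustics jitter ddp",
      "Acoustics shimmer local", "Acoustics shimmer local dB",
      "Acoustics shimmer apq3", "Acoustics shimmer apq5",
      "Acoustics shimmer apq11", "Acoustics shimmer dda",
      "Acoustics mean HNR", "Acoustics standard deviation of HNR",
      "Acoustics mean intensity", "Acoustics standard deviation of intensity",
      "Acoustics minimum intensity", "Acoustics maximum intensity",
      "Acoustics mean F1", "Acoustics mean F2", "Acoustics mean F3",
      "Acoustics standard deviation of F1", "Acoustics standard deviation of F2",
      "Acoustics standard deviation of F3",
      "Acoustics speaking rate", "Acoustics articulation rate",
      "Acoustics phonation time", "Acoustics number of pauses",
      "Acoustics mean pause duration", "Acoustics speech breaks",
      "Acoustics fraction voiced",
      "Acoustics spectral slope", "Acoustics alpha ratio",
      "Acoustics Hammarberg index",
      "ATrP", "FTrP", "ATrI", "FTrI", "ATrF", "FTrF"
    ),
    modality = "acoustic",
    may_be_missing = FALSE,
    is_count = FALSE
  )
  ac$may_be_missing[ac$name %in% tremor_features()] <- TRUE

  if (!is.null(n_language)) lang <- lang[seq_len(n_language), ]
  if (!is.null(n_acoustic)) ac <- ac[seq_len(n_acoustic), ]
  out <- dplyr::bind_rows(lang, ac)
  validate_registry(out)
  out
}

#' Names of the six vocal-tremor features
#'
#' Amplitude- and frequency-tremor power, intensity and frequency measures;
#' the only registry entries permitted to carry missing values.
#'
#' @return Character vector of six feature names.
#' @export
tremor_features <- function() {
  c("ATrP", "FTrP", "ATrI", "FTrI", "ATrF", "FTrF")
}

validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  req <- c("name", "modality", "may_be_missing")
  missing_cols <- setdiff(req, names(registry))
  if (length(missing_cols) > 0) {
    stop("registry lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(registry$name)) {
    stop("registry feature names must be unique")
  }
  if (!all(registry$modality %in% c("acoustic", "language"))) {
    stop("registry modality must be 'acoustic' or 'language'")
  }
  invisible(registry)
}

registry_features <- function(registry, modality = NULL) {
  validate_registry(registry)
  if (is.null(modality)) return(registry$name)
  registry$name[registry$modality == modality]
}
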