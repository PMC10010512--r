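#' Transcripts
#'
#' A transcript is a tibble of ordered, POS-tagged tokens with columns
#' `token`, `pos` (Penn-Treebank-style tag) and `sentence` (integer
#' sentence index, nondecreasing). Tagging is an input, not a stage:
#' the scorer consumes pre-tagged tokens so that results are
#' deterministic and independent of any particular tagger.
#'
#' @name transcript
NULL

PUNCT_TAGS <- c(".", ",", ":", "``", "''", "(", ")", "-LRB-", "-RRB-", "$", "#", "SYM")

KNOWN_TAGS <- c(
  "CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
  "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$", "RB", "RBR",
  "RBS", "RP", "TO", "UH", "VB", "VBD", "VBG", "VBN", "VBP", "VBZ",
  "WDT", "WP", "WP$", "WRB", PUNCT_TAGS
)

as_transcript <- function(x) {
  t <- tibble::as_tibble(x)
  req <- c("token", "pos", "sentence")
  missing_cols <- setdiff(req, names(t))
  if (length(missing_cols) > 0) {
    stop("transcript lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(t) > 0 && is.unsorted(t$sentence)) {
    stop("transcript sentence indices must be nondecreasing")
  }
  t
}

#' Read CoNLL-like transcript files
#'
#' Each transcript file is a tab-separated table with columns
#' `token`, `pos`, `sentence` (header optional when the three columns
#' are in that order). `read_transcripts()` reads every `*.tsv` in a
#' directory, taking the participant id from the file name.
#'
#' @param path A transcript TSV file (`read_transcript`) or a directory
#'   of them (`read_transcripts`).
#' @param participant_id Id to attach; defaults to the file name without
#'   extension.
#' @return A tibble with columns `participant_id`, `token`, `pos`,
#'   `sentence`.
#' @export
read_transcript <- function(path, participant_id = NULL) {
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("^token\t", first)
  t <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("token", "pos", "sentence"),
    skip = 0L,
    col_types = readr::cols(
      token = readr::col_character(),
      pos = readr::col_character(),
      sentence = readr::col_integer()
    ),
    progress = FALSE
  )
  out <- as_transcript(t)
  tibble::add_column(out, participant_id = participant_id, .before = 1)
}

#' @rdname read_transcript
#' @export
read_transcripts <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no .tsv transcript files found in ", path)
  purrr::map_dfr(files, read_transcript)
}

# Greedy longest-match-first scan of a token sequence against the lexicon.
# Matching is case-insensitive, left-to-right and non-overlapping: at each
# position the longest surface form starting there wins (so "cookie jar"
# is one mention of cookie_jar, not cookie + jar). Returns one row per
# matched mention with the unit's attributes.
match_content_units <- function(transcript, lexicon) {
  transcript <- as_transcript(transcript)
  if (!inherits(lexicon, "pd_lexicon")) lexicon <- content_unit_lexicon(lexicon)
  toks <- tolower(transcript$token)
  n <- length(toks)
  forms <- lexicon
  form_tokens <- strsplit(forms$surface_form, " ", fixed = TRUE)
  form_len <- lengths(form_tokens)
  ord <- order(-form_len)
  form_tokens <- form_tokens[ord]
  forms <- forms[ord, ]
  form_len <- form_len[ord]

  hit_pos <- integer(0)
  hit_form <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (k in seq_along(form_tokens)) {
      len <- form_len[k]
      if (i + len - 1L > n) next
      if (all(toks[i:(i + len - 1L)] == form_tokens[[k]])) {
        hit_pos <- c(hit_pos, i)
        hit_form <- c(hit_form, k)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  tibble::tibble(
    position = hit_pos,
    unit_id = forms$unit_id[hit_form],
    surface_form = forms$surface_form[hit_form],
    relatedness = forms$relatedness[hit_form],
    location = forms$location[hit_form]
  )
}

#' Count content units in a transcript
#'
#' Counts lexicon-unit mentions passing a relatedness filter and a
#' side-of-picture filter. With `distinct = TRUE` repeated mentions of
#' the same unit count once. Matching is case-insensitive,
#' longest-match-first over multi-token spans, left-to-right,
#' non-overlapping.
#'
#' @param transcript A transcript tibble (`token`, `pos`, `sentence`).
#' @param lexicon A `pd_lexicon` (see [content_unit_lexicon()]).
#' @param relatedness `"related"` to keep scenario-related units only, or
#'   `"any"` for related and unrelated combined ("ALL" counts).
#' @param location `"left"`, `"right"`, `"both"` (non-localized units), or
#'   `"any"`.
#' @param distinct Count each unit at most once?
#' @return A nonnegative integer count.
#' @export
#' @examples
#' lex <- default_lexicon()
#' t <- tibble::tibble(
#'   token = c("the", "dog", "and", "the", "sink"),
#'   pos = c("DT", "NN", "CC", "DT", "NN"), sentence = 1L
#' )
#' count_content_units(t, lex) # 2 related mentions
count_content_units <- function(transcript, lexicon,
                                relatedness = c("any", "related"),
                                location = c("any", "left", "right", "both"),
                                distinct = FALSE) {
  relatedness <- match.arg(relatedness)
  location <- match.arg(location)
  hits <- match_content_units(transcript, lexicon)
  if (relatedness == "related") hits <- hits[hits$relatedness == "related", ]
  if (location != "any") hits <- hits[hits$location == location, ]
  if (distinct) length(unique(hits$unit_id)) else nrow(hits)
}

#' Closed-class word lists used by the lexical counters
#'
#' Defaults for the surface-form-based categories: indefinite articles,
#' function words (articles, common prepositions, conjunctions, pronouns,
#' auxiliaries), pro-sentences (single words standing for a whole
#' sentence) and fillers. All are configurable arguments of
#' [lexical_counts()].
#'
#' @return A named list of lowercase character vectors.
#' @export
default_word_lists <- function() {
  list(
    indefinite_articles = c("a", "an"),
    function_words = c(
      "a", "an", "the", "this", "that", "these", "those",
      "and", "or", "but", "nor", "so", "yet",
      "in", "on", "at", "by", "for", "with", "about", "against", "between",
      "into", "through", "during", "before", "after", "above", "below",
      "to", "from", "up", "down", "of", "off", "over", "under",
      "i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
      "us", "them", "my", "your", "his", "its", "our", "their",
      "is", "am", "are", "was", "were", "be", "been", "being",
      "do", "does", "did", "have", "has", "had",
      "will", "would", "can", "could", "shall", "should", "may", "might",
      "must", "not", "there"
    ),
    pro_sentences = c(
      "yes", "no", "okay", "ok", "yeah", "yep", "nope", "sure",
      "uh-huh", "mm-hmm", "alright"
    ),
    fillers = c("um", "uh", "er", "ah", "hmm", "mhm", "hm")
  )
}

#' Lexical-category counts
#'
#' Counts tokens per lexical category. Tag-based categories use the
#' Penn-Treebank tag: nouns `NN*`, prepositions `IN`, modals `MD`, and
#' so on. Surface-form categories (indefinite articles, function words,
#' pro-sentences, fillers) use configurable closed-class word lists.
#' Tokens with tags outside the known Penn set are ignored for tag-based
#' categories and reported via a message.
#'
#' @inheritParams count_content_units
#' @param word_lists Named list as from [default_word_lists()].
#' @return A named list of nonnegative integer counts.
#' @export
lexical_counts <- function(transcript, word_lists = default_word_lists()) {
  transcript <- as_transcript(transcript)
  pos <- transcript$pos
  unknown <- setdiff(unique(pos), KNOWN_TAGS)
  if (length(unknown) > 0) {
    message(
      "ignoring tokens with unknown POS tag(s) for tag-based categories: ",
      paste(unknown, collapse = ", ")
    )
    pos[pos %in% unknown] <- NA_character_
  }
  tok <- tolower(transcript$token)
  tag_count <- function(pattern) sum(grepl(pattern, pos) & !is.na(pos))
  list(
    nouns = tag_count("^NN"),
    prepositions = sum(pos == "IN", na.rm = TRUE),
    modals = sum(pos == "MD", na.rm = TRUE),
    indefinite_articles = sum(tok %in% word_lists$indefinite_articles),
    function_words = sum(tok %in% word_lists$function_words),
    pro_sentences = sum(tok %in% word_lists$pro_sentences),
    verbs = tag_count("^VB"),
    adjectives = tag_count("^JJ"),
    adverbs = tag_count("^RB"),
    personal_pronouns = sum(pos == "PRP", na.rm = TRUE),
    determiners = sum(pos == "DT", na.rm = TRUE),
    conjunctions = sum(pos == "CC", na.rm = TRUE),
    cardinal_numbers = sum(pos == "CD", na.rm = TRUE),
    interjections = sum(pos == "UH", na.rm = TRUE),
    particles = sum(pos == "RP", na.rm = TRUE),
    wh_words = tag_count("^W"),
    proper_nouns = sum(pos %in% c("NNP", "NNPS"), na.rm = TRUE),
    plural_nouns = sum(pos %in% c("NNS", "NNPS"), na.rm = TRUE),
    past_tense_verbs = sum(pos == "VBD", na.rm = TRUE),
    gerunds = sum(pos == "VBG", na.rm = TRUE),
    third_person_singular_verbs = sum(pos == "VBZ", na.rm = TRUE),
    base_form_verbs = sum(pos == "VB", na.rm = TRUE),
    comparative_adjectives = sum(pos == "JJR", na.rm = TRUE),
    superlative_adjectives = sum(pos == "JJS", na.rm = TRUE),
    fillers = sum(tok %in% word_lists$fillers)
  )
}

#' Heuristic syllable counter
#'
#' Counts vowel groups (`a e i o u y`) per word, with a correction for a
#' silent final "e" (dropped unless the word ends in a consonant + "le").
#' Every word counts at least one syllable. Pluggable: any function
#' mapping a character vector of words to integer counts can replace it
#' in [length_measures()].
#'
#' @param words Character vector of words.
#' @return Integer vector of syllable counts.
#' @export
#' @examples
#' count_syllables(c("cookie", "water", "stool", "overflowing"))
count_syllables <- function(words) {
  w <- tolower(words)
  groups <- stringr::str_count(w, "[aeiouy]+")
  silent_e <- grepl("[^aeiouy]e$", w) & !grepl("[^aeiouy]le$", w) & groups > 1
  out <- groups - as.integer(silent_e)
  as.integer(pmax(out, 1))
}

is_word_token <- function(transcript) {
  !(transcript$pos %in% PUNCT_TAGS) & grepl("[[:alnum:]]", transcript$token)
}

FINITE_VERB_TAGS <- c("VBD", "VBP", "VBZ", "MD")
NOMINAL_TAGS <- c("NN", "NNS", "NNP", "NNPS", "PRP")

# Lightweight chunker: counts maximal phrase-like runs of tokens.
# A noun-phrase chunk is a maximal run of determiner/possessive/adjective/
# number/noun tags; a verb group is a maximal run of modal/verb/adverb/
# particle tags; a preposition opens a new chunk. Punctuation breaks
# chunks. A heuristic stand-in for full parsing, and pluggable.
count_phrases <- function(pos) {
  np_tags <- c("DT", "PDT", "PRP$", "JJ", "JJR", "JJS", "CD", "NN", "NNS", "NNP", "NNPS", "PRP", "EX")
  vp_tags <- c("MD", "VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "RB", "RBR", "RBS", "RP", "TO")
  kind <- ifelse(pos %in% np_tags, "NP", ifelse(pos %in% vp_tags, "VP", ifelse(pos == "IN", "PP", "O")))
  n_chunks <- 0L
  prev <- "O"
  for (k in kind) {
    if (k %in% c("NP", "VP") && k != prev) n_chunks <- n_chunks + 1L
    if (k == "PP") n_chunks <- n_chunks + 1L # preposition opens a new chunk
    prev <- if (k == "PP") "PP" else k
  }
  n_chunks
}

#' Response-length measures
#'
#' Words (tokens excluding punctuation), sentences (distinct sentence
#' indices), syllables (pluggable counter), complete sentences (default
#' rule: a sentence with at least one finite-verb tag and one nominal
#' tag), phrases (lightweight chunking rule), and per-word syllable
#' summaries.
#'
#' @inheritParams count_content_units
#' @param syllable_counter Function words -> integer counts; defaults to
#'   [count_syllables()].
#' @return Named list: `words`, `syllables`, `sentences`,
#'   `complete_sentences`, `phrases`, `syllables_per_word_min`,
#'   `unique_words`, `type_token_ratio`, `mean_words_per_sentence`,
#'   `mean_syllables_per_word`, `max_words_per_sentence`,
#'   `mean_word_length`.
#' @export
length_measures <- function(transcript, syllable_counter = count_syllables) {
  transcript <- as_transcript(transcript)
  if (nrow(transcript) == 0) {
    return(list(
      words = 0L, syllables = 0L, sentences = 0L, complete_sentences = 0L,
      phrases = 0L, syllables_per_word_min = 0, unique_words = 0L,
      type_token_ratio = 0, mean_words_per_sentence = 0,
      mean_syllables_per_word = 0, max_words_per_sentence = 0,
      mean_word_length = 0
    ))
  }
  wordish <- is_word_token(transcript)
  words <- transcript$token[wordish]
  syl <- if (length(words) > 0) syllable_counter(words) else integer(0)
  sent_split <- split(transcript, transcript$sentence)
  complete <- vapply(sent_split, function(s) {
    any(s$pos %in% FINITE_VERB_TAGS) && any(s$pos %in% NOMINAL_TAGS)
  }, logical(1))
  words_per_sent <- vapply(sent_split, function(s) sum(is_word_token(s)), integer(1))
  phrases <- sum(vapply(sent_split, function(s) count_phrases(s$pos), integer(1)))
  list(
    words = length(words),
    syllables = as.integer(sum(syl)),
    sentences = length(sent_split),
    complete_sentences = as.integer(sum(complete)),
    phrases = as.integer(phrases),
    syllables_per_word_min = if (length(syl) > 0) min(syl) else 0,
    unique_words = length(unique(tolower(words))),
    type_token_ratio = if (length(words) > 0) length(unique(tolower(words))) / length(words) else 0,
    mean_words_per_sentence = mean(words_per_sent),
    mean_syllables_per_word = if (length(syl) > 0) mean(syl) else 0,
    max_words_per_sentence = if (length(words_per_sent) > 0) max(words_per_sent) else 0,
    mean_word_length = if (length(words) > 0) mean(nchar(words)) else 0
  )
}

# Recipes assembling every default-registry language feature from the
# three scoring primitives. Each recipe takes the precomputed pieces.
language_feature_recipes <- function() {
  cu <- function(rel, loc, dist) {
    force(rel); force(loc); force(dist)
    function(p) count_content_units(p$transcript, p$lexicon,
      relatedness = rel, location = loc, distinct = dist
    )
  }
  lx <- function(field) {
    force(field)
    function(p) p$lexical[[field]]
  }
  ln <- function(field) {
    force(field)
    function(p) p$length[[field]]
  }
  list(
    "Count of DISTINCT RELATED content units" = cu("related", "any", TRUE),
    "Count of RELATED content units" = cu("related", "any", FALSE),
    "Count of ALL content units" = cu("any", "any", FALSE),
    "Count of ALL DISTINCT content units" = cu("any", "any", TRUE),
    "Count of content units on RIGHT side of picture" = cu("any", "right", FALSE),
    "Count of DISTINCT content units on RIGHT side of picture" = cu("any", "right", TRUE),
    "Count of content units on LEFT side of picture" = cu("any", "left", FALSE),
    "Count of DISTINCT content units on LEFT side of picture" = cu("any", "left", TRUE),
    "Both Sides Total Content Units" = cu("any", "both", FALSE),
    "Both Sides Total Content Units DISTINCT" = cu("any", "both", TRUE),
    "Count of nouns" = lx("nouns"),
    "Count of prepositions" = lx("prepositions"),
    "Count of indefinite articles" = lx("indefinite_articles"),
    "Count of modals" = lx("modals"),
    "Count of all function words" = lx("function_words"),
    "Pro-sentences" = lx("pro_sentences"),
    "Count of verbs" = lx("verbs"),
    "Count of adjectives" = lx("adjectives"),
    "Count of adverbs" = lx("adverbs"),
    "Count of personal pronouns" = lx("personal_pronouns"),
    "Count of determiners" = lx("determiners"),
    "Count of conjunctions" = lx("conjunctions"),
    "Count of cardinal numbers" = lx("cardinal_numbers"),
    "Count of interjections" = lx("interjections"),
    "Count of particles" = lx("particles"),
    "Count of wh-words" = lx("wh_words"),
    "Count of proper nouns" = lx("proper_nouns"),
    "Count of plural nouns" = lx("plural_nouns"),
    "Count of past tense verbs" = lx("past_tense_verbs"),
    "Count of gerunds" = lx("gerunds"),
    "Count of third person singular verbs" = lx("third_person_singular_verbs"),
    "Count of base form verbs" = lx("base_form_verbs"),
    "Count of comparative adjectives" = lx("comparative_adjectives"),
    "Count of superlative adjectives" = lx("superlative_adjectives"),
    "Count of words" = ln("words"),
    "Count of Syllables" = ln("syllables"),
    "Count of sentences" = ln("sentences"),
    "Count of complete sentences" = ln("complete_sentences"),
    "Count of phrases" = ln("phrases"),
    "Syllables per word min" = ln("syllables_per_word_min"),
    "Count of unique words" = ln("unique_words"),
    "Type token ratio" = ln("type_token_ratio"),
    "Mean words per sentence" = ln("mean_words_per_sentence"),
    "Mean syllables per word" = ln("mean_syllables_per_word"),
    "Max words per sentence" = ln("max_words_per_sentence"),
    "Mean word length" = ln("mean_word_length"),
    "Count of filler words" = lx("fillers")
  )
}

#' Extract language features from transcripts
#'
#' Assembles every language feature named in the registry from the
#' content-unit, lexical and length scoring primitives. Accepts either a
#' single transcript or a multi-participant token table with a
#' `participant_id` column, returning one row per participant.
#'
#' @param transcripts Tibble of tokens (`token`, `pos`, `sentence`,
#'   optionally `participant_id`).
#' @param lexicon A `pd_lexicon`.
#' @param registry A feature registry; only its language rows are scored.
#' @inheritParams length_measures
#' @param word_lists Closed-class word lists for [lexical_counts()].
#' @return A tibble: `participant_id` plus one column per registry
#'   language feature.
#' @export
extract_language_features <- function(transcripts, lexicon = default_lexicon(),
                                      registry = feature_registry(),
                                      syllable_counter = count_syllables,
                                      word_lists = default_word_lists()) {
  validate_registry(registry)
  wanted <- registry_features(registry, "language")
  recipes <- language_feature_recipes()
  unknown <- setdiff(wanted, names(recipes))
  if (length(unknown) > 0) {
    stop(
      "no recipe defined for language feature(s): ",
      paste(unknown, collapse = "; ")
    )
  }
  if (!("participant_id" %in% names(transcripts))) {
    transcripts <- tibble::add_column(
      tibble::as_tibble(transcripts),
      participant_id = "transcript", .before = 1
    )
  }
  ids <- unique(transcripts$participant_id)
  rows <- purrr::map(ids, function(id) {
    t <- as_transcript(transcripts[transcripts$participant_id == id, c("token", "pos", "sentence")])
    parts <- list(
      transcript = t,
      lexicon = lexicon,
      lexical = lexical_counts(t, word_lists = word_lists),
      length = length_measures(t, syllable_counter = syllable_counter)
    )
    vals <- purrr::map_dbl(recipes[wanted], function(f) as.numeric(f(parts)))
    tibble::as_tibble_row(c(list(participant_id = id), as.list(vals)))
  })
  dplyr::bind_rows(rows)
}
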