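lex <- default_lexicon()

mk <- function(text) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  tokens_as_transcript(toks)
}

test_that("content-unit counting honours relatedness, location and distinct filters", {
  t <- mk("the dog and the dog and the sink")
  expect_equal(count_content_units(t, lex), 3) # ALL
  expect_equal(count_content_units(t, lex, distinct = TRUE), 2) # ALL DISTINCT
  expect_equal(count_content_units(t, lex, location = "left"), 2)
  expect_equal(count_content_units(t, lex, location = "left", distinct = TRUE), 1)
  expect_equal(count_content_units(t, lex, location = "right"), 1)
  expect_equal(count_content_units(t, lex, relatedness = "related"), 3)
  # side semantics: dog on the left, sink on the right, kitchen both sides
  expect_equal(count_content_units(mk("kitchen"), lex, location = "both"), 1)
  expect_equal(count_content_units(mk("kitchen"), lex, location = "left"), 0)
})

test_that("matching is case-insensitive and longest-match-first", {
  expect_equal(
    count_content_units(mk("The DOG and the Sink"), lex),
    count_content_units(mk("the dog and the sink"), lex)
  )
  # "cookie jar" must match the jar unit once, not cookie + jar
  t <- mk("the cookie jar fell")
  expect_equal(count_content_units(t, lex), 1)
  m <- pdscreen:::match_content_units(t, lex)
  expect_equal(m$unit_id, "cookie_jar")
  # but a lone "cookie" still matches the cookie unit
  expect_equal(
    pdscreen:::match_content_units(mk("a cookie fell"), lex)$unit_id,
    "cookie"
  )
})

test_that("scanner agrees with the brute-force token-window oracle", {
  withr::with_seed(14, {
    mismatches <- 0
    for (i in 1:200) {
      toks <- random_transcript_tokens(lex, n_tokens = sample(5:40, 1))
      got <- pdscreen:::match_content_units(tokens_as_transcript(toks), lex)
      want <- brute_force_mentions(toks, lex)
      same <- identical(got$position, want$start) &&
        identical(got$unit_id, want$unit_id) &&
        identical(got$relatedness, want$relatedness) &&
        identical(got$location, want$location)
      if (!same) mismatches <- mismatches + 1
    }
    expect_equal(mismatches, 0)
    # spot-check the derived counts on a handful of streams
    for (i in 1:10) {
      toks <- random_transcript_tokens(lex, n_tokens = 30)
      t <- tokens_as_transcript(toks)
      for (rel in c("any", "related")) {
        for (loc in c("any", "left", "right", "both")) {
          expect_equal(
            count_content_units(t, lex, relatedness = rel, location = loc),
            brute_force_count(toks, lex, relatedness = rel, location = loc)
          )
          expect_equal(
            count_content_units(t, lex, relatedness = rel, location = loc, distinct = TRUE),
            brute_force_count(toks, lex, relatedness = rel, location = loc, distinct = TRUE)
          )
        }
      }
    }
  })
})

test_that("adding a mention never decreases counts; distinct grows only for unseen units", {
  withr::with_seed(3, {
    for (i in 1:25) {
      toks <- random_transcript_tokens(lex, n_tokens = 15)
      unit <- lex[sample(nrow(lex), 1), ]
      aug <- c(toks, strsplit(unit$surface_form, " ")[[1]])
      before_all <- count_content_units(tokens_as_transcript(toks), lex)
      after_all <- count_content_units(tokens_as_transcript(aug), lex)
      expect_gte(after_all, before_all)
      seen_before <- unit$unit_id %in%
        pdscreen:::match_content_units(tokens_as_transcript(toks), lex)$unit_id
      before_d <- count_content_units(tokens_as_transcript(toks), lex, distinct = TRUE)
      after_d <- count_content_units(tokens_as_transcript(aug), lex, distinct = TRUE)
      if (!seen_before) expect_gt(after_d, before_d) else expect_gte(after_d, before_d)
    }
  })
})

test_that("related and unrelated mentions partition the ALL count per location", {
  withr::with_seed(8, {
    for (i in 1:30) {
      t <- tokens_as_transcript(random_transcript_tokens(lex, 25))
      for (loc in c("any", "left", "right", "both")) {
        all_n <- count_content_units(t, lex, "any", loc)
        rel_n <- count_content_units(t, lex, "related", loc)
        m <- pdscreen:::match_content_units(t, lex)
        if (loc != "any") m <- m[m$location == loc, ]
        unrel_n <- sum(m$relatedness == "unrelated")
        expect_equal(rel_n + unrel_n, all_n)
        expect_lte(
          count_content_units(t, lex, "any", loc, distinct = TRUE), all_n
        )
      }
    }
  })
})

test_that("lexical counts follow tags and closed-class lists", {
  t <- tibble::tibble(
    token = c("the", "boy", "could", "reach", "a", "cookie"),
    pos = c("DT", "NN", "MD", "VB", "DT", "NN"),
    sentence = 1L
  )
  lc <- lexical_counts(t)
  expect_equal(lc$modals, 1)
  expect_equal(lc$indefinite_articles, 1)
  expect_equal(lc$nouns, 2)
  expect_equal(lc$base_form_verbs, 1)
  empty <- lexical_counts(tibble::tibble(
    token = character(), pos = character(), sentence = integer()
  ))
  expect_true(all(unlist(empty) == 0))
})

test_that("unknown POS tags are skipped for tag-based categories with a message", {
  t <- tibble::tibble(
    token = c("boy", "blip"), pos = c("NN", "ZZ"), sentence = 1L
  )
  expect_message(lc <- lexical_counts(t), "unknown POS")
  expect_equal(lc$nouns, 1)
})

test_that("length measures count words, sentences and syllables as defined", {
  t <- tibble::tibble(
    token = c("the", "dog", "barks", ".", "the", "boy", "runs", "."),
    pos = c("DT", "NN", "VBZ", ".", "DT", "NN", "VBZ", "."),
    sentence = rep(c(1L, 2L), each = 4)
  )
  lm <- length_measures(t)
  expect_equal(lm$words, 6)
  expect_equal(lm$sentences, 2)
  expect_equal(lm$complete_sentences, 2)
  expect_equal(lm$syllables_per_word_min, 1)
  zeros <- length_measures(tibble::tibble(
    token = character(), pos = character(), sentence = integer()
  ))
  expect_true(all(unlist(zeros) == 0))
})

test_that("syllable heuristic matches hand counts on at least 90% of a fixture list", {
  fixture <- c(
    the = 1, dog = 1, cookie = 2, water = 2, window = 2, curtains = 2,
    kitchen = 2, overflowing = 4, family = 3, reaching = 2, stool = 1,
    mother = 2, washing = 2, sink = 1, falling = 2, cabinet = 3,
    counter = 2, basin = 2, dishes = 2, garden = 2
  )
  got <- count_syllables(names(fixture))
  expect_gte(mean(got == unname(fixture)), 0.9)
})

test_that("language feature extraction closes the loop with the generator", {
  sim <- simulate_transcripts(
    transcript_config(n_transcripts = 8, rate_related = 4, rate_unrelated = 2, seed = 6)
  )
  feats <- extract_language_features(sim$tokens)
  gt <- sim$ground_truth
  expect_equal(feats$participant_id, gt$participant_id)
  expect_equal(feats[["Count of RELATED content units"]], as.numeric(gt$related))
  expect_equal(feats[["Count of ALL content units"]], as.numeric(gt$all))
  expect_equal(feats[["Count of DISTINCT RELATED content units"]], as.numeric(gt$distinct_related))
  expect_equal(feats[["Count of ALL DISTINCT content units"]], as.numeric(gt$all_distinct))
  expect_equal(feats[["Count of content units on LEFT side of picture"]], as.numeric(gt$left))
  expect_equal(feats[["Count of content units on RIGHT side of picture"]], as.numeric(gt$right))
  expect_equal(feats[["Both Sides Total Content Units"]], as.numeric(gt$both))
  expect_equal(feats[["Both Sides Total Content Units DISTINCT"]], as.numeric(gt$both_distinct))
  # every default-registry language feature is emitted
  expect_equal(
    sort(setdiff(names(feats), "participant_id")),
    sort(feature_registry()$name[feature_registry()$modality == "language"])
  )
})

test_that("order-insensitive counts survive sentence permutation", {
  sim <- simulate_transcripts(
    transcript_config(n_transcripts = 1, rate_related = 6, rate_unrelated = 2, seed = 12)
  )
  toks <- sim$tokens
  perm <- withr::with_seed(4, sample(unique(toks$sentence)))
  toks2 <- toks[order(match(toks$sentence, perm)), ]
  toks2$sentence <- rep(seq_along(perm), times = table(toks$sentence)[perm])
  f1 <- extract_language_features(toks)
  f2 <- extract_language_features(toks2)
  stable <- c(
    "Count of RELATED content units", "Count of ALL content units",
    "Count of nouns", "Count of words", "Count of Syllables",
    "Count of sentences"
  )
  for (s in stable) expect_equal(f1[[s]], f2[[s]], info = s)
})

test_that("unextractable registry features raise a named error", {
  reg <- feature_registry()
  reg$name[reg$name == "Count of nouns"] <- "Count of martians"
  t <- tokens_as_transcript(c("the", "dog"))
  expect_error(
    extract_language_features(t, registry = reg),
    "Count of martians"
  )
})

test_that("transcript TSV files round-trip through the readers", {
  dir <- withr::local_tempdir()
  t <- tibble::tibble(
    token = c("the", "dog", "."), pos = c("DT", "NN", "."), sentence = 1L
  )
  readr::write_tsv(t, file.path(dir, "P001.tsv"))
  readr::write_tsv(t, file.path(dir, "P002.tsv"))
  got <- read_transcripts(dir)
  expect_equal(unique(got$participant_id), c("P001", "P002"))
  expect_equal(got$token[1:3], t$token)
})
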