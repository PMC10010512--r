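test_that("default synthetic cohort matches the study design", {
  cohort <- simulate_cohort(cohort_config(seed = 11))
  expect_equal(nrow(cohort$features), 95)
  expect_equal(ncol(cohort$features) - 1, 91)
  expect_equal(
    as.vector(table(cohort$participants$diagnosis)[c("HC", "aMCI", "naMCI")]),
    c(62, 18, 15)
  )
  expect_true(all(cohort$participants$age >= 64 & cohort$participants$age <= 85))
  expect_true(all(cohort$participants$gender %in% c("female", "male")))
  expect_false(is.null(cohort$log$config_hash))
})

test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a$features, NULL), serialize(b$features, NULL))
  expect_identical(serialize(a$participants, NULL), serialize(b$participants, NULL))
  c2 <- simulate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$features, c2$features))
})

test_that("null cohort has no systematic group shifts", {
  cfg <- cohort_config(
    n_per_group = c(HC = 200, aMCI = 200, naMCI = 0),
    effect_map = default_effect_map()[0, ], missing_rate = 0, seed = 7
  )
  cohort <- simulate_cohort(cfg)
  feats <- setdiff(names(cohort$features), "participant_id")
  for (f in sample(feats, 20)) {
    x <- cohort$features[[f]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x)), 4 * se + 4 / sqrt(length(x)))
  }
})

test_that("an injected shift is recovered within a quarter SD at n = 500 per group", {
  cfg <- cohort_config(
    n_per_group = c(HC = 500, aMCI = 500, naMCI = 0),
    effect_map = tibble::tibble(
      feature = "Count of nouns", group = "aMCI", shift = -1.0
    ),
    missing_rate = 0, seed = 21
  )
  cohort <- simulate_cohort(cfg)
  x <- cohort$features[["Count of nouns"]]
  g <- cohort$participants$diagnosis
  d_hat <- (mean(x[g == "aMCI"]) - mean(x[g == "HC"])) /
    sqrt((stats::var(x[g == "aMCI"]) + stats::var(x[g == "HC"])) / 2)
  expect_lt(abs(d_hat - (-1.0)), 0.25)
  # untouched features stay null
  x0 <- cohort$features[["Count of modals"]]
  expect_lt(abs(mean(x0[g == "aMCI"]) - mean(x0[g == "HC"])), 0.2)
})

test_that("missingness is confined to tremor features at the configured rate", {
  cfg <- cohort_config(
    n_per_group = c(HC = 400, aMCI = 100, naMCI = 100),
    missing_rate = 0.1, seed = 5
  )
  cohort <- simulate_cohort(cfg)
  reg <- feature_registry()
  for (f in setdiff(reg$name, tremor_features())) {
    expect_false(anyNA(cohort$features[[f]]))
  }
  n <- nrow(cohort$features)
  for (f in tremor_features()) {
    rate <- mean(is.na(cohort$features[[f]]))
    expect_lt(abs(rate - 0.1), 2 * sqrt(0.1 * 0.9 / n) + 1e-9)
  }
})

test_that("count link produces nonnegative integers on count features", {
  cfg <- cohort_config(
    n_per_group = c(HC = 50, aMCI = 10, naMCI = 5),
    count_link = "count", missing_rate = 0, seed = 2
  )
  cohort <- simulate_cohort(cfg)
  x <- cohort$features[["Count of words"]]
  expect_true(all(x >= 0))
  expect_equal(x, round(x))
})

test_that("config validation catches bad inputs", {
  expect_error(cohort_config(n_per_group = c(HC = -1, aMCI = 1, naMCI = 1)), "nonnegative")
  expect_error(cohort_config(missing_rate = 1.5), "missing_rate")
  expect_error(
    cohort_config(effect_map = tibble::tibble(
      feature = "Count of nouns", group = "aMCI", shift = Inf
    )),
    "finite"
  )
  expect_warning(
    cohort_config(
      n_per_group = c(HC = 10, aMCI = 0, naMCI = 0),
      effect_map = tibble::tibble(feature = "Count of nouns", group = "aMCI", shift = -1)
    ),
    "empty group"
  )
})

test_that("written cohort files round-trip with empty cells as missing", {
  cohort <- simulate_cohort(cohort_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  feats <- readr::read_csv(file.path(dir, "features.csv"), show_col_types = FALSE)
  expect_equal(dim(feats), dim(cohort$features))
  expect_equal(
    which(is.na(feats$ATrP)),
    which(is.na(cohort$features$ATrP))
  )
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, 9)
})

test_that("transcript generator emits ground truth matching its own mentions", {
  sim <- simulate_transcripts(
    transcript_config(n_transcripts = 6, rate_related = 4, rate_unrelated = 1, seed = 3)
  )
  expect_equal(nrow(sim$ground_truth), 6)
  expect_true(all(sim$ground_truth$related <= sim$ground_truth$all))
  expect_true(all(sim$ground_truth$distinct_related <= sim$ground_truth$related))
  expect_equal(
    sim$ground_truth$all,
    sim$ground_truth$left + sim$ground_truth$right + sim$ground_truth$both
  )
})

test_that("zero mention rates give transcripts with zero content-unit counts", {
  sim <- simulate_transcripts(
    transcript_config(n_transcripts = 4, rate_related = 0, rate_unrelated = 0, seed = 1)
  )
  expect_true(all(sim$ground_truth$all == 0))
  lex <- default_lexicon()
  for (id in unique(sim$tokens$participant_id)) {
    t <- sim$tokens[sim$tokens$participant_id == id, ]
    expect_equal(count_content_units(t, lex), 0)
  }
})

test_that("mean related mentions tracks the configured Poisson rate", {
  sim <- simulate_transcripts(
    transcript_config(n_transcripts = 200, rate_related = 5, rate_unrelated = 0, seed = 8)
  )
  expect_lt(abs(mean(sim$ground_truth$related) - 5), 0.5)
})

test_that("lexicons with ambiguous surface forms are rejected", {
  bad <- tibble::tibble(
    unit_id = c("dog", "hound"),
    surface_form = c("dog", "dog"),
    relatedness = "related",
    location = "left"
  )
  expect_error(content_unit_lexicon(bad), "more than one unit_id")
})
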