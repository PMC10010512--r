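make_test_cohort <- function(seed = 1, effect_map = default_effect_map(),
                             n = c(HC = 62, aMCI = 18, naMCI = 15)) {
  cohort <- simulate_cohort(cohort_config(
    n_per_group = n, effect_map = effect_map, seed = seed
  ))
  cohort$normalized <- quantile_normalize(cohort$features)
  cohort
}

test_that("risk model keeps unpenalized covariates and registry-only weights", {
  cohort <- make_test_cohort(seed = 41)
  m <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 1, alpha_grid = c(0.5), repeats = 3
  )
  reg <- feature_registry()
  expect_setequal(names(m$weights), reg$name)
  expect_equal(names(m$covariate_weights), c("age", "gender"))
  expect_equal(nrow(m$scores), 62 + 18)
  expect_equal(anyDuplicated(m$scores$participant_id), 0)
  td <- tidy(m)
  expect_true(all(!td$penalized[td$term %in% c("(Intercept)", "age", "gender")]))
  gl <- glance(m)
  expect_equal(gl$task, "aMCI-vs-HC")
  expect_equal(gl$n, 80)
})

test_that("risk fitting is bitwise reproducible from its seed", {
  cohort <- make_test_cohort(seed = 43)
  a <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 7, alpha_grid = c(0.2, 1), repeats = 2
  )
  b <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 7, alpha_grid = c(0.2, 1), repeats = 2
  )
  expect_identical(a$scores$score, b$scores$score)
  expect_identical(a$weights, b$weights)
  c2 <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 8, alpha_grid = c(0.2, 1), repeats = 2
  )
  expect_false(identical(a$scores$score, c2$scores$score))
})

test_that("every out-of-sample score comes from folds excluding the participant", {
  cohort <- make_test_cohort(seed = 47)
  m <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 3, alpha_grid = c(0.5), repeats = 4
  )
  fa <- m$fold_assignments
  expect_equal(dim(fa), c(80, 4))
  # each repeat partitions all participants across the 5 folds
  for (r in seq_len(ncol(fa))) {
    expect_true(all(fa[, r] %in% 1:5))
    expect_equal(length(unique(fa[, r])), 5)
  }
})

test_that("a planted five-feature signal is recovered with strong held-out AUROC", {
  planted <- tibble::tibble(
    feature = c(
      "Count of RELATED content units", "Count of nouns", "Count of words",
      "Acoustics standard deviation of F0", "Acoustics mean HNR"
    ),
    group = "aMCI",
    shift = c(-1, -1, -1, 1, -1)
  )
  cohort <- make_test_cohort(
    seed = 3, effect_map = planted,
    n = c(HC = 60, aMCI = 20, naMCI = 0)
  )
  m <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 3
  )
  support <- names(m$weights)[m$weights != 0]
  expect_gte(sum(planted$feature %in% support), 4)
  expect_gte(m$auroc, 0.8)
})

test_that("a null cohort yields chance-level cross-validated AUROC", {
  cohort <- make_test_cohort(
    seed = 51, effect_map = default_effect_map()[0, ],
    n = c(HC = 60, aMCI = 20, naMCI = 0)
  )
  m <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 5, alpha_grid = c(0.5), repeats = 5
  )
  expect_gt(m$auroc, 0.3)
  expect_lt(m$auroc, 0.7)
})

test_that("tasks with an empty class are rejected", {
  cohort <- make_test_cohort(seed = 53, n = c(HC = 30, aMCI = 10, naMCI = 0))
  expect_error(
    fit_risk_score(cohort$normalized, cohort$participants, task = "naMCI-vs-HC"),
    "empty class"
  )
})

test_that("multinomial liabilities difference exactly and additively", {
  cohort <- make_test_cohort(seed = 57)
  m <- fit_multinomial_risk(cohort$normalized, cohort$participants,
    seed = 2, alpha_grid = c(0.5), repeats = 2
  )
  L <- m$liabilities
  expect_equal(L$`aMCI-HC`, L$aMCI - L$HC)
  expect_equal(L$`aMCI-HC` + L$HC - L$naMCI, L$`aMCI-naMCI`, tolerance = 1e-12)
  expect_equal(nrow(L), 95)
  expect_equal(m$aurocs$task, c("aMCI-vs-HC", "naMCI-vs-HC", "aMCI-vs-naMCI"))
  expect_true(all(m$aurocs$auroc >= 0 & m$aurocs$auroc <= 1))
  gl <- glance(m)
  expect_true("auroc_aMCI_vs_HC" %in% names(gl))
})

test_that("multinomial separation mirrors the aMCI-specific design", {
  cohort <- make_test_cohort(seed = 61)
  m <- fit_multinomial_risk(cohort$normalized, cohort$participants,
    seed = 4, alpha_grid = c(0.2, 1), repeats = 3
  )
  a <- m$aurocs$auroc[m$aurocs$task == "aMCI-vs-HC"]
  b <- m$aurocs$auroc[m$aurocs$task == "naMCI-vs-HC"]
  expect_gt(a, b)
})

test_that("groups below three members are rejected for the multinomial path", {
  cohort <- make_test_cohort(seed = 63, n = c(HC = 30, aMCI = 10, naMCI = 2))
  expect_error(
    fit_multinomial_risk(cohort$normalized, cohort$participants),
    "at least 3"
  )
})

test_that("report tables collect screens, risk AUROCs and violin data", {
  cohort <- make_test_cohort(seed = 67, n = c(HC = 30, aMCI = 10, naMCI = 0))
  sc <- screen_features(cohort$normalized, cohort$participants,
    case = "aMCI", compute_auroc = FALSE
  )
  m <- fit_risk_score(cohort$normalized, cohort$participants,
    task = "aMCI-vs-HC", seed = 1, alpha_grid = c(0.5), repeats = 2
  )
  tb <- report_tables(
    screens = list("features: aMCI vs HC" = sc),
    risk_models = list("aMCI-vs-HC" = m),
    features = cohort$normalized, participants = cohort$participants
  )
  expect_equal(nrow(tb$risk_aurocs), 1)
  expect_equal(tb$risk_aurocs$auroc, m$auroc)
  expect_equal(nrow(tb$violin_data), 40 * 91)
  # empty screen input: headers only
  empty <- report_tables()
  expect_equal(nrow(empty$risk_aurocs), 0)
})
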