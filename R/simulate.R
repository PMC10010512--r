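#' Synthetic cohort configuration
#'
#' Defines the statistical conditions the generator emulates: a
#' three-cohort study (healthy controls, amnestic MCI, non-amnestic MCI)
#' with group-specific standardized shifts on selected features,
#' missingness confined to the six vocal-tremor features, and
#' demographic moments per cohort. Defaults reproduce the study design
#' the pipeline targets: 62 HC / 18 aMCI / 15 naMCI, aMCI-specific
#' deficits on verbosity-linked count features with elevated F0
#' variability, and near-null naMCI effects.
#'
#' @param n_per_group Named counts for `HC`, `aMCI`, `naMCI`.
#' @param effect_map Tibble (`feature`, `group`, `shift`) of standardized
#'   mean shifts (SD units on the latent scale) applied to a feature in a
#'   group. Defaults to [default_effect_map()].
#' @param missing_rate Missing-completely-at-random rate applied to the
#'   six tremor features, in `[0, 1]`.
#' @param age_gender Tibble (`group`, `age_mean`, `age_sd`,
#'   `female_fraction`) of demographic moments; defaults to the target
#'   study design via [default_age_gender_model()].
#' @param age_range Ages are drawn from a normal truncated to this range
#'   (study inclusion required age at least 64).
#' @param verbosity_loading Loading of count-type language features on a
#'   shared latent "verbosity" factor, inducing the positive correlation
#'   among count features that real picture-description data show
#'   (longer responses raise every count).
#' @param count_link `"identity"` exposes the latent Gaussian directly
#'   (default; quantile normalization downstream makes the native scale
#'   immaterial); `"count"` maps count-type features through a monotone
#'   exponential link and rounds to nonnegative integers.
#' @param seed Integer seed; identical config and seed give identical
#'   output.
#' @return A list of class `pd_cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 62, aMCI = 18, naMCI = 15),
                          effect_map = default_effect_map(),
                          missing_rate = 0.1,
                          age_gender = default_age_gender_model(),
                          age_range = c(64, 85),
                          verbosity_loading = 0.6,
                          count_link = c("identity", "count"),
                          seed = 1L) {
  count_link <- match.arg(count_link)
  if (!all(c("HC", "aMCI", "naMCI") %in% names(n_per_group))) {
    stop("n_per_group must name HC, aMCI and naMCI")
  }
  if (any(n_per_group < 0)) stop("group counts must be nonnegative")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  effect_map <- tibble::as_tibble(effect_map)
  if (nrow(effect_map) > 0) {
    stopifnot(all(c("feature", "group", "shift") %in% names(effect_map)))
    if (!all(is.finite(effect_map$shift))) stop("effect shifts must be finite")
    empty_groups <- names(n_per_group)[n_per_group == 0]
    hit <- intersect(unique(effect_map$group), empty_groups)
    if (length(hit) > 0) {
      warning("effects requested for empty group(s): ", paste(hit, collapse = ", "))
    }
  }
  structure(
    list(
      n_per_group = n_per_group, effect_map = effect_map,
      missing_rate = missing_rate, age_gender = tibble::as_tibble(age_gender),
      age_range = age_range, verbosity_loading = verbosity_loading,
      count_link = count_link, seed = as.integer(seed)
    ),
    class = "pd_cohort_config"
  )
}

#' Default standardized effect map
#'
#' The aMCI cohort gets negative shifts (0.6 to 1.1 SD) on the
#' count-type language features that the screening analysis targets,
#' and a positive shift (+0.8 SD) on the standard deviation of F0
#' (raised pitch variability); naMCI carries no effects. Magnitudes are
#' back-solved from the per-feature discriminations this design should
#' produce (cross-validated AUROCs in roughly the 0.65-0.85 range via
#' AUROC = Phi(d / sqrt(2))); directions follow the screening
#' literature's consistent finding that verbosity-linked counts are
#' lower in amnestic MCI.
#'
#' @return Tibble with columns `feature`, `group`, `shift`.
#' @export
default_effect_map <- function() {
  tibble::tibble(
    feature = c(
      "Count of DISTINCT RELATED content units",
      "Count of RELATED content units",
      "Count of indefinite articles",
      "Count of prepositions",
      "Count of nouns",
      "Both Sides Total Content Units DISTINCT",
      "Both Sides Total Content Units",
      "Count of ALL content units",
      "Count of content units on RIGHT side of picture",
      "Count of Syllables",
      "Count of words",
      "Count of ALL DISTINCT content units",
      "Count of DISTINCT content units on RIGHT side of picture",
      "Count of sentences",
      "Count of phrases",
      "Acoustics standard deviation of F0",
      "Count of complete sentences",
      "Count of content units on LEFT side of picture",
      "Count of all function words",
      "Count of DISTINCT content units on LEFT side of picture"
    ),
    group = "aMCI",
    shift = c(
      -1.1, -1.1, -1.0, -1.0, -1.0, -1.0, -0.95, -0.9, -0.9, -0.85,
      -0.8, -0.8, -0.75, -0.7, -0.7, 0.8, -0.65, -0.65, -0.6, -0.6
    )
  )
}

#' Default demographic model
#'
#' Per-cohort age means/SDs and female fractions matching the target
#' study design (ages about 70, slight male excess in the MCI groups).
#'
#' @return Tibble (`group`, `age_mean`, `age_sd`, `female_fraction`).
#' @export
default_age_gender_model <- function() {
  tibble::tibble(
    group = c("HC", "aMCI", "naMCI"),
    age_mean = c(70.3, 70.2, 71.5),
    age_sd = c(4.5, 7.4, 5.8),
    female_fraction = c(35 / 62, 6 / 18, 6 / 15)
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws participants (id, diagnosis, age, gender) and a feature table
#' with the structure the downstream analysis assumes: latent
#' standard-normal feature values per group, plus the standardized
#' shifts in `config$effect_map`; count-type language features share a
#' latent verbosity factor; missing entries occur only in features the
#' registry flags `may_be_missing` (the six tremor measures), at the
#' configured MCAR rate. Gender is coded `female`/`male` in the
#' participants table and as female = 0, male = 1 wherever a numeric
#' covariate is needed.
#'
#' @param config A [cohort_config()].
#' @param registry A feature registry (default [feature_registry()]);
#'   must define at least one feature per modality present.
#' @return A list of class `pd_cohort`: `participants` (tibble),
#'   `features` (tibble, `participant_id` + one column per registry
#'   feature), `config`, and `log` (seed and config hash).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' dim(cohort$features)
simulate_cohort <- function(config = cohort_config(), registry = feature_registry()) {
  stopifnot(inherits(config, "pd_cohort_config"))
  validate_registry(registry)
  with_rng_seed(config$seed, {
    groups <- c("HC", "aMCI", "naMCI")
    n <- config$n_per_group[groups]
    total <- sum(n)
    diagnosis <- rep(groups, times = n)
    ids <- sprintf("P%03d", seq_len(total))
    ag <- config$age_gender
    age <- numeric(total)
    gender <- character(total)
    for (g in groups) {
      idx <- which(diagnosis == g)
      if (length(idx) == 0) next
      row <- ag[ag$group == g, ]
      if (nrow(row) == 0) stop("age_gender model lacks group ", g)
      age[idx] <- rtruncnorm1(
        length(idx), row$age_mean, row$age_sd,
        config$age_range[1], config$age_range[2]
      )
      gender[idx] <- ifelse(
        stats::runif(length(idx)) < row$female_fraction, "female", "male"
      )
    }
    participants <- tibble::tibble(
      participant_id = ids, diagnosis = diagnosis,
      age = age, gender = gender
    )

    z_verb <- stats::rnorm(total)
    lam <- config$verbosity_loading
    is_count <- if ("is_count" %in% names(registry)) registry$is_count else rep(FALSE, nrow(registry))
    vals <- matrix(NA_real_, nrow = total, ncol = nrow(registry))
    colnames(vals) <- registry$name
    for (j in seq_len(nrow(registry))) {
      eps <- stats::rnorm(total)
      latent <- if (is_count[j] && registry$modality[j] == "language") {
        lam * z_verb + sqrt(1 - lam^2) * eps
      } else {
        eps
      }
      em <- config$effect_map
      if (nrow(em) > 0) {
        em_j <- em[em$feature == registry$name[j], ]
        for (k in seq_len(nrow(em_j))) {
          latent[diagnosis == em_j$group[k]] <- latent[diagnosis == em_j$group[k]] + em_j$shift[k]
        }
      }
      if (config$count_link == "count" && is_count[j]) {
        latent <- pmax(round(exp(2.5 + 0.6 * latent)), 0)
      }
      vals[, j] <- latent
    }
    for (j in which(registry$may_be_missing)) {
      miss <- stats::runif(total) < config$missing_rate
      vals[miss, j] <- NA_real_
    }
    features <- dplyr::bind_cols(
      tibble::tibble(participant_id = ids),
      tibble::as_tibble(vals)
    )
    structure(
      list(
        participants = participants, features = features, config = config,
        log = list(seed = config$seed, config_hash = rlang::hash(unclass(config)))
      ),
      class = "pd_cohort"
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `participants.csv`, `features.csv` (empty cell = missing) and
#' `ground_truth.json` (effect map and seed) into `dir`.
#'
#' @param cohort A `pd_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    features = file.path(dir, "features.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(cohort$participants, paths["participants"], na = "")
  readr::write_csv(cohort$features, paths["features"], na = "")
  jsonlite::write_json(
    list(
      seed = cohort$config$seed,
      config_hash = cohort$log$config_hash,
      effect_map = cohort$config$effect_map,
      missing_rate = cohort$config$missing_rate
    ),
    paths["ground_truth"],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Transcript generator configuration
#'
#' @param n_transcripts Number of transcripts to draw.
#' @param rate_related,rate_unrelated Poisson means for the number of
#'   related / unrelated content-unit mentions per transcript.
#' @param n_filler_sentences Non-lexicon filler sentences appended to
#'   each transcript.
#' @param seed Integer seed.
#' @return A list of class `pd_transcript_config`.
#' @export
transcript_config <- function(n_transcripts = 10, rate_related = 5,
                              rate_unrelated = 1, n_filler_sentences = 1,
                              seed = 1L) {
  stopifnot(n_transcripts >= 0, rate_related >= 0, rate_unrelated >= 0)
  structure(
    list(
      n_transcripts = n_transcripts, rate_related = rate_related,
      rate_unrelated = rate_unrelated,
      n_filler_sentences = n_filler_sentences, seed = as.integer(seed)
    ),
    class = "pd_transcript_config"
  )
}

#' Generate toy POS-tagged transcripts with known content-unit counts
#'
#' Emits simple template sentences ("the <unit> is there .") around
#' content-unit mentions sampled from the lexicon at the configured
#' Poisson rates, plus filler sentences containing no lexicon words.
#' The true mention counts are tracked at emission time and returned as
#' ground truth, so the transcript scorer can be tested in a closed
#' loop. The templates are deliberately minimal: they exercise the
#' scoring logic, not realistic discourse.
#'
#' @param config A [transcript_config()].
#' @param lexicon A `pd_lexicon`; must be non-empty.
#' @return A list: `tokens` (tibble `participant_id`, `token`, `pos`,
#'   `sentence`) and `ground_truth` (tibble of per-transcript true
#'   counts: `related`, `all`, `distinct_related`, `all_distinct`,
#'   `left`, `left_distinct`, `right`, `right_distinct`, `both`,
#'   `both_distinct`).
#' @export
simulate_transcripts <- function(config = transcript_config(),
                                 lexicon = default_lexicon()) {
  stopifnot(inherits(config, "pd_transcript_config"))
  if (!inherits(lexicon, "pd_lexicon")) lexicon <- content_unit_lexicon(lexicon)
  if (nrow(lexicon) == 0) stop("lexicon must be non-empty")
  units <- dplyr::distinct(lexicon, .data$unit_id, .data$relatedness, .data$location)
  with_rng_seed(config$seed, {
    all_tokens <- list()
    gt <- list()
    for (i in seq_len(config$n_transcripts)) {
      id <- sprintf("T%03d", i)
      n_rel <- stats::rpois(1, config$rate_related)
      n_unrel <- stats::rpois(1, config$rate_unrelated)
      rel_units <- units[units$relatedness == "related", ]
      unrel_units <- units[units$relatedness == "unrelated", ]
      mentions <- dplyr::bind_rows(
        if (n_rel > 0 && nrow(rel_units) > 0) {
          rel_units[sample.int(nrow(rel_units), n_rel, replace = TRUE), ]
        },
        if (n_unrel > 0 && nrow(unrel_units) > 0) {
          unrel_units[sample.int(nrow(unrel_units), n_unrel, replace = TRUE), ]
        }
      )
      if (nrow(mentions) == 0) mentions <- units[0, ]
      sent <- 0L
      toks <- list()
      if (nrow(mentions) > 0) {
        for (m in seq_len(nrow(mentions))) {
          sent <- sent + 1L
          forms <- lexicon$surface_form[lexicon$unit_id == mentions$unit_id[m]]
          form <- forms[sample.int(length(forms), 1)]
          form_toks <- strsplit(form, " ", fixed = TRUE)[[1]]
          toks[[length(toks) + 1L]] <- tibble::tibble(
            token = c("the", form_toks, "is", "there", "."),
            pos = c("DT", rep("NN", length(form_toks)), "VBZ", "RB", "."),
            sentence = sent
          )
        }
      }
      for (f in seq_len(config$n_filler_sentences)) {
        sent <- sent + 1L
        toks[[length(toks) + 1L]] <- tibble::tibble(
          token = c("um", "i", "see", "it", "."),
          pos = c("UH", "PRP", "VBP", "PRP", "."),
          sentence = sent
        )
      }
      tok_tbl <- dplyr::bind_rows(toks)
      tok_tbl$participant_id <- id
      all_tokens[[i]] <- tok_tbl[, c("participant_id", "token", "pos", "sentence")]
      cnt <- function(rows) nrow(rows)
      dst <- function(rows) length(unique(rows$unit_id))
      rel <- mentions[mentions$relatedness == "related", ]
      gt[[i]] <- tibble::tibble(
        participant_id = id,
        related = cnt(rel), distinct_related = dst(rel),
        all = cnt(mentions), all_distinct = dst(mentions),
        left = cnt(mentions[mentions$location == "left", ]),
        left_distinct = dst(mentions[mentions$location == "left", ]),
        right = cnt(mentions[mentions$location == "right", ]),
        right_distinct = dst(mentions[mentions$location == "right", ]),
        both = cnt(mentions[mentions$location == "both", ]),
        both_distinct = dst(mentions[mentions$location == "both", ])
      )
    }
    list(
      tokens = dplyr::bind_rows(all_tokens),
      ground_truth = dplyr::bind_rows(gt)
    )
  })
}
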