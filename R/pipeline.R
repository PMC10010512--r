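#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults reproduce
#' the screening protocol the package implements: 5-fold
#' cross-validation, 10 averaged replications, Benjamini-Yekutieli FDR,
#' and a 0.85 specificity floor for threshold metrics.
#'
#' @param cohort A [cohort_config()] used when no data are supplied.
#' @param features,participants Optional observed tables (tibbles or CSV
#'   paths); when `NULL` a synthetic cohort is generated from `cohort`.
#' @param registry Feature registry.
#' @param screen_pairs List of cohort pairs to screen; each element is a
#'   list with `case` and `control` labels.
#' @param risk_tasks Risk-score tasks to fit.
#' @param run_contrasts,run_risk,run_multinomial Stage toggles.
#' @param contrast_auroc Also evaluate the per-contrast classifiers
#'   (slow: one repeated-CV fit per contrast; association p-values and
#'   FDR are always computed)?
#' @param nfolds,repeats,alpha_grid,min_specificity CV and threshold
#'   settings.
#' @param out_dir Optional output directory for the report bundle.
#' @param seed Global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @return A list of class `pd_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            features = NULL, participants = NULL,
                            registry = feature_registry(),
                            screen_pairs = list(
                              list(case = "aMCI", control = "HC"),
                              list(case = "naMCI", control = "HC")
                            ),
                            risk_tasks = c("aMCI-vs-HC", "naMCI-vs-HC", "MCI-vs-HC"),
                            run_contrasts = TRUE, run_risk = TRUE,
                            run_multinomial = FALSE,
                            contrast_auroc = FALSE,
                            nfolds = 5, repeats = 10,
                            alpha_grid = seq(0, 1, by = 0.1),
                            min_specificity = 0.85,
                            out_dir = NULL, seed = 1L) {
  structure(
    list(
      cohort = cohort, features = features, participants = participants,
      registry = registry, screen_pairs = screen_pairs,
      risk_tasks = risk_tasks, run_contrasts = run_contrasts,
      run_risk = run_risk, run_multinomial = run_multinomial,
      contrast_auroc = contrast_auroc, nfolds = nfolds, repeats = repeats,
      alpha_grid = alpha_grid, min_specificity = min_specificity,
      fdr_method = "BY", out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pd_pipeline_config"
  )
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: cohort input (synthetic generation
#' unless observed tables are supplied), quantile normalization,
#' within-modality contrasts, adjusted association screens with BY FDR
#' for each configured cohort pair (features and contrasts as separate
#' FDR families), elastic-net risk scores per task, optional penalized
#' multinomial risk scores, and a report bundle with a manifest
#' recording the seed, config hash and per-stage dimensions. Re-running
#' with an identical config and seed reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pd_report`: `participants`, `features`
#'   (normalized), `contrasts`, `screens` (named list of `pd_screen`
#'   tibbles), `risk_models`, `multinomial`, `tables` (report tables
#'   from [report_tables()]) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pd_pipeline_config"))
  registry <- config$registry
  seed <- config$seed

  if (is.null(config$features)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- derive_seed(seed, "simulate")
    cohort <- simulate_cohort(cohort_cfg, registry)
    participants <- cohort$participants
    features_raw <- cohort$features
  } else {
    features_raw <- maybe_read_csv(config$features)
    participants <- maybe_read_csv(config$participants)
  }

  features <- quantile_normalize(features_raw)
  contrasts <- if (config$run_contrasts) build_contrasts(features, registry) else NULL

  screens <- list()
  for (i in seq_along(config$screen_pairs)) {
    pair <- config$screen_pairs[[i]]
    key <- paste(paste(pair$case, collapse = "+"), "vs", pair$control)
    screens[[paste0("features: ", key)]] <- screen_features(
      features, participants,
      case = pair$case, control = pair$control,
      compute_auroc = TRUE, min_specificity = config$min_specificity,
      seed = derive_seed(seed, "screen_features") + i,
      nfolds = config$nfolds, repeats = config$repeats
    )
    if (config$run_contrasts) {
      screens[[paste0("contrasts: ", key)]] <- screen_features(
        contrasts, participants,
        case = pair$case, control = pair$control,
        compute_auroc = config$contrast_auroc,
        min_specificity = config$min_specificity,
        seed = derive_seed(seed, "screen_contrasts") + i,
        nfolds = config$nfolds, repeats = config$repeats
      )
    }
  }

  risk_models <- list()
  if (config$run_risk) {
    stage_seed <- c(
      "aMCI-vs-HC" = "risk_amci", "naMCI-vs-HC" = "risk_namci",
      "MCI-vs-HC" = "risk_mci"
    )
    for (task in config$risk_tasks) {
      risk_models[[task]] <- fit_risk_score(
        features, participants,
        task = task, registry = registry,
        alpha_grid = config$alpha_grid, nfolds = config$nfolds,
        repeats = config$repeats,
        seed = derive_seed(seed, stage_seed[[task]])
      )
    }
  }
  multinomial <- if (config$run_multinomial) {
    fit_multinomial_risk(
      features, participants,
      registry = registry,
      alpha_grid = config$alpha_grid, nfolds = config$nfolds,
      repeats = config$repeats, seed = derive_seed(seed, "risk_multinomial")
    )
  } else {
    NULL
  }

  tables <- report_tables(screens, risk_models, multinomial,
    features = features, participants = participants
  )
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    fdr_method = config$fdr_method,
    n_participants = nrow(participants),
    n_features = length(setdiff(names(features), "participant_id")),
    n_contrasts = if (is.null(contrasts)) 0L else length(setdiff(names(contrasts), "participant_id")),
    n_language_contrasts = if (is.null(contrasts)) 0L else sum(attr(contrasts, "pd_contrast_pairs")$modality == "language"),
    n_acoustic_contrasts = if (is.null(contrasts)) 0L else sum(attr(contrasts, "pd_contrast_pairs")$modality == "acoustic"),
    screens = names(screens),
    risk_tasks = names(risk_models)
  )
  out <- structure(
    list(
      participants = participants, features = features,
      contrasts = contrasts, screens = screens,
      risk_models = risk_models, multinomial = multinomial,
      tables = tables, manifest = manifest
    ),
    class = "pd_report"
  )
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

maybe_read_csv <- function(x) {
  if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
}

#' Assemble report tables
#'
#' Renders the pipeline results as plain tibbles: one screening table
#' per cohort pair (sorted by ascending p, with p, FDR, AUROC and
#' effect direction), a risk-score AUROC table with one row per task,
#' and a long-format table of feature values by cohort ready for violin
#' plots.
#'
#' @param screens Named list of `pd_screen` tibbles.
#' @param risk_models Named list of `pd_risk_model` objects.
#' @param multinomial Optional `pd_multinomial_risk`.
#' @param features,participants Optional normalized feature and
#'   participant tables for the plot-ready long table.
#' @return Named list of tibbles: `screens` (named list),
#'   `risk_aurocs`, `violin_data`.
#' @export
report_tables <- function(screens = list(), risk_models = list(),
                          multinomial = NULL, features = NULL,
                          participants = NULL) {
  risk_aurocs <- if (length(risk_models) > 0) {
    purrr::imap_dfr(risk_models, function(m, task) {
      tibble::tibble(task = task, auroc = m$auroc, alpha = m$alpha, lambda = m$lambda)
    })
  } else {
    tibble::tibble(task = character(), auroc = numeric(), alpha = numeric(), lambda = numeric())
  }
  if (!is.null(multinomial)) {
    risk_aurocs <- dplyr::bind_rows(
      risk_aurocs,
      dplyr::mutate(multinomial$aurocs,
        task = paste0("multinomial: ", .data$task),
        alpha = multinomial$alpha, lambda = multinomial$lambda
      )
    )
  }
  violin_data <- if (!is.null(features) && !is.null(participants)) {
    features |>
      tidyr::pivot_longer(-"participant_id", names_to = "feature", values_to = "value") |>
      dplyr::left_join(
        participants[, c("participant_id", "diagnosis")],
        by = "participant_id"
      )
  } else {
    NULL
  }
  list(screens = screens, risk_aurocs = risk_aurocs, violin_data = violin_data)
}

#' Write a report bundle to disk
#'
#' CSV renditions of every screen table, the risk AUROC table, the
#' violin-plot-ready long table, and a JSON manifest in which every
#' written file is listed with a content hash.
#'
#' @param report A `pd_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pd_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(report$screens)) {
    fn <- file.path(dir, paste0(
      gsub("[^A-Za-z0-9]+", "_", tolower(nm)), ".csv"
    ))
    readr::write_csv(report$screens[[nm]], fn, na = "")
    files <- c(files, fn)
  }
  fn <- file.path(dir, "risk_aurocs.csv")
  readr::write_csv(report$tables$risk_aurocs, fn, na = "")
  files <- c(files, fn)
  if (!is.null(report$tables$violin_data)) {
    fn <- file.path(dir, "violin_data.csv")
    readr::write_csv(report$tables$violin_data, fn, na = "")
    files <- c(files, fn)
  }
  manifest <- report$manifest
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), hash = rlang::hash(readr::read_file(f)))
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
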