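#' Elastic-net picture-description risk score
#'
#' Builds a combined risk score for one cohort pair from the full
#' feature panel plus age and gender. Age and gender are never
#' penalized, so they always stay in the model; features carry the
#' elastic-net penalty (`alpha` mixes L1 and L2, `lambda` scales both).
#' `alpha` and `lambda` are chosen jointly on a grid by minimizing
#' 5-fold cross-validated predictive deviance, with the missing tremor
#' features imputed separately within every train and test subset (the
#' completion is fit on each subset alone, so nothing leaks across the
#' split). After the penalties are fixed, out-of-sample link-scale
#' predictions from `repeats` further replications of cross-validation
#' are averaged per participant; those averages are the risk scores (an
#' estimate of each participant's log-odds of being a case) and are
#' summarized by AUROC. Features are expected quantile normalized, so
#' no further internal standardization is applied (it would distort the
#' unpenalized covariates' scale); set `standardize = TRUE` to override.
#'
#' @param features Quantile-normalized feature tibble
#'   (`participant_id` + all registry features; missing values only in
#'   `may_be_missing` features).
#' @param participants Tibble with `participant_id`, `diagnosis`,
#'   `age`, `gender`.
#' @param task `"aMCI-vs-HC"`, `"naMCI-vs-HC"` or `"MCI-vs-HC"`
#'   (combined aMCI + naMCI cases).
#' @param registry Feature registry matching the feature columns.
#' @param alpha_grid Candidate L1:L2 mixing values (default 0, 0.1, ...,
#'   1).
#' @param nfolds Cross-validation folds (default 5, stratified by
#'   class).
#' @param repeats Replications of cross-validation averaged into the
#'   final scores (default 10).
#' @param seed Integer seed; the full fit is reproducible from it.
#' @param rank_max Maximum rank for the tremor-feature completion.
#' @param standardize Internal standardization inside the penalized fit
#'   (default off; see Details).
#' @param lambda_choice `"min"` (deviance-minimizing lambda, default) or
#'   `"1se"` (largest lambda within one SE of the minimum).
#' @return An object of class `pd_risk_model`: task, selected `alpha`
#'   and `lambda`, sparse feature `weights`, `intercept`,
#'   `covariate_weights` (age, gender), per-participant out-of-sample
#'   `scores` tibble, `auroc`, fold bookkeeping and seed.
#' @export
fit_risk_score <- function(features, participants,
                           task = c("aMCI-vs-HC", "naMCI-vs-HC", "MCI-vs-HC"),
                           registry = feature_registry(),
                           alpha_grid = seq(0, 1, by = 0.1),
                           nfolds = 5, repeats = 10, seed = 1L,
                           rank_max = 5, standardize = FALSE,
                           lambda_choice = c("min", "1se")) {
  task <- match.arg(task)
  lambda_choice <- match.arg(lambda_choice)
  case <- switch(task,
    "aMCI-vs-HC" = "aMCI",
    "naMCI-vs-HC" = "naMCI",
    "MCI-vs-HC" = c("aMCI", "naMCI")
  )
  prep <- prepare_risk_data(features, participants, c(case, "HC"), registry)
  y <- as.integer(prep$participants$diagnosis %in% case)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("task ", task, " has an empty class in these data")
  }

  with_rng_seed(seed, {
    sel <- select_elastic_net_penalties(
      prep, y,
      family = "binomial", alpha_grid = alpha_grid, nfolds = nfolds,
      rank_max = rank_max, standardize = standardize,
      lambda_choice = lambda_choice
    )
    full <- impute_split(prep$features, NULL, registry = registry, rank_max = rank_max)$train
    Xfull <- risk_design(full, prep$participants, registry)
    fit <- glmnet::glmnet(Xfull, y,
      family = "binomial", alpha = sel$alpha,
      lambda = ridge_lambda_path(sel$lambda),
      penalty.factor = prep$penalty_factor, standardize = standardize
    )
    coefs <- as.numeric(stats::coef(fit, s = sel$lambda))
    names(coefs) <- c("(Intercept)", colnames(Xfull))

    oos <- oos_scores_cv(
      prep, y,
      family = "binomial", alpha = sel$alpha, lambda = sel$lambda,
      nfolds = nfolds, repeats = repeats, rank_max = rank_max,
      standardize = standardize
    )
    scores <- tibble::tibble(
      participant_id = prep$participants$participant_id,
      diagnosis = prep$participants$diagnosis,
      score = oos$scores
    )
    structure(
      list(
        task = task, alpha = sel$alpha, lambda = sel$lambda,
        weights = coefs[registry$name],
        intercept = coefs[["(Intercept)"]],
        covariate_weights = coefs[c("age", "gender")],
        scores = scores,
        auroc = auroc(scores$score, y),
        cv_deviance = sel$cv_table,
        fold_assignments = oos$fold_assignments,
        nfolds = nfolds, repeats = repeats, seed = seed
      ),
      class = "pd_risk_model"
    )
  })
}

# Align features and participants for a task; features first in the
# design, then the unpenalized covariates.
prepare_risk_data <- function(features, participants, keep_groups, registry) {
  validate_registry(registry)
  missing_feats <- setdiff(registry$name, names(features))
  if (length(missing_feats) > 0) {
    stop("feature table lacks registry feature(s): ", paste(utils::head(missing_feats, 5), collapse = "; "))
  }
  part <- participants[participants$diagnosis %in% keep_groups, ]
  feat <- dplyr::semi_join(features, part, by = "participant_id")
  part <- part[match(feat$participant_id, part$participant_id), ]
  norm_attr <- attr(features, "pd_normalized")
  feat <- feat[, c("participant_id", registry$name)]
  attr(feat, "pd_normalized") <- norm_attr
  list(
    features = feat, participants = part, registry = registry,
    penalty_factor = c(rep(1, nrow(registry)), 0, 0)
  )
}

risk_design <- function(features, participants, registry) {
  X <- as.matrix(features[, registry$name, drop = FALSE])
  cbind(X, age = participants$age, gender = code_gender(participants$gender))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

# Joint (alpha, lambda) selection by cross-validated deviance with
# per-split imputation inside every fold.
select_elastic_net_penalties <- function(prep, y, family, alpha_grid, nfolds,
                                         rank_max, standardize, lambda_choice) {
  registry <- prep$registry
  strat <- if (family == "multinomial") as.character(y) else y
  foldid <- make_stratified_folds(strat, nfolds)
  full_imp <- impute_split(prep$features, NULL, registry = registry, rank_max = rank_max)$train
  Xfull <- risk_design(full_imp, prep$participants, registry)
  # fold-wise split imputation does not depend on alpha: do it once
  fold_designs <- lapply(seq_len(nfolds), function(f) {
    tr <- foldid != f
    sp <- impute_split(prep$features[tr, ], prep$features[!tr, ],
      registry = registry, rank_max = rank_max
    )
    list(
      tr = tr,
      Xtr = risk_design(sp$train, prep$participants[tr, ], registry),
      Xte = risk_design(sp$test, prep$participants[!tr, ], registry)
    )
  })
  cv_rows <- list()
  best <- list(dev = Inf)
  for (alpha in alpha_grid) {
    path_fit <- glmnet::glmnet(Xfull, y,
      family = family, alpha = alpha,
      penalty.factor = prep$penalty_factor, standardize = standardize,
      nlambda = 100
    )
    lambdas <- path_fit$lambda
    dev <- matrix(0, nrow = nfolds, ncol = length(lambdas))
    for (f in seq_len(nfolds)) {
      tr <- fold_designs[[f]]$tr
      Xtr <- fold_designs[[f]]$Xtr
      Xte <- fold_designs[[f]]$Xte
      fit <- glmnet::glmnet(Xtr, if (family == "multinomial") y[tr] else y[tr],
        family = family, alpha = alpha, lambda = lambdas,
        penalty.factor = prep$penalty_factor, standardize = standardize
      )
      pr <- stats::predict(fit, Xte, s = lambdas, type = "response")
      if (family == "binomial") {
        for (l in seq_along(lambdas)) {
          dev[f, l] <- binomial_deviance(y[!tr], pr[, l])
        }
      } else {
        yte <- as.character(y[!tr])
        for (l in seq_along(lambdas)) {
          pmat <- pr[, , l]
          ptrue <- pmat[cbind(seq_along(yte), match(yte, colnames(pmat)))]
          dev[f, l] <- -2 * sum(log(pmin(pmax(ptrue, 1e-12), 1)))
        }
      }
    }
    mean_dev <- colSums(dev)
    li <- which.min(mean_dev)
    if (lambda_choice == "1se") {
      se <- apply(dev, 2, stats::sd) / sqrt(nfolds)
      ok <- mean_dev <= mean_dev[li] + se[li]
      li <- which(ok)[1] # lambdas are decreasing: first = largest
    }
    cv_rows[[length(cv_rows) + 1]] <- tibble::tibble(
      alpha = alpha, lambda = lambdas[li], deviance = mean_dev[li]
    )
    if (mean_dev[li] < best$dev) {
      best <- list(alpha = alpha, lambda = lambdas[li], dev = mean_dev[li])
    }
  }
  list(alpha = best$alpha, lambda = best$lambda, cv_table = dplyr::bind_rows(cv_rows))
}

# Repeated cross-validated out-of-sample predictions at fixed penalties,
# with per-split imputation; every score comes from a model whose
# training fold excluded that participant.
oos_scores_cv <- function(prep, y, family, alpha, lambda, nfolds, repeats,
                          rank_max, standardize) {
  registry <- prep$registry
  n <- length(y)
  strat <- if (family == "multinomial") as.character(y) else y
  n_class <- if (family == "multinomial") nlevels(factor(y)) else 1
  preds <- array(NA_real_, dim = c(n, n_class, repeats))
  fold_assignments <- matrix(NA_integer_, nrow = n, ncol = repeats)
  class_names <- NULL
  for (r in seq_len(repeats)) {
    foldid <- make_stratified_folds(strat, nfolds)
    fold_assignments[, r] <- foldid
    for (f in seq_len(nfolds)) {
      tr <- foldid != f
      sp <- impute_split(prep$features[tr, ], prep$features[!tr, ],
        registry = registry, rank_max = rank_max
      )
      Xtr <- risk_design(sp$train, prep$participants[tr, ], registry)
      Xte <- risk_design(sp$test, prep$participants[!tr, ], registry)
      fit <- glmnet::glmnet(Xtr, y[tr],
        family = family, alpha = alpha,
        lambda = ridge_lambda_path(lambda),
        penalty.factor = prep$penalty_factor, standardize = standardize
      )
      lk <- stats::predict(fit, Xte, s = lambda, type = "link")
      if (family == "binomial") {
        preds[!tr, 1, r] <- as.numeric(lk)
      } else {
        if (is.null(class_names)) class_names <- colnames(lk)
        preds[!tr, , r] <- lk[, , 1]
      }
    }
  }
  scores <- apply(preds, c(1, 2), mean)
  if (family == "binomial") {
    list(scores = scores[, 1], fold_assignments = fold_assignments)
  } else {
    colnames(scores) <- class_names
    list(scores = scores, fold_assignments = fold_assignments)
  }
}

#' Penalized multinomial risk scores for the three-cohort problem
#'
#' Fits one penalized multinomial logistic model over all three
#' diagnoses simultaneously (age and gender unpenalized), selecting
#' `alpha` and `lambda` by 5-fold cross-validated deviance with
#' per-split imputation, then averages link-scale class liabilities
#' over `repeats` further rounds of cross-validation. Differences of
#' liabilities for a pair of diagnoses estimate the pairwise log-odds
#' and serve as risk scores for the three classification tasks
#' (aMCI vs HC, naMCI vs HC, aMCI vs naMCI), each summarized by AUROC.
#'
#' @inheritParams fit_risk_score
#' @return An object of class `pd_multinomial_risk`: selected penalties,
#'   per-class coefficient table, `liabilities` tibble (per participant,
#'   one column per diagnosis plus the three pairwise differences), and
#'   `aurocs` tibble for the three pairwise tasks.
#' @export
fit_multinomial_risk <- function(features, participants,
                                 registry = feature_registry(),
                                 alpha_grid = seq(0, 1, by = 0.1),
                                 nfolds = 5, repeats = 10, seed = 1L,
                                 rank_max = 5, standardize = FALSE,
                                 lambda_choice = c("min", "1se")) {
  lambda_choice <- match.arg(lambda_choice)
  groups <- c("HC", "aMCI", "naMCI")
  prep <- prepare_risk_data(features, participants, groups, registry)
  y <- factor(prep$participants$diagnosis, levels = groups)
  counts <- table(y)
  if (any(counts < 3)) {
    stop(
      "every diagnosis needs at least 3 members for the multinomial model ",
      "(consider the two-class fit_risk_score path); counts: ",
      paste(names(counts), counts, sep = "=", collapse = ", ")
    )
  }

  with_rng_seed(seed, {
    sel <- select_elastic_net_penalties(
      prep, y,
      family = "multinomial", alpha_grid = alpha_grid, nfolds = nfolds,
      rank_max = rank_max, standardize = standardize,
      lambda_choice = lambda_choice
    )
    full <- impute_split(prep$features, NULL, registry = registry, rank_max = rank_max)$train
    Xfull <- risk_design(full, prep$participants, registry)
    fit <- glmnet::glmnet(Xfull, y,
      family = "multinomial", alpha = sel$alpha,
      lambda = ridge_lambda_path(sel$lambda),
      penalty.factor = prep$penalty_factor, standardize = standardize
    )
    co <- stats::coef(fit, s = sel$lambda)
    coef_tbl <- purrr::imap_dfr(co, function(m, cls) {
      tibble::tibble(
        class = cls, term = rownames(m), estimate = as.numeric(m)
      )
    })

    oos <- oos_scores_cv(
      prep, y,
      family = "multinomial", alpha = sel$alpha, lambda = sel$lambda,
      nfolds = nfolds, repeats = repeats, rank_max = rank_max,
      standardize = standardize
    )
    liab <- tibble::as_tibble(oos$scores)
    liab <- liab[, groups]
    liabilities <- dplyr::bind_cols(
      tibble::tibble(
        participant_id = prep$participants$participant_id,
        diagnosis = prep$participants$diagnosis
      ),
      liab,
      tibble::tibble(
        `aMCI-HC` = liab$aMCI - liab$HC,
        `naMCI-HC` = liab$naMCI - liab$HC,
        `aMCI-naMCI` = liab$aMCI - liab$naMCI
      )
    )
    pair_auroc <- function(case, control, diff_col) {
      keep <- liabilities$diagnosis %in% c(case, control)
      auroc(liabilities[[diff_col]][keep], as.integer(liabilities$diagnosis[keep] == case))
    }
    aurocs <- tibble::tibble(
      task = c("aMCI-vs-HC", "naMCI-vs-HC", "aMCI-vs-naMCI"),
      auroc = c(
        pair_auroc("aMCI", "HC", "aMCI-HC"),
        pair_auroc("naMCI", "HC", "naMCI-HC"),
        pair_auroc("aMCI", "naMCI", "aMCI-naMCI")
      )
    )
    structure(
      list(
        alpha = sel$alpha, lambda = sel$lambda, coefficients = coef_tbl,
        liabilities = liabilities, aurocs = aurocs,
        cv_deviance = sel$cv_table, fold_assignments = oos$fold_assignments,
        nfolds = nfolds, repeats = repeats, seed = seed
      ),
      class = "pd_multinomial_risk"
    )
  })
}
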