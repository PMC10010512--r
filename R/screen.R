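#' Age- and gender-adjusted logistic association test
#'
#' Fits `glm(y ~ age + gender + x, family = binomial)` with cases coded
#' 1 and controls 0, and returns the feature coefficient with its Wald
#' p-value. The effect direction is the coefficient's sign: positive
#' means cases sit higher on the feature after adjusting for age and
#' gender. Rows with missing `x` are dropped (with a message), so
#' contrasts are always tested on observed, never imputed, values.
#' Complete or quasi-complete separation is detected from a diverging
#' coefficient (or non-convergence) and flagged; the p-value is then
#' unreliable and reported as `NA`.
#'
#' @param y Binary labels, cases = 1.
#' @param x Feature or contrast values (may contain `NA`).
#' @param age Age in years.
#' @param gender `"female"`/`"male"` or numeric (female = 0, male = 1).
#' @return One-row tibble: `beta`, `p_value`, `effect_direction`
#'   (`"+"`/`"-"`), `separation` (logical), `n_used`.
#' @export
adjusted_association <- function(y, x, age, gender) {
  y <- as_binary_labels(y)
  g <- code_gender(gender)
  keep <- !is.na(x) & !is.na(y) & !is.na(age) & !is.na(g)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("adjusted_association: dropping ", n_drop, " row(s) with missing values")
  }
  y <- y[keep]; x <- x[keep]; age <- age[keep]; g <- g[keep]
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 participants per class")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ age + g + x, family = stats::binomial(link = "logit"))
  )
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  separation <- !fit$converged || abs(beta) > 15 || se > 100
  p <- if (separation) NA_real_ else co["x", "Pr(>|z|)"]
  tibble::tibble(
    beta = beta,
    p_value = p,
    effect_direction = ifelse(beta >= 0, "+", "-"),
    separation = separation,
    n_used = length(y)
  )
}

#' Benjamini-Yekutieli false discovery rates
#'
#' Step-up FDR adjustment valid under arbitrary dependence among tests:
#' adjusted value at rank `i` (ascending p) is
#' `p_i * m * c(m) / i` with `c(m) = sum(1/1..1/m)`, made monotone
#' nonincreasing from the largest rank down and capped at 1. The family
#' is exactly the vector passed in: feature screens and contrast
#' screens are adjusted as separate families.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA`s allowed, returned as
#'   `NA`).
#' @return Adjusted values, same length and order as `p`.
#' @export
#' @examples
#' by_fdr(c(0.01, 0.02, 0.03, 0.04))
by_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  out <- rep(NA_real_, length(p))
  obs <- which(!is.na(p))
  if (length(obs) == 0) return(out)
  pv <- p[obs]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  cm <- sum(1 / seq_len(m))
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m * cm / (m:1) * pv[o]))[ro]
  out[obs] <- adj
  out
}

#' Single-feature ridge classifier with repeated cross-validation
#'
#' Evaluates one feature (plus age and gender) as a classifier. The L2
#' penalty is selected by 5-fold cross-validated deviance; out-of-sample
#' link-scale predictions are then generated by 5-fold cross-validation
#' at the selected penalty, repeated `repeats` times with fresh
#' stratified fold splits and averaged per participant. The averaged
#' scores estimate each participant's log-odds of being a case and are
#' summarized by their AUROC. With fewer than `nfolds` members in a
#' class the fold count is reduced (minimum 3) with a warning.
#'
#' @inheritParams adjusted_association
#' @param x Feature values; rows with `NA` are dropped.
#' @param seed Integer seed controlling fold assignment.
#' @param nfolds Folds for penalty selection and prediction (default 5).
#' @param repeats Cross-validation replications averaged (default 10).
#' @return List: `auroc`, `scores` (per-participant averaged
#'   out-of-sample log-odds), `keep` (logical row filter used),
#'   `lambda` (selected penalty).
#' @export
single_feature_classifier <- function(y, x, age, gender, seed = 1L,
                                      nfolds = 5, repeats = 10) {
  y <- as_binary_labels(y)
  g <- code_gender(gender)
  keep <- !is.na(x) & !is.na(y) & !is.na(age) & !is.na(g)
  y <- y[keep]; x <- x[keep]; age <- age[keep]; g <- g[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (min(n1, n0) < nfolds) {
    nfolds <- max(3, min(n1, n0))
    warning("reducing folds to ", nfolds, " (small class)")
  }
  X <- cbind(x = x, age = age, gender = g)
  with_rng_seed(seed, {
    cvfit <- glmnet::cv.glmnet(X, y,
      alpha = 0, family = "binomial",
      nfolds = nfolds, foldid = make_stratified_folds(y, nfolds)
    )
    lambda <- cvfit$lambda.min
    preds <- matrix(NA_real_, nrow = length(y), ncol = repeats)
    for (r in seq_len(repeats)) {
      foldid <- make_stratified_folds(y, nfolds)
      for (f in seq_len(nfolds)) {
        tr <- foldid != f
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
          alpha = 0, family = "binomial", lambda = ridge_lambda_path(lambda)
        )
        preds[!tr, r] <- as.numeric(
          stats::predict(fit, X[!tr, , drop = FALSE], s = lambda, type = "link")
        )
      }
    }
    scores <- rowMeans(preds)
    list(auroc = auroc(scores, y), scores = scores, keep = keep, lambda = lambda)
  })
}

# glmnet prefers a decreasing path ending at the target lambda; the fit
# is then evaluated exactly at that lambda.
ridge_lambda_path <- function(lambda) {
  lam0 <- max(lambda, 1e-6)
  path <- exp(seq(log(lam0 * 100), log(lam0), length.out = 10))
  path[length(path)] <- lam0 # exact target, no roundoff near-duplicate
  if (lambda < lam0) path <- c(path, lambda)
  path
}

#' Screen features or contrasts against a cohort pair
#'
#' Runs the adjusted logistic association test for every target column,
#' adjusts the resulting p-values by Benjamini-Yekutieli within exactly
#' this family of tests, and (optionally) evaluates each target as a
#' ridge classifier with repeated cross-validation, reporting AUROC and
#' specificity-constrained threshold metrics. Rows are sorted by
#' ascending p-value, the convention used to present screening tables.
#'
#' @param targets Feature or contrast tibble (`participant_id` + one
#'   numeric column per target), quantile normalized upstream.
#' @param participants Tibble with `participant_id`, `diagnosis`, `age`,
#'   `gender`.
#' @param case Diagnosis label(s) coded 1 (e.g. `"aMCI"`, or
#'   `c("aMCI", "naMCI")` for combined MCI).
#' @param control Diagnosis label(s) coded 0 (default `"HC"`).
#' @param compute_auroc Evaluate the per-target classifier too?
#' @param min_specificity Specificity floor for threshold metrics.
#' @param seed Integer seed for classifier fold assignment.
#' @param nfolds,repeats Cross-validation settings for the classifier.
#' @return A `pd_screen` tibble: `target`, `beta`, `p_value`, `fdr`,
#'   `effect_direction`, `separation`, `n_used`, and when
#'   `compute_auroc` also `auroc`, `threshold`, `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `f1`.
#' @export
screen_features <- function(targets, participants, case, control = "HC",
                            compute_auroc = TRUE, min_specificity = 0.85,
                            seed = 1L, nfolds = 5, repeats = 10) {
  stopifnot(all(c("participant_id", "diagnosis", "age", "gender") %in% names(participants)))
  part <- participants[participants$diagnosis %in% c(case, control), ]
  dat <- dplyr::inner_join(part, targets, by = "participant_id")
  y <- as.integer(dat$diagnosis %in% case)
  target_names <- setdiff(names(targets), "participant_id")
  rows <- purrr::imap(target_names, function(nm, i) {
    res <- suppressMessages(adjusted_association(y, dat[[nm]], dat$age, dat$gender))
    res$target <- nm
    if (compute_auroc) {
      clf <- suppressWarnings(single_feature_classifier(
        y, dat[[nm]], dat$age, dat$gender,
        seed = derive_seed(seed, i), nfolds = nfolds, repeats = repeats
      ))
      thr <- select_threshold(clf$scores, y[clf$keep], min_specificity = min_specificity)
      res$auroc <- clf$auroc
      res$threshold <- thr$threshold
      res$sensitivity <- thr$sensitivity
      res$specificity <- thr$specificity
      res$precision <- thr$precision
      res$accuracy <- thr$accuracy
      res$f1 <- thr$f1
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- by_fdr(out$p_value)
  front <- c("target", "beta", "p_value", "fdr", "effect_direction")
  out <- out[order(out$p_value), c(front, setdiff(names(out), front))]
  class(out) <- c("pd_screen", class(out))
  attr(out, "cohort_pair") <- paste(paste(case, collapse = "+"), "vs", paste(control, collapse = "+"))
  out
}
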