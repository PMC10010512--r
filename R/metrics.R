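#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties counted one half. Computed from ranks, so
#' it equals brute-force enumeration over all case-control pairs.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param labels Binary labels, cases = 1, controls = 0 (logical or
#'   two-level factor also accepted).
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("factor labels must have exactly two levels")
    return(as.integer(labels == levels(labels)[2]))
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1 (cases = 1)")
  y
}

#' Confusion-matrix metrics at a threshold
#'
#' Predicted positive = score strictly above the threshold; positive =
#' case (label 1). F1 is the harmonic mean of sensitivity and precision
#' and is 0 when its denominator vanishes.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold (may be infinite).
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f1`, and the counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  pred <- scores > threshold
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  acc <- (tp + tn) / length(y)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  tibble::tibble(
    threshold = threshold, sensitivity = sens, specificity = spec,
    precision = prec, accuracy = acc, f1 = f1,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Specificity-constrained threshold selection
#'
#' Candidate thresholds are the midpoints between adjacent sorted unique
#' scores plus minus and plus infinity. Among candidates whose
#' specificity is at least `min_specificity`, the one maximizing F1 is
#' returned; ties break toward higher specificity, then higher
#' threshold. The constraint is always satisfiable: a +Inf threshold
#' classifies everyone negative, with specificity 1 and F1 0. Screening
#' applications set a specificity floor (default 0.85) to keep the
#' false-positive rate clinically tolerable; under the floor the other
#' metrics (sensitivity, precision, F1) can be low.
#'
#' @inheritParams auroc
#' @param min_specificity Specificity floor in `[0, 1]`; 0 recovers
#'   unconstrained F1 maximization.
#' @return One-row tibble as [confusion_metrics()] plus `feasible`
#'   (a finite threshold meeting the constraint exists), `auroc`.
#' @export
select_threshold <- function(scores, labels, min_specificity = 0.85) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  grid <- purrr::map_dfr(cand, function(th) confusion_metrics(scores, y, th))
  ok <- grid$specificity >= min_specificity
  feasible_grid <- grid[ok, , drop = FALSE]
  # +Inf always qualifies, so feasible_grid is never empty
  best <- feasible_grid[order(-feasible_grid$f1, -feasible_grid$specificity,
    -feasible_grid$threshold
  )[1], , drop = FALSE]
  best$feasible <- any(ok & is.finite(grid$threshold)) || any(ok)
  best$auroc <- auroc(scores, y)
  best
}
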