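#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted risk-score model
#'
#' One row per model term with its coefficient at the selected
#' penalties; `selected` marks terms retained with nonzero weight
#' (age and gender are unpenalized, hence always present).
#'
#' @param x A `pd_risk_model`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `penalized`, `selected`.
#' @method tidy pd_risk_model
#' @export
tidy.pd_risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$weights), names(x$covariate_weights)),
    estimate = c(x$intercept, unname(x$weights), unname(x$covariate_weights)),
    penalized = c(FALSE, rep(TRUE, length(x$weights)), FALSE, FALSE)
  ) |>
    dplyr::mutate(selected = .data$estimate != 0)
}

#' Model-level summary of a fitted risk-score model
#'
#' @param x A `pd_risk_model`.
#' @param ... Unused.
#' @return One-row tibble: `task`, `auroc`, `alpha`, `lambda`,
#'   `n_selected` (penalized features with nonzero weight), `n`,
#'   `nfolds`, `repeats`.
#' @method glance pd_risk_model
#' @export
glance.pd_risk_model <- function(x, ...) {
  tibble::tibble(
    task = x$task, auroc = x$auroc, alpha = x$alpha, lambda = x$lambda,
    n_selected = sum(x$weights != 0), n = nrow(x$scores),
    nfolds = x$nfolds, repeats = x$repeats
  )
}

#' @method tidy pd_multinomial_risk
#' @export
tidy.pd_multinomial_risk <- function(x, ...) x$coefficients

#' @method glance pd_multinomial_risk
#' @export
glance.pd_multinomial_risk <- function(x, ...) {
  wide <- stats::setNames(x$aurocs$auroc, paste0("auroc_", gsub("-", "_", x$aurocs$task)))
  dplyr::bind_cols(
    tibble::tibble(alpha = x$alpha, lambda = x$lambda),
    tibble::as_tibble_row(as.list(wide))
  )
}

#' @export
print.pd_risk_model <- function(x, ...) {
  cat("<pd_risk_model> task:", x$task, "\n")
  cat("  alpha:", format(x$alpha), " lambda:", format(x$lambda, digits = 4), "\n")
  cat("  features selected:", sum(x$weights != 0), "of", length(x$weights), "\n")
  cat("  out-of-sample AUROC:", round(x$auroc, 3), "\n")
  invisible(x)
}

#' @export
print.pd_multinomial_risk <- function(x, ...) {
  cat("<pd_multinomial_risk> alpha:", format(x$alpha),
    " lambda:", format(x$lambda, digits = 4), "\n"
  )
  print(x$aurocs)
  invisible(x)
}

#' Violin plots of feature distributions by cohort
#'
#' The standard presentation of screened features: one panel per
#' feature, a violin with an embedded boxplot per cohort.
#'
#' @param features Feature tibble (`participant_id` + columns); raw or
#'   normalized.
#' @param participants Tibble with `participant_id` and `diagnosis`.
#' @param feature_names Features to plot (default: first 4 columns).
#' @return A ggplot object.
#' @export
plot_feature_violins <- function(features, participants,
                                 feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- utils::head(setdiff(names(features), "participant_id"), 4)
  }
  long <- features[, c("participant_id", feature_names)] |>
    tidyr::pivot_longer(-"participant_id", names_to = "feature", values_to = "value") |>
    dplyr::left_join(participants[, c("participant_id", "diagnosis")], by = "participant_id") |>
    dplyr::mutate(
      feature = factor(.data$feature, levels = feature_names),
      diagnosis = factor(.data$diagnosis, levels = c("aMCI", "HC", "naMCI"))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diagnosis, y = .data$value, fill = .data$diagnosis)) +
    ggplot2::geom_violin(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5, fill = "white", na.rm = TRUE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "feature value")
}

#' @describeIn screen_features Plot the strongest associations of a
#'   screen: -log10 p per target, colored by effect direction.
#' @param object A `pd_screen` tibble.
#' @param n Number of top targets to display.
#' @param ... Unused.
#' @method autoplot pd_screen
#' @export
autoplot.pd_screen <- function(object, n = 20, ...) {
  top <- utils::head(object, n)
  top$target <- factor(top$target, levels = rev(top$target))
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(.data$p_value), y = .data$target,
    color = .data$effect_direction
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(-log[10](p)), y = NULL, color = "direction",
      title = attr(object, "cohort_pair")
    )
}

#' @describeIn fit_risk_score Plot out-of-sample risk scores by cohort.
#' @param object A `pd_risk_model`.
#' @param ... Unused.
#' @method autoplot pd_risk_model
#' @export
autoplot.pd_risk_model <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$diagnosis, y = .data$score, fill = .data$diagnosis
  )) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(
      x = NULL, y = "risk score (log-odds)",
      title = object$task,
      subtitle = paste0("out-of-sample AUROC = ", round(object$auroc, 3))
    )
}
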