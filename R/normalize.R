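#' Quantile normalize a feature table
#'
#' Replaces each feature column by normal quantiles of its ranks:
#' non-missing values become `qnorm(rank / (n + 1))` with ranks
#' `1..n` over the column's non-missing entries and ties receiving the
#' mean of their rank positions. After normalization every complete
#' column shares the same fixed normal-quantile grid, so feature values
#' are in standard-deviation units and invariant to any strictly
#' monotone transform of the raw scale. Missing entries stay missing.
#'
#' @param features Tibble: `participant_id` plus numeric feature
#'   columns. Must not already be normalized.
#' @param id_col Name of the id column.
#' @return The normalized tibble, flagged via the `pd_normalized`
#'   attribute (checked by [build_contrasts()]).
#' @export
#' @examples
#' qt <- quantile_normalize(tibble::tibble(participant_id = c("a", "b", "c"), x = c(3.2, 1.1, 5)))
#' round(qt$x, 4)
quantile_normalize <- function(features, id_col = "participant_id") {
  features <- tibble::as_tibble(features)
  if (isTRUE(attr(features, "pd_normalized"))) {
    stop("feature table is already quantile normalized")
  }
  stopifnot(id_col %in% names(features))
  cols <- setdiff(names(features), id_col)
  for (cl in cols) {
    x <- features[[cl]]
    obs <- !is.na(x)
    n <- sum(obs)
    if (n == 0) stop("column is entirely missing: ", cl)
    r <- rank(x[obs], ties.method = "average")
    x[obs] <- stats::qnorm(r / (n + 1))
    features[[cl]] <- x
  }
  attr(features, "pd_normalized") <- TRUE
  features
}

is_normalized <- function(features) isTRUE(attr(features, "pd_normalized"))

#' Enumerate within-modality contrast pairs
#'
#' All unordered pairs of same-modality features, oriented so feature A
#' precedes feature B in registry order; no cross-modality or self
#' pairs. With the default registry this is choose(47, 2) = 1081
#' language pairs plus choose(44, 2) = 946 acoustic pairs, 2027 in all.
#'
#' @param registry A feature registry.
#' @return Tibble: `contrast` (key `"A - B"`), `feature_a`, `feature_b`,
#'   `modality`.
#' @export
contrast_pairs <- function(registry = feature_registry()) {
  validate_registry(registry)
  out <- lapply(c("language", "acoustic"), function(mod) {
    feats <- registry_features(registry, mod)
    if (length(feats) < 2) {
      return(tibble::tibble(
        contrast = character(), feature_a = character(),
        feature_b = character(), modality = character()
      ))
    }
    idx <- utils::combn(length(feats), 2)
    tibble::tibble(
      contrast = paste(feats[idx[1, ]], "-", feats[idx[2, ]]),
      feature_a = feats[idx[1, ]],
      feature_b = feats[idx[2, ]],
      modality = mod
    )
  })
  dplyr::bind_rows(out)
}

#' Build all within-modality pairwise contrasts
#'
#' For each same-modality feature pair (A, B) with A before B in
#' registry order, computes the per-participant difference of
#' quantile-normalized values A - B. A contrast value is missing
#' whenever either involved feature is missing for that participant:
#' imputed values are never used for contrasts, so rows with missing
#' tremor features simply drop out of contrast screens involving them.
#'
#' @param features A quantile-normalized feature tibble (from
#'   [quantile_normalize()]).
#' @param registry A feature registry matching the feature columns.
#' @param id_col Name of the id column.
#' @return Tibble: `participant_id` plus one column per contrast, keyed
#'   `"A - B"`; carries the `pd_normalized` attribute.
#' @export
build_contrasts <- function(features, registry = feature_registry(),
                            id_col = "participant_id") {
  if (!is_normalized(features)) {
    stop("build_contrasts requires a quantile-normalized feature table")
  }
  validate_registry(registry)
  missing_feats <- setdiff(registry$name, names(features))
  if (length(missing_feats) > 0) {
    stop(
      "feature table lacks registry feature(s): ",
      paste(utils::head(missing_feats, 5), collapse = "; ")
    )
  }
  pairs <- contrast_pairs(registry)
  mat <- as.matrix(features[, registry$name, drop = FALSE])
  vals <- mat[, pairs$feature_a, drop = FALSE] - mat[, pairs$feature_b, drop = FALSE]
  colnames(vals) <- pairs$contrast
  out <- dplyr::bind_cols(
    features[, id_col, drop = FALSE],
    tibble::as_tibble(vals)
  )
  attr(out, "pd_normalized") <- TRUE
  attr(out, "pd_contrast_pairs") <- pairs
  out
}
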