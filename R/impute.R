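#' Low-rank matrix completion by soft-thresholded SVD
#'
#' Fills missing entries of a numeric matrix by iterating: fill missing
#' entries with the current estimate (initially column means of observed
#' values), take the SVD, soft-threshold the singular values by
#' `lambda`, keep at most `rank_max` components, and refill. Converges
#' when the relative change of the completed matrix drops below `tol`.
#' This is the classic nuclear-norm-regularized completion scheme used
#' for sporadically missing feature panels.
#'
#' @param x Numeric matrix with `NA`s to complete.
#' @param rank_max Maximum rank retained.
#' @param lambda Soft-threshold on singular values (0 = plain truncated
#'   SVD refill).
#' @param tol Relative-change convergence tolerance.
#' @param maxit Maximum iterations.
#' @return The completed matrix (observed entries untouched).
#' @export
soft_impute_matrix <- function(x, rank_max = 5, lambda = 0, tol = 1e-4, maxit = 200) {
  stopifnot(is.matrix(x), is.numeric(x))
  miss <- is.na(x)
  if (!any(miss)) return(x)
  col_fill <- colMeans(x, na.rm = TRUE)
  col_fill[!is.finite(col_fill)] <- 0
  xf <- x
  for (j in seq_len(ncol(x))) xf[miss[, j], j] <- col_fill[j]
  # Warm-started rank escalation: run the refill iteration to
  # convergence at rank 1, then 2, ... up to rank_max. Starting each
  # rank from the previous solution keeps excess components from
  # locking in the initial column-mean fill (a failure mode of jumping
  # straight to the full rank).
  rank_max <- min(rank_max, nrow(x), ncol(x))
  for (k in seq_len(rank_max)) {
    for (it in seq_len(maxit)) {
      sv <- svd(xf)
      d <- pmax(sv$d - lambda, 0)
      kk <- min(k, sum(d > 0))
      if (kk == 0) {
        xhat <- matrix(0, nrow(x), ncol(x))
      } else {
        xhat <- sv$u[, seq_len(kk), drop = FALSE] %*%
          (d[seq_len(kk)] * t(sv$v[, seq_len(kk), drop = FALSE]))
      }
      new <- xf
      new[miss] <- xhat[miss]
      delta <- sqrt(sum((new - xf)^2)) / max(sqrt(sum(xf^2)), 1e-12)
      xf <- new
      if (delta < tol) break
    }
  }
  xf
}

#' Impute missing tremor features, separately per split
#'
#' Completes the feature matrix of a training split and (independently)
#' of a test split. Each split is imputed by a completion fit on that
#' split alone, so no information leaks across the train/test boundary:
#' perturbing test rows cannot change imputed training values. Missing
#' values must be confined to registry features flagged
#' `may_be_missing`. A column entirely missing within a split falls back
#' to 0 (the center of the normalized scale), with a message.
#'
#' @param train,test Feature tibbles (`participant_id` + feature
#'   columns). `test` may be `NULL`.
#' @param registry A feature registry matching the columns.
#' @param rank_max,lambda,tol,maxit Passed to [soft_impute_matrix()].
#' @param id_col Name of the id column.
#' @return List with completed `train` and `test` tibbles (no missing
#'   entries), each retaining any normalization flag.
#' @export
impute_split <- function(train, test = NULL, registry = feature_registry(),
                         rank_max = 5, lambda = 0, tol = 1e-4, maxit = 200,
                         id_col = "participant_id") {
  validate_registry(registry)
  complete_one <- function(tbl) {
    if (is.null(tbl)) return(NULL)
    feats <- intersect(registry$name, names(tbl))
    mat <- as.matrix(tbl[, feats, drop = FALSE])
    bad <- colSums(is.na(mat)) > 0 &
      !registry$may_be_missing[match(feats, registry$name)]
    if (any(bad)) {
      stop(
        "missing values outside may_be_missing features: ",
        paste(utils::head(feats[bad], 5), collapse = "; ")
      )
    }
    all_gone <- colSums(!is.na(mat)) == 0
    if (any(all_gone)) {
      message(
        "column(s) entirely missing in split, filled with 0: ",
        paste(feats[all_gone], collapse = ", ")
      )
      mat[, all_gone] <- 0
    }
    done <- soft_impute_matrix(mat,
      rank_max = rank_max, lambda = lambda,
      tol = tol, maxit = maxit
    )
    out <- tbl
    out[, feats] <- tibble::as_tibble(done)
    attr(out, "pd_normalized") <- attr(tbl, "pd_normalized")
    out
  }
  list(train = complete_one(train), test = complete_one(test))
}
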