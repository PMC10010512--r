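# Independent oracles used to validate the package's implementations.
# Each is written as directly as possible from the defining property,
# not by sharing code with the implementation under test.

# AUROC by explicit enumeration of all case-control pairs, ties 1/2.
brute_force_auroc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(cases) * length(controls))
}

# Content-unit mention scan: enumerate every candidate (start, form)
# window by direct string comparison, then resolve left to right taking
# the longest candidate at each position.
brute_force_mentions <- function(tokens, lexicon) {
  toks <- tolower(tokens)
  cand <- list()
  for (r in seq_len(nrow(lexicon))) {
    ft <- strsplit(lexicon$surface_form[r], " ", fixed = TRUE)[[1]]
    L <- length(ft)
    if (L > length(toks)) next
    for (i in seq_len(length(toks) - L + 1)) {
      if (paste(toks[i:(i + L - 1)], collapse = "\r") == paste(ft, collapse = "\r")) {
        cand[[length(cand) + 1]] <- data.frame(
          start = i, len = L,
          unit_id = lexicon$unit_id[r],
          relatedness = lexicon$relatedness[r],
          location = lexicon$location[r],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(
      start = integer(), len = integer(), unit_id = character(),
      relatedness = character(), location = character()
    ))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, -cand$len), ]
  out <- cand[0, ]
  pos <- 1
  while (pos <= length(toks)) {
    here <- cand[cand$start == pos, , drop = FALSE]
    if (nrow(here) == 0) {
      pos <- pos + 1
    } else {
      out <- rbind(out, here[1, ])
      pos <- pos + here$len[1]
    }
  }
  out
}

brute_force_count <- function(tokens, lexicon, relatedness = "any",
                              location = "any", distinct = FALSE) {
  m <- brute_force_mentions(tokens, lexicon)
  if (relatedness != "any") m <- m[m$relatedness == relatedness, , drop = FALSE]
  if (location != "any") m <- m[m$location == location, , drop = FALSE]
  if (distinct) length(unique(m$unit_id)) else nrow(m)
}

# Exhaustive threshold search: every midpoint plus +/-Inf, metrics from
# an explicit 2x2 table, feasibility and tie-breaks applied literally.
brute_force_threshold <- function(scores, labels, min_specificity = 0.85) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    if (spec < min_specificity) next
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    rec <- list(threshold = th, f1 = f1, specificity = spec)
    if (is.null(best) ||
      f1 > best$f1 ||
      (f1 == best$f1 && spec > best$specificity) ||
      (f1 == best$f1 && spec == best$specificity && th > best$threshold)) {
      best <- rec
    }
  }
  best
}

# Random token streams salted with lexicon words (including multi-token
# forms and their overlapping pieces) for scanner fuzzing.
random_transcript_tokens <- function(lexicon, n_tokens = 30) {
  pieces <- unique(unlist(strsplit(lexicon$surface_form, " ", fixed = TRUE)))
  vocab <- c(pieces, lexicon$surface_form, "the", "a", "and", "is", "was",
    "then", "next", "over", "xyz", "qrs")
  toks <- sample(vocab, n_tokens, replace = TRUE)
  # random capitalization exercises case-insensitivity
  caps <- runif(n_tokens) < 0.3
  toks[caps] <- toupper(toks[caps])
  unlist(strsplit(toks, " ", fixed = TRUE))
}

tokens_as_transcript <- function(tokens) {
  tibble::tibble(token = tokens, pos = "NN", sentence = 1L)
}

# Small two-group cohort helper used across screen/risk tests.
toy_labelled_data <- function(n1 = 60, n0 = 60, d = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- c(rep(1, n1), rep(0, n0))
    list(
      y = y,
      x = stats::rnorm(n1 + n0) + d * y,
      age = stats::rnorm(n1 + n0, 70, 5),
      gender = stats::rbinom(n1 + n0, 1, 0.5)
    )
  })
}
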