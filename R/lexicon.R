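#' Content-unit lexicons
#'
#' A content-unit lexicon maps surface forms that may appear in a
#' picture-description transcript to named content units, each labelled
#' with whether it is related to the depicted scenario and with the side
#' of the picture it occupies (`left`, `right`, or `both` for units such
#' as "kitchen" that are not localized to one side). Scoring functions
#' are parameterized over the lexicon, so a study can substitute its own
#' unit list without touching the code.
#'
#' @name lexicon
NULL

#' Build a content-unit lexicon from a tibble of entries
#'
#' @param entries A data frame with columns `unit_id`, `surface_form`
#'   (one row per surface form), `relatedness` (`"related"`/`"unrelated"`)
#'   and `location` (`"left"`/`"right"`/`"both"`).
#' @return A validated tibble of class `pd_lexicon`.
#' @export
content_unit_lexicon <- function(entries) {
  lex <- tibble::as_tibble(entries)
  req <- c("unit_id", "surface_form", "relatedness", "location")
  missing_cols <- setdiff(req, names(lex))
  if (length(missing_cols) > 0) {
    stop("lexicon lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  lex$surface_form <- tolower(lex$surface_form)
  if (any(!nzchar(lex$surface_form))) stop("empty surface forms are not allowed")
  if (!all(lex$relatedness %in% c("related", "unrelated"))) {
    stop("relatedness must be 'related' or 'unrelated'")
  }
  if (!all(lex$location %in% c("left", "right", "both"))) {
    stop("location must be 'left', 'right' or 'both'")
  }
  # one surface form must resolve to exactly one unit
  dup <- lex |>
    dplyr::distinct(.data$surface_form, .data$unit_id) |>
    dplyr::count(.data$surface_form) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(
      "surface form(s) mapped to more than one unit_id: ",
      paste(dup$surface_form, collapse = ", ")
    )
  }
  # unit attributes must be consistent across its surface forms
  incons <- lex |>
    dplyr::distinct(.data$unit_id, .data$relatedness, .data$location) |>
    dplyr::count(.data$unit_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(incons) > 0) {
    stop(
      "unit_id(s) with inconsistent relatedness/location: ",
      paste(incons$unit_id, collapse = ", ")
    )
  }
  lex <- dplyr::distinct(lex)
  class(lex) <- c("pd_lexicon", class(lex))
  lex
}

#' Read a content-unit lexicon from JSON
#'
#' The JSON schema is a list of entries, each with `unit_id`,
#' `surface_forms` (array), `relatedness` and `location`; see the file
#' shipped at `system.file("extdata", "cookie_theft_lexicon.json",
#' package = "pdscreen")`.
#'
#' @param path Path to a lexicon JSON file.
#' @return A `pd_lexicon` tibble (one row per surface form).
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  entries <- purrr::map_dfr(raw$entries, function(e) {
    tibble::tibble(
      unit_id = e$unit_id,
      surface_form = unlist(e$surface_forms),
      relatedness = e$relatedness,
      location = e$location
    )
  })
  content_unit_lexicon(entries)
}

#' The default Cookie Theft lexicon
#'
#' Package default enumerating the standard objects, actors and actions
#' of the Cookie Theft scene plus a few off-topic distractor units; the
#' study-specific list this stands in for is not public. Editable: copy
#' the JSON, modify, and load with [read_lexicon()].
#'
#' @return A `pd_lexicon` tibble.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "cookie_theft_lexicon.json",
    package = "pdscreen",
    mustWork = TRUE
  ))
}
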