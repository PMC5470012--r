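#' Activity catalogs
#'
#' An activity catalog maps each reportable activity code to its MET
#' (metabolic equivalent of task) values. Three kinds of activity are
#' supported:
#'
#' * **simple** activities carry a single MET value (`met_none`);
#' * **effort-ranked** activities carry one MET value per effort level
#'   (`met_light`, `met_medium`, `met_hard`), monotone nondecreasing;
#' * **posture-adjustable** activities carry sitting and standing MET values
#'   (`met_sitting`, `met_standing`) combined linearly by the reported
#'   standing fraction.
#'
#' Each activity belongs to one of 13 broad categories (sleeping/reclining,
#' personal care, food, transportation, household, occupation, shopping,
#' leisure, sports, social, outdoor, lawn/garden, miscellaneous).
#'
#' The CSV dialect is
#' `code,name,category,met_none,met_light,met_medium,met_hard,met_sitting,met_standing`
#' with UTF-8 encoding, a header row, and empty cells meaning "absent".
#'
#' `demo_catalog()` ships a reduced demonstration catalog of 34 activities
#' spanning all 13 categories, with MET values taken from the public
#' Ainsworth compendium of physical activities. It is fixture data for
#' examples, simulation, and tests — not a complete instrument catalog;
#' any user catalog in the documented CSV dialect is accepted.
#'
#' @param path Path to a catalog CSV file.
#' @param x A data frame with the catalog columns.
#' @return A tibble of class `par24_catalog`, one row per activity.
#' @examples
#' catalog <- demo_catalog()
#' dplyr::count(catalog, category)
#' @name catalog
NULL

catalog_columns <- c(
  "code", "name", "category", "met_none", "met_light", "met_medium",
  "met_hard", "met_sitting", "met_standing"
)

#' @rdname catalog
#' @export
read_activity_catalog <- function(path) {
  if (!file.exists(path)) {
    stop_par24(paste0("catalog file not found: ", path), "par24_format_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_character(),
      name = readr::col_character(),
      category = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  as_activity_catalog(df)
}

#' @rdname catalog
#' @export
as_activity_catalog <- function(x) {
  df <- as_tibble(x)
  missing_cols <- setdiff(catalog_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_par24(
      paste0("catalog is missing columns: ", paste(missing_cols, collapse = ", ")),
      "par24_format_error"
    )
  }
  df <- df[catalog_columns]
  if (nrow(df) == 0) {
    stop_par24("catalog is empty", "par24_format_error")
  }
  if (anyNA(df$code) || any(df$code == "")) {
    stop_par24(
      paste0("missing activity code in row(s) ",
             paste(which(is.na(df$code) | df$code == ""), collapse = ", ")),
      "par24_format_error"
    )
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0) {
    stop_par24(
      paste0("duplicate activity code(s): ", paste(unique(dup), collapse = ", "),
             " (rows ", paste(which(df$code %in% dup), collapse = ", "), ")"),
      "par24_format_error"
    )
  }
  bad_cat <- !is_whole(df$category) | df$category < 1 | df$category > 13
  if (any(bad_cat)) {
    stop_par24(
      paste0("category must be an integer in 1..13; offending code(s): ",
             paste(df$code[bad_cat], collapse = ", ")),
      "par24_validation_error"
    )
  }
  met_cols <- c("met_none", "met_light", "met_medium", "met_hard",
                "met_sitting", "met_standing")
  for (col in met_cols) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stop_par24(
        paste0("non-positive MET in column ", col, " for code(s): ",
               paste(df$code[bad], collapse = ", ")),
        "par24_validation_error"
      )
    }
  }
  has_effort <- !is.na(df$met_light) | !is.na(df$met_medium) | !is.na(df$met_hard)
  full_effort <- !is.na(df$met_light) & !is.na(df$met_medium) & !is.na(df$met_hard)
  if (any(has_effort & !full_effort)) {
    stop_par24(
      paste0("effort-ranked activities need all of met_light, met_medium, met_hard; ",
             "offending code(s): ", paste(df$code[has_effort & !full_effort], collapse = ", ")),
      "par24_validation_error"
    )
  }
  has_posture <- !is.na(df$met_sitting) | !is.na(df$met_standing)
  full_posture <- !is.na(df$met_sitting) & !is.na(df$met_standing)
  if (any(has_posture & !full_posture)) {
    stop_par24(
      paste0("posture-adjustable activities need both met_sitting and met_standing; ",
             "offending code(s): ", paste(df$code[has_posture & !full_posture], collapse = ", ")),
      "par24_validation_error"
    )
  }
  kinds <- (!is.na(df$met_none)) + full_effort + full_posture
  if (any(kinds != 1L)) {
    stop_par24(
      paste0("each activity must be exactly one of simple (met_none), ",
             "effort-ranked, or posture-adjustable; offending code(s): ",
             paste(df$code[kinds != 1L], collapse = ", ")),
      "par24_validation_error"
    )
  }
  non_mono <- full_effort & (df$met_medium < df$met_light | df$met_hard < df$met_medium)
  if (any(non_mono)) {
    stop_par24(
      paste0("effort MET values must be nondecreasing light <= medium <= hard; ",
             "offending code(s): ", paste(df$code[non_mono], collapse = ", ")),
      "par24_validation_error"
    )
  }
  class(df) <- c("par24_catalog", class(df))
  df
}

#' @rdname catalog
#' @param catalog A `par24_catalog`.
#' @export
write_activity_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "par24_catalog"))
  readr::write_csv(as_tibble(catalog)[catalog_columns], path, na = "")
  invisible(path)
}

#' @rdname catalog
#' @export
demo_catalog <- function() {
  read_activity_catalog(
    system.file("extdata", "activity_catalog_demo.csv", package = "par24",
                mustWork = TRUE)
  )
}

#' MET value of a diary entry
#'
#' Resolves the MET value of a reported activity given its optional effort
#' level and standing fraction. Effort must be supplied exactly for
#' effort-ranked activities; the standing fraction exactly for
#' posture-adjustable ones, whose MET is the time-weighted average
#' `standing_fraction * met_standing + (1 - standing_fraction) * met_sitting`.
#'
#' @param catalog A `par24_catalog`.
#' @param code Character vector of activity codes.
#' @param effort Character vector: `"light"`, `"medium"`, `"hard"`, or `NA`
#'   for activities that are not effort-ranked. Recycled against `code`.
#' @param standing_fraction Numeric vector in `[0, 1]`, or `NA` for activities
#'   that are not posture-adjustable. Recycled against `code`.
#' @return Numeric vector of MET values.
#' @examples
#' catalog <- demo_catalog()
#' met_for_entry(catalog, "DSK1", standing_fraction = 0.5)
#' @export
met_for_entry <- function(catalog, code, effort = NA_character_,
                          standing_fraction = NA_real_) {
  stopifnot(inherits(catalog, "par24_catalog"))
  args <- recycle_common(as.character(code), as.character(effort),
                         as.numeric(standing_fraction))
  code <- args[[1]]; effort <- args[[2]]; sf <- args[[3]]

  idx <- match(code, catalog$code)
  if (anyNA(idx)) {
    stop_par24(
      paste0("unknown activity code(s): ",
             paste(unique(code[is.na(idx)]), collapse = ", ")),
      "par24_validation_error"
    )
  }
  def <- catalog[idx, ]
  ranked <- !is.na(def$met_light)
  posture <- !is.na(def$met_sitting)

  if (any(!is.na(effort) & !effort %in% effort_levels)) {
    stop_par24("effort must be one of light, medium, hard", "par24_validation_error")
  }
  if (any(ranked & is.na(effort))) {
    stop_par24(
      paste0("effort level required for effort-ranked code(s): ",
             paste(unique(code[ranked & is.na(effort)]), collapse = ", ")),
      "par24_contract_error"
    )
  }
  if (any(!ranked & !is.na(effort))) {
    stop_par24(
      paste0("effort level given for non-effort-ranked code(s): ",
             paste(unique(code[!ranked & !is.na(effort)]), collapse = ", ")),
      "par24_contract_error"
    )
  }
  if (any(posture & is.na(sf))) {
    stop_par24(
      paste0("standing_fraction required for posture-adjustable code(s): ",
             paste(unique(code[posture & is.na(sf)]), collapse = ", ")),
      "par24_contract_error"
    )
  }
  if (any(!posture & !is.na(sf))) {
    stop_par24(
      paste0("standing_fraction given for non-posture-adjustable code(s): ",
             paste(unique(code[!posture & !is.na(sf)]), collapse = ", ")),
      "par24_contract_error"
    )
  }
  if (any(!is.na(sf) & (sf < 0 | sf > 1))) {
    stop_par24("standing_fraction must lie in [0, 1]", "par24_validation_error")
  }

  met <- def$met_none
  if (any(ranked)) {
    eff_col <- c(light = "met_light", medium = "met_medium", hard = "met_hard")
    met[ranked] <- vapply(which(ranked), function(i) {
      def[[eff_col[[effort[i]]]]][i]
    }, numeric(1))
  }
  met[posture] <- sf[posture] * def$met_standing[posture] +
    (1 - sf[posture]) * def$met_sitting[posture]
  met
}
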