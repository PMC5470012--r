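#' 24-hour activity diaries
#'
#' A diary day is the ordered set of timed activity entries a participant
#' reports for one midnight-to-midnight period. Entries live on a 5-minute
#' grid of half-open intervals `[start_min, end_min)` with 0-based minutes
#' since midnight; a valid day covers all 1440 minutes with at most two
#' concurrent activities at any minute.
#'
#' The CSV dialect is
#' `participant_id,recall_index,code,start_min,end_min,effort,standing_pct`
#' with one row per entry; `standing_pct` is an integer 0-100 and empty cells
#' mean "absent". `read_diary_csv()` converts `standing_pct` to the
#' `standing_fraction` column in `[0, 1]` used throughout the package.
#'
#' @param path Path to a diary CSV file.
#' @return `read_diary_csv()` returns a tibble with columns `participant_id`,
#'   `recall_index`, `code`, `start_min`, `end_min`, `effort`,
#'   `standing_fraction`.
#' @name diary
NULL

#' @rdname diary
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) {
    stop_par24(paste0("diary file not found: ", path), "par24_format_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      recall_index = readr::col_integer(),
      code = readr::col_character(),
      start_min = readr::col_integer(),
      end_min = readr::col_integer(),
      effort = readr::col_character(),
      standing_pct = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("participant_id", "recall_index", "code", "start_min",
                "end_min", "effort", "standing_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_par24(
      paste0("diary is missing columns: ", paste(missing_cols, collapse = ", ")),
      "par24_format_error"
    )
  }
  if (any(!is.na(df$standing_pct) & (df$standing_pct < 0 | df$standing_pct > 100))) {
    stop_par24("standing_pct must lie in 0..100", "par24_validation_error")
  }
  df$standing_fraction <- df$standing_pct / 100
  df$standing_pct <- NULL
  df
}

#' @rdname diary
#' @param diary A tibble of diary entries (one or many participant-days).
#' @export
write_diary_csv <- function(diary, path) {
  out <- dplyr::mutate(
    diary,
    standing_pct = ifelse(is.na(.data$standing_fraction), NA_real_,
                          round(100 * .data$standing_fraction))
  )
  out <- out[c("participant_id", "recall_index", "code", "start_min",
               "end_min", "effort", "standing_pct")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validate one diary day
#'
#' Checks a single participant-day of entries against the diary contract:
#' entries on the 5-minute grid with bouts of at least 5 minutes, all codes
#' known to the catalog, full coverage of the 1440-minute day, and never
#' more than two concurrent activities. Violations are returned as data, one
#' row each, so callers can report them; an empty result means the day is
#' valid and scorable.
#'
#' @param entries Tibble of entries for one participant-day (columns `code`,
#'   `start_min`, `end_min`, plus optionally `effort`, `standing_fraction`).
#' @param catalog A `par24_catalog`.
#' @return A tibble with columns `kind` (one of `"unknown_code"`,
#'   `"bad_interval"`, `"granularity"`, `"gap"`, `"overlap"`), `start_min`,
#'   `end_min`, and `detail`; zero rows iff the day is valid.
#' @examples
#' catalog <- demo_catalog()
#' day <- tibble::tibble(code = "SLP1", start_min = 0, end_min = 1440)
#' validate_diary(day, catalog)
#' @export
validate_diary <- function(entries, catalog) {
  stopifnot(inherits(catalog, "par24_catalog"))
  v <- list()
  viol <- function(kind, start_min, end_min, detail) {
    tibble(kind = kind, start_min = as.integer(start_min),
           end_min = as.integer(end_min), detail = detail)
  }

  unknown <- !entries$code %in% catalog$code
  if (any(unknown)) {
    v <- c(v, Map(function(code, s, e) {
      viol("unknown_code", s, e, paste0("code not in catalog: ", code))
    }, entries$code[unknown], entries$start_min[unknown], entries$end_min[unknown]))
  }

  bad_order <- !is_whole(entries$start_min) | !is_whole(entries$end_min) |
    entries$start_min < 0 | entries$end_min > 1440 |
    entries$start_min >= entries$end_min
  if (any(bad_order)) {
    v <- c(v, Map(function(s, e) {
      viol("bad_interval", s, e, "need 0 <= start_min < end_min <= 1440")
    }, entries$start_min[bad_order], entries$end_min[bad_order]))
  }

  off_grid <- !bad_order &
    (entries$start_min %% 5 != 0 | entries$end_min %% 5 != 0 |
       entries$end_min - entries$start_min < 5)
  if (any(off_grid)) {
    v <- c(v, Map(function(s, e) {
      viol("granularity", s, e,
           "entries must lie on the 5-min grid with bouts of >= 5 min")
    }, entries$start_min[off_grid], entries$end_min[off_grid]))
  }

  # Coverage is assessed from the well-formed intervals only.
  ok <- !bad_order
  cover <- integer(1440)
  for (i in which(ok)) {
    idx <- (entries$start_min[i] + 1):entries$end_min[i]
    cover[idx] <- cover[idx] + 1L
  }
  for (seg in split_segments(cover == 0)) {
    v <- c(v, list(viol("gap", seg[1], seg[2],
                        sprintf("no activity covers [%d,%d)", seg[1], seg[2]))))
  }
  for (seg in split_segments(cover > 2)) {
    v <- c(v, list(viol("overlap", seg[1], seg[2],
                        sprintf("more than 2 concurrent activities on [%d,%d)",
                                seg[1], seg[2]))))
  }

  if (length(v) == 0) {
    return(tibble(kind = character(), start_min = integer(),
                  end_min = integer(), detail = character()))
  }
  dplyr::bind_rows(v)
}

# Runs of TRUE in a logical vector over minutes 0..1439, as [start, end) pairs.
split_segments <- function(flag) {
  segs <- rle_segments(flag)
  segs <- segs[segs$value, , drop = FALSE]
  if (nrow(segs) == 0) return(list())
  lapply(seq_len(nrow(segs)), function(i) c(segs$start[i], segs$end[i]))
}

#' Minute-level MET profile of a diary day
#'
#' Expands a valid diary day into 1440 per-minute MET values. Each minute
#' takes the MET of its covering entry; where two activities were reported
#' concurrently the per-minute MET is the maximum of the two by default
#' (the dominant activity determines intensity), or their mean under
#' `overlap_rule = "mean"`.
#'
#' @inheritParams validate_diary
#' @param overlap_rule How to combine two concurrent activities: `"max"`
#'   (default) or `"mean"`.
#' @return Numeric vector of length 1440, minutes 0-1439 since midnight.
#' @examples
#' catalog <- demo_catalog()
#' day <- tibble::tibble(code = c("SLP1", "DSK1"),
#'                       start_min = c(0, 480), end_min = c(480, 1440),
#'                       standing_fraction = c(NA, 0.25))
#' profile <- minute_met_profile(day, catalog)
#' table(classify_met(profile))
#' @export
minute_met_profile <- function(entries, catalog, overlap_rule = c("max", "mean")) {
  overlap_rule <- match.arg(overlap_rule)
  violations <- validate_diary(entries, catalog)
  if (nrow(violations) > 0) {
    stop_par24(
      paste0("diary day fails validation (", nrow(violations),
             " violation(s)); run validate_diary() and fix the entries first"),
      "par24_contract_error"
    )
  }
  if (!"effort" %in% names(entries)) entries$effort <- NA_character_
  if (!"standing_fraction" %in% names(entries)) entries$standing_fraction <- NA_real_
  mets <- met_for_entry(catalog, entries$code, entries$effort,
                        entries$standing_fraction)

  if (overlap_rule == "max") {
    profile <- rep(-Inf, 1440)
    for (i in seq_len(nrow(entries))) {
      idx <- (entries$start_min[i] + 1):entries$end_min[i]
      profile[idx] <- pmax(profile[idx], mets[i])
    }
  } else {
    total <- numeric(1440)
    cover <- integer(1440)
    for (i in seq_len(nrow(entries))) {
      idx <- (entries$start_min[i] + 1):entries$end_min[i]
      total[idx] <- total[idx] + mets[i]
      cover[idx] <- cover[idx] + 1L
    }
    profile <- total / cover
  }
  profile
}

#' Classify MET values into intensity classes
#'
#' Applies the MET intensity boundaries: sedentary for MET <= 1.5, light for
#' 1.5 < MET < 3.0, and moderate-to-vigorous (MVPA) for MET >= 3.0. The
#' sedentary boundary is inclusive of 1.5.
#'
#' @param met Numeric vector of positive MET values.
#' @return Factor with levels `sedentary`, `light`, `mvpa`.
#' @examples
#' classify_met(c(1.5, 2, 3))
#' @export
classify_met <- function(met) {
  if (any(!is.finite(met) | met <= 0)) {
    stop_par24("MET values must be positive and finite", "par24_validation_error")
  }
  # sedentary boundary is inclusive: MET <= 1.5 sedentary, >= 3.0 MVPA
  factor(
    ifelse(met <= 1.5, "sedentary", ifelse(met < 3, "light", "mvpa")),
    levels = intensity_levels
  )
}

#' Intensity summary of a minute-level MET profile
#'
#' Reduces a 1440-minute MET profile to total minutes spent sedentary, in
#' light activity, and in MVPA, plus the 24-h average MET.
#'
#' @param profile Numeric vector of 1440 positive MET values, as returned by
#'   [minute_met_profile()].
#' @return One-row tibble with columns `sedentary_min`, `light_min`,
#'   `mvpa_min`, `avg_met`, `included_min` (always 1440 for diaries).
#' @export
diary_summary <- function(profile) {
  if (length(profile) != 1440) {
    stop_par24("a diary MET profile must have exactly 1440 values",
               "par24_contract_error")
  }
  cls <- classify_met(profile)
  tibble(
    sedentary_min = sum(cls == "sedentary"),
    light_min = sum(cls == "light"),
    mvpa_min = sum(cls == "mvpa"),
    avg_met = mean(profile),
    included_min = 1440L
  )
}

#' Score a multi-participant diary table
#'
#' Convenience wrapper: validates and scores every participant-day (grouped
#' by `participant_id` and `recall_index`) in a diary table. Days that fail
#' validation are not scored; they are returned in the `invalid` component
#' with their violations.
#'
#' @param diary Tibble of diary entries as returned by [read_diary_csv()].
#' @param catalog A `par24_catalog`.
#' @inheritParams minute_met_profile
#' @return A list with `summaries` (tibble: `participant_id`, `recall_index`,
#'   intensity summary columns) and `invalid` (tibble of violations with
#'   `participant_id`, `recall_index`).
#' @export
score_diary <- function(diary, catalog, overlap_rule = c("max", "mean")) {
  overlap_rule <- match.arg(overlap_rule)
  days <- dplyr::group_split(dplyr::group_by(diary, .data$participant_id,
                                             .data$recall_index))
  res <- purrr::map(days, function(day) {
    key <- day[1, c("participant_id", "recall_index")]
    violations <- validate_diary(day, catalog)
    if (nrow(violations) > 0) {
      return(list(summary = NULL, invalid = dplyr::bind_cols(key, violations)))
    }
    profile <- minute_met_profile(day, catalog, overlap_rule)
    list(summary = dplyr::bind_cols(key, diary_summary(profile)), invalid = NULL)
  })
  list(
    summaries = dplyr::bind_rows(purrr::map(res, "summary")),
    invalid = dplyr::bind_rows(purrr::map(res, "invalid"))
  )
}
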