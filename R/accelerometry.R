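#' Accelerometer count series
#'
#' Epoch-level activity counts from a waist-worn accelerometer, reduced to
#' counts per minute (cpm) over the recall day and classified into intensity
#' minutes with the Freedson/Matthews cut-points. The counts column is
#' interpreted as vertical-axis counts, the convention under which those
#' cut-points were derived.
#'
#' The CSV dialect is
#' `participant_id,timestamp_iso8601,epoch_seconds,counts,wear` with rows
#' time-ordered and contiguous within each participant, a constant epoch
#' length throughout the file, nonnegative integer counts, and `wear` in
#' `{0, 1}`. Wear flags are an input (the study design collected
#' participant-reported wear interruptions rather than applying a detection
#' algorithm); [detect_nonwear()] offers an optional convenience detector.
#'
#' @param path Path to a counts CSV file.
#' @return `read_counts_csv()` returns a tibble of class `par24_counts` with
#'   columns `participant_id`, `time` (POSIXct, UTC), `epoch_seconds`,
#'   `counts`, `wear` (logical).
#' @name counts
NULL

#' @rdname counts
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) {
    stop_par24(paste0("counts file not found: ", path), "par24_format_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp_iso8601 = readr::col_datetime(),
      epoch_seconds = readr::col_integer(),
      counts = readr::col_double(),
      wear = readr::col_integer()
    ),
    progress = FALSE
  )
  required <- c("participant_id", "timestamp_iso8601", "epoch_seconds",
                "counts", "wear")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_par24(
      paste0("counts file is missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "par24_format_error"
    )
  }
  df <- tibble(
    participant_id = df$participant_id,
    time = df$timestamp_iso8601,
    epoch_seconds = df$epoch_seconds,
    counts = df$counts,
    wear = df$wear == 1L
  )
  as_count_series(df)
}

#' @rdname counts
#' @param x A data frame with the count-series columns.
#' @export
as_count_series <- function(x) {
  df <- as_tibble(x)
  if (nrow(df) > 0) {
    ep <- unique(df$epoch_seconds)
    if (length(ep) != 1) {
      stop_par24("mixed epoch lengths in one series", "par24_format_error")
    }
    if (!ep %in% c(1L, 5L, 10L, 15L, 30L, 60L)) {
      stop_par24("epoch_seconds must be one of 1, 5, 10, 15, 30, 60",
                 "par24_format_error")
    }
    bad <- !is_whole(df$counts) | df$counts < 0
    if (any(bad)) {
      stop_par24(
        paste0("counts must be nonnegative integers; offending row(s): ",
               paste(utils::head(which(bad), 5), collapse = ", ")),
        "par24_format_error"
      )
    }
    if (anyNA(df$time)) {
      stop_par24("unparseable timestamp(s) in counts file", "par24_format_error")
    }
    for (pid in unique(df$participant_id)) {
      tt <- df$time[df$participant_id == pid]
      dt <- as.numeric(diff(tt), units = "secs")
      gap <- which(abs(dt - ep) > 1e-6)
      if (length(gap) > 0) {
        stop_par24(
          sprintf("gap or disorder in epoch sequence for participant %s after %s",
                  pid, format(tt[gap[1]], "%Y-%m-%d %H:%M:%S")),
          "par24_format_error"
        )
      }
    }
  }
  class(df) <- c("par24_counts", class(df))
  df
}

#' @rdname counts
#' @param series A `par24_counts` tibble.
#' @export
write_counts_csv <- function(series, path) {
  out <- tibble(
    participant_id = series$participant_id,
    timestamp_iso8601 = format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    epoch_seconds = series$epoch_seconds,
    counts = series$counts,
    wear = as.integer(series$wear)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Reduce epoch counts to counts per minute over the recall day
#'
#' Sums epoch counts within each of the 1440 minutes of the recall day. A
#' minute containing any non-wear epoch is wholly non-wear (its cpm is `NA`),
#' avoiding partial-minute count inflation. The recall day is selected by
#' explicit date, never inferred: only epochs in `[recall_date 00:00,
#' next midnight)` are used, and each participant must have the complete
#' 24-h window.
#'
#' @param series A `par24_counts` tibble (one or many participants).
#' @param recall_date The recall day as `Date` or `"YYYY-MM-DD"`. If `NULL`,
#'   the series must span exactly one full day per participant.
#' @return Tibble with columns `participant_id`, `minute` (0-1439), `cpm`
#'   (`NA` for non-wear minutes), `wear` (logical).
#' @export
to_minute_counts <- function(series, recall_date = NULL) {
  stopifnot(inherits(series, "par24_counts"))
  ep <- unique(series$epoch_seconds)
  per_min <- 60L / ep
  out <- lapply(split(seq_len(nrow(series)), series$participant_id), function(idx) {
    df <- series[idx, ]
    if (is.null(recall_date)) {
      day0 <- as.POSIXct(format(df$time[1], "%Y-%m-%d"), tz = "UTC")
    } else {
      day0 <- as.POSIXct(paste0(as.character(as.Date(recall_date)), " 00:00:00"),
                         tz = "UTC")
    }
    sec <- as.numeric(difftime(df$time, day0, units = "secs"))
    in_day <- sec >= 0 & sec < 86400
    if (sum(in_day) != 86400 / ep) {
      stop_par24(
        sprintf("participant %s: recall day %s has %d epochs, expected %d",
                df$participant_id[1], format(day0, "%Y-%m-%d"),
                sum(in_day), 86400 %/% ep),
        "par24_format_error"
      )
    }
    df <- df[in_day, ]
    minute <- as.integer(sec[in_day] %/% 60)
    cpm <- as.vector(tapply(df$counts, minute, sum))
    wear_min <- as.vector(tapply(df$wear, minute, all))
    tibble(
      participant_id = df$participant_id[1],
      minute = 0:1439,
      cpm = ifelse(wear_min, cpm, NA_real_),
      wear = wear_min
    )
  })
  dplyr::bind_rows(out)
}

#' Classify counts per minute into intensity classes
#'
#' Applies the Freedson/Matthews cut-points: sedentary below 100 cpm, light
#' for 100-1951 cpm, and moderate-to-vigorous (MVPA) at or above 1952 cpm.
#'
#' @param cpm Numeric vector of nonnegative counts per minute.
#' @return Factor with levels `sedentary`, `light`, `mvpa`; `NA` in gives
#'   `NA` out.
#' @examples
#' classify_cpm(c(99, 100, 1951, 1952))
#' @export
classify_cpm <- function(cpm) {
  if (any(cpm < 0, na.rm = TRUE)) {
    stop_par24("counts per minute must be nonnegative", "par24_validation_error")
  }
  factor(
    ifelse(cpm < 100, "sedentary", ifelse(cpm < 1952, "light", "mvpa")),
    levels = intensity_levels
  )
}

#' Wear-time inclusion rule
#'
#' A recall day is analysable only if the device was worn at least half of
#' it: days with fewer than 720 wear minutes (12 h) are excluded.
#'
#' @param minutes Minute-counts tibble from [to_minute_counts()].
#' @return Tibble with one row per participant: `participant_id`,
#'   `wear_minutes`, `keep` (logical).
#' @export
wear_time_filter <- function(minutes) {
  out <- dplyr::summarise(
    dplyr::group_by(minutes, .data$participant_id),
    wear_minutes = sum(.data$wear),
    .groups = "drop"
  )
  out$keep <- out$wear_minutes >= 720L
  out
}

#' Intensity summary of an accelerometer recall day
#'
#' Counts sedentary, light, and MVPA minutes over the wear minutes of each
#' kept participant-day. Counts are never converted to MET, so `avg_met` is
#' `NA` in accelerometer summaries; `included_min` is the number of wear
#' minutes.
#'
#' @param minutes Minute-counts tibble from [to_minute_counts()]; every
#'   participant must pass [wear_time_filter()] (contract error otherwise).
#' @return Tibble with one row per participant: `participant_id`,
#'   `sedentary_min`, `light_min`, `mvpa_min`, `avg_met` (`NA`),
#'   `included_min`.
#' @export
accelerometer_summary <- function(minutes) {
  wf <- wear_time_filter(minutes)
  if (any(!wf$keep)) {
    stop_par24(
      paste0("accelerometer_summary called on wear-excluded participant(s): ",
             paste(wf$participant_id[!wf$keep], collapse = ", "),
             "; apply wear_time_filter() first"),
      "par24_contract_error"
    )
  }
  worn <- dplyr::filter(minutes, .data$wear)
  worn$class <- classify_cpm(worn$cpm)
  dplyr::summarise(
    dplyr::group_by(worn, .data$participant_id),
    sedentary_min = sum(.data$class == "sedentary"),
    light_min = sum(.data$class == "light"),
    mvpa_min = sum(.data$class == "mvpa"),
    avg_met = NA_real_,
    included_min = dplyr::n(),
    .groups = "drop"
  )
}

#' Optional non-wear detector
#'
#' Flags runs of at least `min_run` consecutive zero-cpm minutes as
#' non-wear. The study design this package supports records wear
#' interruptions as reported by participants, so detection is off by
#' default and provided only as a convenience for data lacking wear flags.
#'
#' @param minutes Minute-counts tibble from [to_minute_counts()].
#' @param min_run Minimum length (minutes) of a zero run flagged as
#'   non-wear; default 60.
#' @return The input with `wear` set to `FALSE` (and `cpm` to `NA`) on
#'   detected non-wear runs.
#' @export
detect_nonwear <- function(minutes, min_run = 60L) {
  out <- lapply(split(minutes, minutes$participant_id), function(df) {
    df <- df[order(df$minute), ]
    zero <- !is.na(df$cpm) & df$cpm == 0
    segs <- rle_segments(zero)
    for (i in which(segs$value & (segs$end - segs$start) >= min_run)) {
      idx <- (segs$start[i] + 1):segs$end[i]
      df$wear[idx] <- FALSE
      df$cpm[idx] <- NA_real_
    }
    df
  })
  dplyr::bind_rows(out)
}
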