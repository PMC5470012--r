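#' Validity study: diary versus accelerometer
#'
#' Runs the full concurrent-validity analysis: scores every diary
#' (recall 1) into intensity minutes, reduces every accelerometer stream to
#' counts-per-minute intensity minutes over the recall day, applies the
#' 12-h wear-time rule, matches participants across the two methods and the
#' covariate table, and computes the agreement analysis per intensity class
#' overall and within age, gender, and BMI strata, with a between-strata
#' rank-sum test per stratifier. Differences are diary minus accelerometer.
#'
#' Every input participant ends up either in the report or in the exclusion
#' log with a reason (invalid diary, wear-time exclusion with the wear
#' minutes, or missing counterpart); participants missing covariates are
#' retained in the overall block and dropped from stratified blocks only.
#'
#' @param diaries Diary entries tibble ([read_diary_csv()] layout); recall 1
#'   is used.
#' @param counts A `par24_counts` tibble.
#' @param covariates Tibble `participant_id, age_years, gender, bmi`.
#' @param catalog A `par24_catalog`.
#' @param recall_date Recall day passed to [to_minute_counts()].
#' @param overlap_rule Concurrent-activity rule for diary scoring.
#' @param denominator Percent-difference denominator rule.
#' @return An object of class `par24_report`: list with `study`, `results`
#'   (tibble: one row per quantity x stratum), `pairs` (the matched paired
#'   observations), `exclusions` (tibble `participant_id, reason, detail`),
#'   and `notes` (stratified blocks that could not be analysed — a stratum
#'   under three participants or a constant measurement — with the reason).
#'   Use [generics::tidy()] to get the results tibble.
#' @export
run_validity_study <- function(diaries, counts, covariates, catalog,
                               recall_date = NULL,
                               overlap_rule = c("max", "mean"),
                               denominator = c("per_pair", "pooled_median")) {
  overlap_rule <- match.arg(overlap_rule)
  denominator <- match.arg(denominator)
  exclusions <- list()

  d1 <- dplyr::filter(diaries, .data$recall_index == 1L)
  scored <- score_diary(d1, catalog, overlap_rule)
  if (nrow(scored$invalid) > 0) {
    bad <- unique(scored$invalid$participant_id)
    exclusions <- c(exclusions, list(tibble(
      participant_id = bad, reason = "invalid_diary",
      detail = vapply(bad, function(p) {
        v <- scored$invalid[scored$invalid$participant_id == p, ]
        paste0(nrow(v), " violation(s), first: ", v$detail[1])
      }, character(1))
    )))
  }
  diary_sum <- scored$summaries

  minutes <- to_minute_counts(counts, recall_date)
  wf <- wear_time_filter(minutes)
  if (any(!wf$keep)) {
    drop <- wf[!wf$keep, ]
    exclusions <- c(exclusions, list(tibble(
      participant_id = drop$participant_id, reason = "wear_time",
      detail = sprintf("only %d wear minutes (< 720)", drop$wear_minutes)
    )))
  }
  kept <- dplyr::semi_join(minutes, dplyr::filter(wf, .data$keep),
                           by = "participant_id")
  accel_sum <- if (nrow(kept) > 0) accelerometer_summary(kept) else
    tibble(participant_id = character(), sedentary_min = integer(),
           light_min = integer(), mvpa_min = integer(), avg_met = double(),
           included_min = integer())

  matched <- intersect(diary_sum$participant_id, accel_sum$participant_id)
  already_logged <- unlist(lapply(exclusions, function(e) e$participant_id))
  only_diary <- setdiff(setdiff(diary_sum$participant_id, matched),
                        already_logged)
  only_accel <- setdiff(setdiff(accel_sum$participant_id, matched),
                        already_logged)
  if (length(only_diary) > 0) {
    exclusions <- c(exclusions, list(tibble(
      participant_id = only_diary, reason = "unmatched",
      detail = "no kept accelerometer day")))
  }
  if (length(only_accel) > 0) {
    exclusions <- c(exclusions, list(tibble(
      participant_id = only_accel, reason = "unmatched",
      detail = "no valid recall-1 diary")))
  }
  if (length(matched) == 0) {
    stop_par24("no participants with both a valid diary and a kept accelerometer day",
               "par24_pipeline_error")
  }

  pairs_all <- purrr::map(stats::setNames(nm = c("sedentary_min", "light_min", "mvpa_min")),
                          function(q) {
    tibble(
      participant_id = matched,
      value_a = diary_sum[[q]][match(matched, diary_sum$participant_id)],
      value_b = accel_sum[[q]][match(matched, accel_sum$participant_id)]
    )
  })
  build_report("validity", pairs_all, covariates, exclusions, denominator)
}

#' Reliability study: replicate recalls
#'
#' Runs the test-retest analysis between the first and second diary recall
#' of the same 24-h period: intensity minutes per class plus the 24-h
#' average MET, per stratum, with between-strata rank-sum tests.
#' Differences are recall 1 minus recall 2. Participants lacking either
#' recall (or with an invalid diary) are logged and dropped.
#'
#' @inheritParams run_validity_study
#' @return A `par24_report`, as for [run_validity_study()], with an
#'   `avg_met` quantity in addition to the three intensity classes.
#' @export
run_reliability_study <- function(diaries, covariates, catalog,
                                  overlap_rule = c("max", "mean"),
                                  denominator = c("per_pair", "pooled_median")) {
  overlap_rule <- match.arg(overlap_rule)
  denominator <- match.arg(denominator)
  exclusions <- list()

  scored <- score_diary(diaries, catalog, overlap_rule)
  if (nrow(scored$invalid) > 0) {
    bad <- unique(scored$invalid$participant_id)
    exclusions <- c(exclusions, list(tibble(
      participant_id = bad, reason = "invalid_diary",
      detail = vapply(bad, function(p) {
        v <- scored$invalid[scored$invalid$participant_id == p, ]
        paste0(nrow(v), " violation(s), first: ", v$detail[1])
      }, character(1))
    )))
  }
  s <- scored$summaries
  r1 <- dplyr::filter(s, .data$recall_index == 1L)
  r2 <- dplyr::filter(s, .data$recall_index == 2L)
  matched <- intersect(r1$participant_id, r2$participant_id)
  lone <- setdiff(union(r1$participant_id, r2$participant_id), matched)
  if (length(lone) > 0) {
    exclusions <- c(exclusions, list(tibble(
      participant_id = lone, reason = "single_recall",
      detail = "participant has only one valid recall")))
  }
  if (length(matched) == 0) {
    stop_par24("no participants with two valid recalls", "par24_pipeline_error")
  }

  quantities <- c("sedentary_min", "light_min", "mvpa_min", "avg_met")
  pairs_all <- purrr::map(stats::setNames(nm = quantities), function(q) {
    tibble(
      participant_id = matched,
      value_a = r1[[q]][match(matched, r1$participant_id)],
      value_b = r2[[q]][match(matched, r2$participant_id)]
    )
  })
  build_report("reliability", pairs_all, covariates, exclusions, denominator)
}

# Assemble the per-quantity x per-stratum report shared by both studies.
# Stratified blocks that cannot be analysed (a stratum smaller than three
# participants, or one in which a method is constant) are dropped from the
# results and recorded in the report notes; the overall block always runs.
build_report <- function(study, pairs_all, covariates, exclusions, denominator) {
  notes <- list()
  results <- purrr::imap(pairs_all, function(pairs, quantity) {
    overall <- dplyr::mutate(
      tidy(method_agreement(pairs, quantity, denominator)),
      stratum = "all", stratifier = "none", between_strata_p = NA_real_,
      .before = 1
    )
    with_cov <- dplyr::inner_join(
      pairs,
      dplyr::rename(covariates, age = "age_years"),
      by = "participant_id"
    )
    with_cov <- dplyr::filter(with_cov, !is.na(.data$age),
                              !is.na(.data$gender), !is.na(.data$bmi))
    strat_rows <- purrr::map(c("age", "gender", "bmi"), function(sv) {
      tryCatch({
        st <- stratified_comparison(with_cov, sv, quantity = quantity,
                                    denominator = denominator)
        dplyr::relocate(tidy(st), "stratum", "stratifier", "between_strata_p")
      }, par24_error = function(e) {
        notes[[length(notes) + 1]] <<- tibble(
          quantity = quantity, stratifier = sv, issue = conditionMessage(e)
        )
        NULL
      })
    })
    dplyr::bind_rows(c(list(overall), strat_rows))
  })
  results <- dplyr::bind_rows(results)
  exclusions <- if (length(exclusions) > 0) dplyr::bind_rows(exclusions) else
    tibble(participant_id = character(), reason = character(),
           detail = character())
  notes <- if (length(notes) > 0) dplyr::bind_rows(notes) else
    tibble(quantity = character(), stratifier = character(),
           issue = character())
  structure(
    list(study = study, results = results, pairs = pairs_all,
         exclusions = exclusions, notes = notes),
    class = "par24_report"
  )
}

#' @rdname run_validity_study
#' @param x A `par24_report`.
#' @param ... Unused.
#' @method tidy par24_report
#' @export
tidy.par24_report <- function(x, ...) {
  x$results
}

#' @export
print.par24_report <- function(x, ...) {
  cat(sprintf("par24 %s study: %d quantities x %d strata rows; %d exclusion(s)\n",
              x$study, length(x$pairs), nrow(x$results), nrow(x$exclusions)))
  if (nrow(x$notes) > 0) {
    cat(sprintf("  %d stratified block(s) not analysable; see $notes\n",
                nrow(x$notes)))
  }
  print(x$results)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes the results table as CSV, the full report (results plus
#' exclusions) as machine-readable JSON, and the exclusion log as CSV.
#' Output is deterministic for identical inputs.
#'
#' @param report A `par24_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "par24_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- report$study
  readr::write_csv(report$results, file.path(dir, paste0(prefix, "_report.csv")),
                   na = "")
  readr::write_csv(report$exclusions,
                   file.path(dir, paste0(prefix, "_exclusions.csv")), na = "")
  jsonlite::write_json(
    list(study = report$study, results = report$results,
         exclusions = report$exclusions),
    file.path(dir, paste0(prefix, "_report.json")),
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
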