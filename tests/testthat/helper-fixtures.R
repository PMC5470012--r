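# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except the shipped demonstration catalog.

# A minimal catalog of simple single-MET activities, one per wanted MET.
simple_catalog <- function(mets) {
  as_activity_catalog(tibble::tibble(
    code = paste0("A", seq_along(mets)),
    name = paste("activity", seq_along(mets)),
    category = rep_len(1:13, length(mets)),
    met_none = mets,
    met_light = NA_real_, met_medium = NA_real_, met_hard = NA_real_,
    met_sitting = NA_real_, met_standing = NA_real_
  ))
}

# One diary day built from parallel vectors of codes and [start, end) bounds.
make_day <- function(codes, starts, ends, effort = NA_character_,
                     standing_fraction = NA_real_, participant_id = "T01",
                     recall_index = 1L) {
  tibble::tibble(
    participant_id = participant_id,
    recall_index = recall_index,
    code = codes,
    start_min = as.integer(starts),
    end_min = as.integer(ends),
    effort = rep_len(effort, length(codes)),
    standing_fraction = rep_len(standing_fraction, length(codes))
  )
}

# A one-day count series from a 1440-long cpm vector, optionally split into
# sub-minute epochs (counts spread evenly so totals are conserved).
make_counts_day <- function(cpm, wear = rep(TRUE, 1440), epoch_seconds = 60L,
                            participant_id = "T01", date = "2011-07-15") {
  per_min <- 60L %/% epoch_seconds
  if (per_min == 1L) {
    counts <- cpm
  } else {
    counts <- unlist(lapply(cpm, function(x) {
      base <- rep(x %/% per_min, per_min)
      rem <- x %% per_min
      if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
      base
    }))
  }
  day0 <- as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC")
  as_count_series(tibble::tibble(
    participant_id = participant_id,
    time = day0 + seq(0, 86400 - epoch_seconds, by = epoch_seconds),
    epoch_seconds = epoch_seconds,
    counts = as.numeric(counts),
    wear = rep(wear, each = per_min)
  ))
}
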