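#' Simulation configuration
#'
#' Builds the configuration for the synthetic paired diary + accelerometer
#' cohort generator. The defaults emulate the validation-study conditions
#' this package targets: true daily schedules centred on roughly 1000
#' sedentary, 400 light, and 40 MVPA minutes (near the accelerometer medians
#' of such cohorts), count emission whose class-conditional distributions
#' are truncated to the 100/1952 cpm intervals so the truth class of every
#' minute is identifiable, and recall misreporting that moves true light
#' time into reported MVPA (over-reporting) and into reported sedentary time
#' (under-reporting). With the default factors the expected transfers at 400
#' true light minutes are about +90 min of spurious MVPA and -120 min of
#' light time.
#'
#' @param n_participants Number of participants.
#' @param seed Master seed; per-participant substreams are derived as
#'   `(seed + 1000003 * index) mod (2^31 - 1)` so existing participants are
#'   unchanged when the cohort grows.
#' @param schedule List: `mean_min` (named vector, expected true minutes per
#'   class, renormalised to 1440), `concentration` (Dirichlet-style
#'   concentration; larger = less between-participant variation),
#'   `mean_bout_min` (mean bout length per class, minutes).
#' @param counts_model List: `mean` and `sd` (per-class cpm emission,
#'   truncated to the class interval). `sd = 0` gives degenerate
#'   class-typical emission.
#' @param misreport List: `mvpa_overreport_factor` (probability that a true
#'   light 5-min block is reported as MVPA), `light_underreport_factor`
#'   (probability it is reported as sedentary), `boundary_confusion_prob`
#'   (per-block probability that a replicate recall flips the reported class
#'   to an adjacent one), `granularity_min` (reporting grid, fixed at 5).
#' @param covariates List: `age_mean`, `age_sd`, `age_range` (ages are drawn
#'   from a normal clamped to the range), `prop_female`, `bmi_mean`,
#'   `bmi_sd`, `bmi_range`.
#' @param wear List: `nonwear_prob` (probability a day contains one non-wear
#'   bout), `nonwear_min_range` (bout length range, minutes).
#' @param epoch_seconds Accelerometer epoch length; 60 by default,
#'   sub-minute values exercise the epoch-to-minute reduction.
#' @param recall_date Date of the simulated recall day.
#' @return A list of class `par24_sim_config`.
#' @export
sim_config <- function(n_participants = 49L,
                       seed = 20110715L,
                       schedule = list(),
                       counts_model = list(),
                       misreport = list(),
                       covariates = list(),
                       wear = list(),
                       epoch_seconds = 60L,
                       recall_date = "2011-07-15") {
  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    schedule = utils::modifyList(list(
      mean_min = c(sedentary = 1000, light = 400, mvpa = 40),
      concentration = 40,
      mean_bout_min = c(sedentary = 60, light = 30, mvpa = 20)
    ), schedule),
    counts_model = utils::modifyList(list(
      mean = c(sedentary = 30, light = 600, mvpa = 3000),
      sd = c(sedentary = 25, light = 400, mvpa = 800)
    ), counts_model),
    misreport = utils::modifyList(list(
      mvpa_overreport_factor = 0.225,
      light_underreport_factor = 0.075,
      boundary_confusion_prob = 0.02,
      granularity_min = 5L
    ), misreport),
    covariates = utils::modifyList(list(
      age_mean = 52,
      age_sd = 13,
      age_range = c(22, 70),
      prop_female = 0.5,
      bmi_mean = 26.1,
      bmi_sd = 4.4,
      bmi_range = c(18.1, 41.2)
    ), covariates),
    wear = utils::modifyList(list(
      nonwear_prob = 0.1,
      nonwear_min_range = c(30, 120)
    ), wear),
    epoch_seconds = as.integer(epoch_seconds),
    recall_date = as.character(recall_date)
  )
  if (cfg$n_participants < 0) {
    stop_par24("n_participants must be nonnegative", "par24_config_error")
  }
  if (any(cfg$schedule$mean_min < 0) || sum(cfg$schedule$mean_min) <= 0) {
    stop_par24("schedule mean_min must be nonnegative and not all zero",
               "par24_config_error")
  }
  probs <- c(cfg$misreport$mvpa_overreport_factor,
             cfg$misreport$light_underreport_factor,
             cfg$misreport$boundary_confusion_prob,
             cfg$covariates$prop_female, cfg$wear$nonwear_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_par24("all probabilities must lie in [0, 1]", "par24_config_error")
  }
  if (cfg$misreport$mvpa_overreport_factor +
      cfg$misreport$light_underreport_factor > 1) {
    stop_par24("misreport factors must sum to at most 1", "par24_config_error")
  }
  if (!cfg$epoch_seconds %in% c(1L, 5L, 10L, 15L, 30L, 60L)) {
    stop_par24("epoch_seconds must be one of 1, 5, 10, 15, 30, 60",
               "par24_config_error")
  }
  structure(cfg, class = "par24_sim_config")
}

participant_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 1000003 * index) %% (2^31 - 1))
}

# cpm intervals that make truth classes identifiable by construction
class_cpm_interval <- function(class) {
  switch(class,
         sedentary = c(0, 99),
         light = c(100, 1951),
         mvpa = c(1952, 10000))
}

# Truncated-normal cpm draw via inverse CDF; sd = 0 collapses to the mean
# clamped into the class interval.
draw_cpm <- function(n, mean, sd, interval) {
  if (sd == 0) {
    return(rep(round(min(max(mean, interval[1]), interval[2])), n))
  }
  pa <- stats::pnorm(interval[1] - 0.5, mean, sd)
  pb <- stats::pnorm(interval[2] + 0.5, mean, sd)
  x <- stats::qnorm(stats::runif(n, pa, pb), mean, sd)
  pmin(pmax(round(x), interval[1]), interval[2])
}

# Enumerate reportable (code, effort, standing_fraction) variants of a
# catalog together with the MET and intensity class each resolves to.
catalog_variants <- function(catalog) {
  simple <- catalog[!is.na(catalog$met_none), ]
  ranked <- catalog[!is.na(catalog$met_light), ]
  posture <- catalog[!is.na(catalog$met_sitting), ]
  sf <- c(0, 0.5, 1)
  out <- dplyr::bind_rows(
    tibble(code = simple$code, effort = NA_character_,
           standing_fraction = NA_real_, met = simple$met_none),
    tibble(code = rep(ranked$code, each = 3),
           effort = rep(effort_levels, nrow(ranked)),
           standing_fraction = NA_real_,
           met = as.vector(rbind(ranked$met_light, ranked$met_medium,
                                 ranked$met_hard))),
    tibble(code = rep(posture$code, each = 3),
           effort = NA_character_,
           standing_fraction = rep(sf, nrow(posture)),
           met = as.vector(vapply(seq_len(nrow(posture)), function(i) {
             sf * posture$met_standing[i] + (1 - sf) * posture$met_sitting[i]
           }, numeric(3))))
  )
  out$class <- classify_met(out$met)
  out
}

# Largest-remainder rounding of class proportions onto n_blocks 5-min blocks.
allocate_blocks <- function(props, n_blocks) {
  raw <- props * n_blocks
  base <- floor(raw)
  short <- n_blocks - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# True day as a sequence of 5-min blocks: alternating bouts whose lengths
# follow a geometric block count with the configured per-class mean.
build_truth_blocks <- function(blocks_per_class, mean_bout_min) {
  remaining <- blocks_per_class
  seq_out <- integer(0)
  last <- NA_character_
  classes <- names(blocks_per_class)
  while (sum(remaining) > 0) {
    avail <- classes[remaining > 0]
    pick_from <- setdiff(avail, last)
    if (length(pick_from) == 0) pick_from <- avail
    w <- remaining[pick_from]
    cls <- if (length(pick_from) == 1) pick_from else
      sample(pick_from, 1, prob = w)
    mean_blocks <- max(mean_bout_min[[cls]] / 5, 1)
    len <- min(remaining[[cls]], 1L + stats::rgeom(1, prob = 1 / mean_blocks))
    seq_out <- c(seq_out, rep(match(cls, intensity_levels), len))
    remaining[[cls]] <- remaining[[cls]] - len
    last <- cls
  }
  factor(intensity_levels[seq_out], levels = intensity_levels)
}

# Reported schedule: independent per-block transfer of true light time into
# reported MVPA (over-reporting) or sedentary (under-reporting).
misreport_blocks <- function(truth_blocks, misreport) {
  reported <- truth_blocks
  light_idx <- which(truth_blocks == "light")
  if (length(light_idx) > 0) {
    u <- stats::runif(length(light_idx))
    p_up <- misreport$mvpa_overreport_factor
    p_down <- misreport$light_underreport_factor
    reported[light_idx[u < p_up]] <- "mvpa"
    reported[light_idx[u >= p_up & u < p_up + p_down]] <- "sedentary"
  }
  reported
}

# Replicate-recall noise: flip a block's reported class to an adjacent one
# with the boundary-confusion probability.
confuse_blocks <- function(blocks, prob) {
  if (prob == 0) return(blocks)
  flip <- stats::runif(length(blocks)) < prob
  out <- as.character(blocks)
  out[flip & blocks == "sedentary"] <- "light"
  out[flip & blocks == "mvpa"] <- "light"
  light_flip <- which(flip & blocks == "light")
  if (length(light_flip) > 0) {
    up <- stats::runif(length(light_flip)) < 0.5
    out[light_flip[up]] <- "mvpa"
    out[light_flip[!up]] <- "sedentary"
  }
  factor(out, levels = intensity_levels)
}

# Turn a block-class sequence into diary entries by sampling, per bout, a
# reportable catalog variant of the matching intensity class.
blocks_to_entries <- function(blocks, variants, participant_id, recall_index) {
  segs <- rle_segments(as.character(blocks))
  pools <- split(seq_len(nrow(variants)), as.character(variants$class))
  pick <- vapply(segs$value, function(cls) {
    pool <- pools[[cls]]
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  tibble(
    participant_id = participant_id,
    recall_index = as.integer(recall_index),
    code = variants$code[pick],
    start_min = as.integer(segs$start * 5L),
    end_min = as.integer(segs$end * 5L),
    effort = variants$effort[pick],
    standing_fraction = variants$standing_fraction[pick]
  )
}

#' Simulate one participant
#'
#' Draws one participant's true minute-level schedule, an accelerometer
#' count stream whose class-conditional emission makes the truth
#' recoverable, two replicate diary recalls distorted by the configured
#' misreporting, and covariates. Deterministic given the configuration:
#' the participant's substream seed depends only on the master seed and the
#' participant index.
#'
#' @param config A [sim_config()] object.
#' @param participant_index Positive integer.
#' @param catalog Catalog used to pick reportable activities; defaults to
#'   [demo_catalog()].
#' @return List with `truth` (factor, 1440 minute classes), `diary` (entries
#'   for recall 1 and 2), `counts` (a `par24_counts` tibble), `covariates`
#'   (one-row tibble).
#' @export
simulate_participant <- function(config, participant_index,
                                 catalog = demo_catalog()) {
  stopifnot(inherits(config, "par24_sim_config"))
  set.seed(participant_seed(config$seed, participant_index))
  pid <- sprintf("P%03d", participant_index)
  variants <- catalog_variants(catalog)

  # covariates
  cv <- config$covariates
  age <- round(min(max(stats::rnorm(1, cv$age_mean, cv$age_sd),
                       cv$age_range[1]), cv$age_range[2]))
  gender <- if (stats::runif(1) < cv$prop_female) "female" else "male"
  bmi <- min(max(stats::rnorm(1, cv$bmi_mean, cv$bmi_sd), cv$bmi_range[1]),
             cv$bmi_range[2])
  covariates <- tibble(participant_id = pid, age_years = age,
                       gender = gender, bmi = round(bmi, 1))

  # true schedule
  sch <- config$schedule
  p <- sch$mean_min / sum(sch$mean_min)
  g <- stats::setNames(stats::rgamma(3, shape = sch$concentration * p), names(p))
  blocks <- allocate_blocks(g / sum(g), 288L)
  truth_blocks <- build_truth_blocks(blocks, sch$mean_bout_min)
  truth <- rep(truth_blocks, each = 5L)

  # counts from truth
  cm <- config$counts_model
  cpm <- numeric(1440)
  for (cls in intensity_levels) {
    idx <- which(truth == cls)
    if (length(idx) > 0) {
      cpm[idx] <- draw_cpm(length(idx), cm$mean[[cls]], cm$sd[[cls]],
                           class_cpm_interval(cls))
    }
  }
  ep <- config$epoch_seconds
  per_min <- 60L %/% ep
  if (per_min == 1L) {
    counts <- cpm
  } else {
    # spread each minute's counts over its epochs, conserving the total
    counts <- unlist(lapply(cpm, function(x) {
      base <- rep(x %/% per_min, per_min)
      rem <- x %% per_min
      if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
      base
    }))
  }
  wear_min <- rep(TRUE, 1440)
  if (stats::runif(1) < config$wear$nonwear_prob) {
    len <- round(stats::runif(1, config$wear$nonwear_min_range[1],
                              config$wear$nonwear_min_range[2]))
    start <- sample.int(1440 - len + 1, 1)
    wear_min[start:(start + len - 1)] <- FALSE
  }
  day0 <- as.POSIXct(paste0(config$recall_date, " 00:00:00"), tz = "UTC")
  counts_tbl <- as_count_series(tibble(
    participant_id = pid,
    time = day0 + seq(0, 86400 - ep, by = ep),
    epoch_seconds = ep,
    counts = as.numeric(counts),
    wear = rep(wear_min, each = per_min)
  ))

  # diaries: one stable reported schedule, two independently confused recalls
  reported <- misreport_blocks(truth_blocks, config$misreport)
  recall1 <- confuse_blocks(reported, config$misreport$boundary_confusion_prob)
  recall2 <- confuse_blocks(reported, config$misreport$boundary_confusion_prob)
  diary <- dplyr::bind_rows(
    blocks_to_entries(recall1, variants, pid, 1L),
    blocks_to_entries(recall2, variants, pid, 2L)
  )

  list(truth = truth, diary = diary, counts = counts_tbl,
       covariates = covariates)
}

#' Simulate a cohort
#'
#' Draws `n_participants` independent participants (each from its own
#' substream of the master seed) and stacks their diaries, count streams,
#' covariates, and per-participant truth minute totals into the tables the
#' package's readers and pipelines consume.
#'
#' @inheritParams simulate_participant
#' @param dir Optional directory; when given, `diaries.csv`, `counts.csv`,
#'   `covariates.csv`, and `truth.csv` are written there.
#' @return List of class `par24_cohort` with `diaries`, `counts`,
#'   `covariates`, `truth` (tibble: participant, true minutes per class),
#'   and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 3, seed = 1))
#' cohort$truth
#' @export
simulate_cohort <- function(config, catalog = demo_catalog(), dir = NULL) {
  stopifnot(inherits(config, "par24_sim_config"))
  sims <- lapply(seq_len(config$n_participants), function(i) {
    simulate_participant(config, i, catalog)
  })
  empty_diary <- tibble(participant_id = character(), recall_index = integer(),
                        code = character(), start_min = integer(),
                        end_min = integer(), effort = character(),
                        standing_fraction = double())
  cohort <- list(
    diaries = if (length(sims)) dplyr::bind_rows(purrr::map(sims, "diary")) else empty_diary,
    counts = as_count_series(
      if (length(sims)) dplyr::bind_rows(purrr::map(sims, "counts")) else
        tibble(participant_id = character(), time = as.POSIXct(character(), tz = "UTC"),
               epoch_seconds = integer(), counts = double(), wear = logical())
    ),
    covariates = if (length(sims)) dplyr::bind_rows(purrr::map(sims, "covariates")) else
      tibble(participant_id = character(), age_years = double(),
             gender = character(), bmi = double()),
    truth = dplyr::bind_rows(purrr::map(sims, function(s) {
      tibble(
        participant_id = s$covariates$participant_id,
        sedentary_min = sum(s$truth == "sedentary"),
        light_min = sum(s$truth == "light"),
        mvpa_min = sum(s$truth == "mvpa")
      )
    })),
    config = config
  )
  class(cohort) <- "par24_cohort"
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @rdname simulate_cohort
#' @param cohort A `par24_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "par24_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_diary_csv(cohort$diaries, file.path(dir, "diaries.csv"))
  write_counts_csv(cohort$counts, file.path(dir, "counts.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"), na = "")
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
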