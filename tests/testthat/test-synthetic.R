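test_that("simulation is deterministic given config and participant index", {
  cfg <- sim_config(n_participants = 2, seed = 99)
  s1 <- simulate_participant(cfg, 1)
  s2 <- simulate_participant(cfg, 1)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$diary), as.data.frame(s2$diary))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("growing the cohort does not change existing participants", {
  small <- simulate_cohort(sim_config(n_participants = 2, seed = 99))
  large <- simulate_cohort(sim_config(n_participants = 4, seed = 99))
  p2_small <- dplyr::filter(small$diaries, participant_id == "P002")
  p2_large <- dplyr::filter(large$diaries, participant_id == "P002")
  expect_identical(as.data.frame(p2_small), as.data.frame(p2_large))
})

test_that("different seeds give different cohorts", {
  c1 <- simulate_cohort(sim_config(n_participants = 3, seed = 1))
  c2 <- simulate_cohort(sim_config(n_participants = 3, seed = 2))
  expect_false(identical(as.data.frame(c1$diaries), as.data.frame(c2$diaries)))
})

test_that("simulated diaries validate and counts pass format checks", {
  catalog <- demo_catalog()
  cohort <- simulate_cohort(sim_config(n_participants = 4, seed = 5), catalog)
  for (pid in unique(cohort$diaries$participant_id)) {
    for (ri in 1:2) {
      day <- dplyr::filter(cohort$diaries, participant_id == pid,
                           recall_index == ri)
      expect_equal(nrow(validate_diary(day, catalog)), 0,
                   info = paste(pid, ri))
    }
  }
  expect_s3_class(cohort$counts, "par24_counts")
  expect_equal(nrow(cohort$counts), 4 * 1440)
})

test_that("with no distortion, diary, accelerometer, and truth agree exactly", {
  cfg <- sim_config(
    n_participants = 1, seed = 77,
    misreport = list(mvpa_overreport_factor = 0, light_underreport_factor = 0,
                     boundary_confusion_prob = 0),
    counts_model = list(sd = c(sedentary = 0, light = 0, mvpa = 0)),
    wear = list(nonwear_prob = 0)
  )
  catalog <- demo_catalog()
  s <- simulate_participant(cfg, 1)
  truth_minutes <- c(sum(s$truth == "sedentary"), sum(s$truth == "light"),
                     sum(s$truth == "mvpa"))
  day <- dplyr::filter(s$diary, recall_index == 1)
  ds <- diary_summary(minute_met_profile(day, catalog))
  as_ <- accelerometer_summary(to_minute_counts(s$counts))
  expect_equal(c(ds$sedentary_min, ds$light_min, ds$mvpa_min), truth_minutes)
  expect_equal(c(as_$sedentary_min, as_$light_min, as_$mvpa_min), truth_minutes)
})

test_that("MVPA over-reporting only ever adds reported MVPA time", {
  cfg <- sim_config(
    n_participants = 1, seed = 123,
    misreport = list(mvpa_overreport_factor = 0.4, light_underreport_factor = 0,
                     boundary_confusion_prob = 0)
  )
  catalog <- demo_catalog()
  for (i in 1:5) {
    s <- simulate_participant(cfg, i)
    day <- dplyr::filter(s$diary, recall_index == 1)
    ds <- diary_summary(minute_met_profile(day, catalog))
    expect_gte(ds$mvpa_min, sum(s$truth == "mvpa"))
    expect_lte(ds$light_min, sum(s$truth == "light"))
  }
})

test_that("cohort files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(sim_config(n_participants = 5, seed = 31), dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("diaries.csv", "counts.csv", "covariates.csv", "truth.csv")
  ))))
  diaries <- read_diary_csv(file.path(dir, "diaries.csv"))
  counts <- read_counts_csv(file.path(dir, "counts.csv"))
  covariates <- readr::read_csv(file.path(dir, "covariates.csv"),
                                show_col_types = FALSE)
  expect_equal(as.data.frame(diaries), as.data.frame(cohort$diaries))
  expect_equal(counts$counts, cohort$counts$counts)
  expect_equal(counts$wear, cohort$counts$wear)
  expect_equal(nrow(covariates), 5)
})

test_that("an empty cohort is well-formed", {
  cohort <- simulate_cohort(sim_config(n_participants = 0, seed = 1))
  expect_equal(nrow(cohort$diaries), 0)
  expect_equal(nrow(cohort$counts), 0)
  expect_equal(nrow(cohort$covariates), 0)
  expect_named(cohort$diaries,
               c("participant_id", "recall_index", "code", "start_min",
                 "end_min", "effort", "standing_fraction"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(schedule = list(mean_min = c(sedentary = -10, light = 400, mvpa = 40))),
               class = "par24_config_error")
  expect_error(sim_config(misreport = list(boundary_confusion_prob = 1.5)),
               class = "par24_config_error")
  expect_error(sim_config(misreport = list(mvpa_overreport_factor = 0.6,
                                           light_underreport_factor = 0.6)),
               class = "par24_config_error")
  expect_error(sim_config(epoch_seconds = 7), class = "par24_config_error")
  expect_error(sim_config(n_participants = -1), class = "par24_config_error")
})

test_that("replicate-recall agreement improves as boundary confusion shrinks", {
  catalog <- demo_catalog()
  mean_rel <- function(confusion) {
    rs <- vapply(1:3, function(seed) {
      cfg <- sim_config(n_participants = 25, seed = 1000 + seed,
                        misreport = list(boundary_confusion_prob = confusion))
      cohort <- simulate_cohort(cfg, catalog)
      s <- score_diary(cohort$diaries, catalog)$summaries
      r1 <- dplyr::filter(s, recall_index == 1)
      r2 <- dplyr::filter(s, recall_index == 2)
      pairs <- tibble::tibble(
        value_a = r1$sedentary_min[match(r2$participant_id, r1$participant_id)],
        value_b = r2$sedentary_min
      )
      spearman(pairs)
    }, numeric(1))
    mean(rs)
  }
  expect_gt(mean_rel(0.01), mean_rel(0.25))
})

test_that("sub-minute epoch emission preserves the accelerometer summary", {
  catalog <- demo_catalog()
  base <- sim_config(n_participants = 1, seed = 55)
  fine <- sim_config(n_participants = 1, seed = 55, epoch_seconds = 15L)
  s60 <- simulate_participant(base, 1, catalog)
  s15 <- simulate_participant(fine, 1, catalog)
  expect_identical(s60$truth, s15$truth)
  a60 <- accelerometer_summary(to_minute_counts(s60$counts))
  a15 <- accelerometer_summary(to_minute_counts(s15$counts))
  expect_equal(a15[-1], a60[-1])
})
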