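Package: par24
Title: Scoring and Validation of 24-Hour Physical Activity Recalls Against Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring computer-based 24-hour physical activity recall
    diaries into minute-level MET (metabolic equivalent of task) profiles and
    sedentary/light/moderate-to-vigorous intensity summaries, for reducing
    accelerometer epoch counts to counts-per-minute intensity summaries under
    the Freedson/Matthews cut-points, and for the full nonparametric
    concordance analysis used to evaluate such instruments: Spearman
    correlation, Wilcoxon signed-rank and rank-sum tests, median-of-differences
    with percent differences, Bland-Altman bias and limits of agreement, and
    comparisons stratified by age, gender, and BMI. Includes a synthetic cohort
    generator with configurable recall misreporting so the whole validity and
    reliability pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
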