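#' Held-out normative calibration of the fitting pipeline
#'
#' End-to-end adequacy check of the chart machinery on synthetic full-term
#' data: simulate a term cohort from a ground-truth chart, fit charts and
#' estimate the study offset on a random half, score the held-out half, and
#' report, per region, the percentage of held-out subjects whose deviation
#' score lies strictly inside the normative range (0.05, 0.95). With a
#' well-calibrated pipeline each region sits near 90%; the minimum over
#' regions is the headline adequacy number (published charts report more
#' than 85% of full-term individuals inside the normative range in every
#' region).
#'
#' @param seed Seed driving the ground truth, the cohort draw and the
#'   train/test split.
#' @param n_term Number of term subjects (sex balanced).
#' @return List with `per_region` (named percentages), `minimum`, `mean`
#'   and `n_scored`.
#' @export
normative_calibration <- function(seed = 42L, n_term = 1000L) {
  truth <- default_ground_truth(seed = seed)
  bundle <- simulate_cohort(truth, n_term = n_term, n_preterm = 0L)
  m <- bundle$morphometry
  ids <- unique(m$subject_id)
  half <- with_seed(derive_seed(seed, 23L),
                    sample(ids, floor(length(ids) / 2)))
  train <- m[m$subject_id %in% half, , drop = FALSE]
  test <- m[!(m$subject_id %in% half), , drop = FALSE]
  chart <- fit_reference_charts(train, seed = seed)
  chart <- adapt_study_offset(chart, train, names(truth$study_offsets)[1])
  scored <- compute_deviation_scores(chart, test)
  inside <- scored$score > 0.05 & scored$score < 0.95
  per_region <- 100 * tapply(inside, scored$region, mean)
  list(per_region = per_region,
       minimum = min(per_region),
       mean = mean(per_region),
       n_scored = length(unique(scored$subject_id)))
}
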