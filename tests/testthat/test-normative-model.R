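regs4 <- dk_region_names()[1:4]

small_truth <- function(seed = 1L, ...) {
  default_ground_truth(seed = seed, region_names = regs4,
                       geometry = synthetic_centroids(regs4, seed = seed),
                       ...)
}

test_that("charts refit from their own draws recover the location curve", {
  truth <- small_truth(seed = 31L)
  b <- simulate_cohort(truth, n_term = 1000L, n_preterm = 0L)
  chart <- fit_reference_charts(b$morphometry, seed = 31L)
  probe_ages <- seq(25.7, 28.7, length.out = 5)
  days <- age_to_days(probe_ages, "years")
  for (reg in regs4) {
    for (sx in c("M", "F")) {
      mu_hat <- ibap:::chart_params(chart, rep(reg, 5), rep(sx, 5), days)$mu
      mu_true <- ibap:::chart_params(truth$chart, rep(reg, 5), rep(sx, 5),
                                     days)$mu
      expect_lt(max(abs(mu_hat - mu_true) / abs(mu_true)), 0.02)
    }
  }
})

test_that("constant-variance Gaussian family reduces to OLS", {
  truth <- small_truth(seed = 32L)
  b <- simulate_cohort(truth, n_term = 120L, n_preterm = 0L)
  d <- b$morphometry[b$morphometry$region == regs4[1], ]
  chart <- fit_reference_charts(d, family = "gaussian",
                                df_location = 2L, df_scale = 0L,
                                seed = 1L)
  for (sx in c("M", "F")) {
    ds <- d[d$sex == sx, ]
    t <- ibap:::chart_t(chart, ibap:::mt_days(ds))
    ols <- coef(lm(ds$value ~ t + I(t^2)))
    co <- chart$coef[chart$coef$sex == sx, c("b0", "b1", "b2")]
    expect_equal(as.numeric(co), as.numeric(ols), tolerance = 1e-6)
  }
  expect_equal(chart$coef$nu, c(0, 0))
})

test_that("a known study shift is recovered by offset adaptation", {
  truth <- small_truth(seed = 33L,
                       study_offsets = c(SYNTH = 0, SHIFTED = 0.10))
  b <- simulate_cohort(truth, n_term = 200L, n_preterm = 0L)
  m <- b$morphometry
  chart <- fit_reference_charts(m[m$study == "SYNTH", ], seed = 33L)
  chart <- adapt_study_offset(chart, m, "SHIFTED")
  expect_lt(abs(chart$offsets[["SHIFTED"]] - 0.10), 0.02)

  # null-shift study: bootstrap CI of the median residual covers 0
  chart <- adapt_study_offset(chart, m, "SYNTH")
  term <- m[m$study == "SYNTH" & m$group == "term", ]
  par <- ibap:::chart_params(chart, term$region, term$sex,
                             ibap:::mt_days(term))
  res <- term$value - par$mu
  set.seed(1)
  meds <- replicate(500, median(sample(res, length(res), replace = TRUE)))
  ci <- quantile(meds, c(0.025, 0.975))
  expect_true(ci[1] <= 0 && ci[2] >= 0)

  # adaptation recentres deviation scores of the shifted study
  sh <- m[m$study == "SHIFTED", ]
  d_adapted <- compute_deviation_scores(chart, sh)$score
  chart0 <- chart; chart0$offsets["SHIFTED"] <- 0
  d_raw <- compute_deviation_scores(chart0, sh)$score
  expect_lt(mean(abs(d_adapted - 0.5)), mean(abs(d_raw - 0.5)))
})

test_that("offset requires term-born members of the study", {
  truth <- small_truth(seed = 34L, study_offsets = c(A = 0, B = 0.05))
  b <- suppressWarnings(simulate_cohort(truth, n_term = 100L, n_preterm = 50L))
  m <- b$morphometry
  chart <- fit_reference_charts(m[m$study == "A", ], seed = 1L)
  only_pre <- m[m$study == "B" & m$group == "preterm", ]
  expect_error(adapt_study_offset(chart, only_pre, "B"), "term-born")
})

test_that("deviation scores are percentiles of the adapted chart", {
  truth <- small_truth(seed = 35L)
  chart <- truth$chart
  days <- age_to_days(27, "years")
  par <- ibap:::chart_params(chart, regs4[2], "F", days)

  row <- data.frame(subject_id = "X1", study = "SYNTH", timepoint = 1L,
                    age = 27, sex = "F", group = "term", ga_weeks = 39,
                    region = regs4[2], measure = "CTh", value = NA_real_)
  # chart median -> score 0.5
  row$value <- qshash(0.5, par$mu, par$sigma, par$nu)
  expect_equal(compute_deviation_scores(chart, row)$score, 0.5,
               tolerance = 1e-10)
  # below the 5th percentile -> infra
  row$value <- qshash(0.03, par$mu, par$sigma, par$nu)
  expect_identical(compute_deviation_scores(chart, row)$label, "infra")
  # round trip at the named percentiles
  for (p in c(0.01, 0.05, 0.5, 0.95, 0.99)) {
    row$value <- qshash(p, par$mu, par$sigma, par$nu)
    expect_equal(compute_deviation_scores(chart, row)$score, p,
                 tolerance = 1e-8)
  }
  # strictly increasing in the observed value
  vals <- qshash(seq(0.02, 0.98, by = 0.04), par$mu, par$sigma, par$nu)
  rows <- row[rep(1, length(vals)), ]; rows$value <- vals
  rows$subject_id <- sprintf("X%02d", seq_along(vals))
  expect_true(all(diff(compute_deviation_scores(chart, rows)$score) > 0))
})

test_that("strict thresholds and counts behave at the boundary", {
  labels <- matrix("normal", 1, 4,
                   dimnames = list("s1", regs4))
  p <- make_profiles(labels)
  p$score <- c(0.04, 0.5, 0.96, 0.05)   # 0.05 exactly must stay normal
  p <- classify_extranormal(p)
  expect_identical(p$label, c("infra", "normal", "supra", "normal"))
  cnt <- count_extranormal(p)
  expect_identical(cnt$n_infra, 1L)
  expect_identical(cnt$n_supra, 1L)
  expect_identical(cnt$n_extra, 2L)

  p$score <- rep(0.5, 4)
  expect_identical(count_extranormal(classify_extranormal(p))$n_extra, 0L)
})

test_that("excluded regions yield missing scores and never extranormal", {
  truth <- small_truth(seed = 36L)
  b <- suppressWarnings(simulate_cohort(truth, n_term = 60L, n_preterm = 20L))
  chart <- fit_reference_charts(b$morphometry,
                                exclude_regions = regs4[1], seed = 1L)
  chart <- adapt_study_offset(chart, b$morphometry, "SYNTH")
  pr <- compute_deviation_scores(chart, b$morphometry)
  ex <- pr[pr$region == regs4[1], ]
  expect_true(all(is.na(ex$score)))
  expect_true(all(ex$label == "missing"))
  expect_identical(sum(count_extranormal(ex)$n_extra), 0L)
})

test_that("study offsets are equivariant under constant shifts", {
  truth <- small_truth(seed = 37L, study_offsets = c(A = 0, B = 0))
  b <- simulate_cohort(truth, n_term = 160L, n_preterm = 0L)
  m <- b$morphometry
  chart <- fit_reference_charts(m[m$study == "A", ], seed = 2L)
  chart <- adapt_study_offset(chart, m, "B")
  u0 <- chart$offsets[["B"]]
  d0 <- compute_deviation_scores(chart, m[m$study == "B", ])$score

  m2 <- m
  shift <- 0.37
  m2$value[m2$study == "B"] <- m2$value[m2$study == "B"] + shift
  chart2 <- adapt_study_offset(chart, m2, "B")
  expect_equal(chart2$offsets[["B"]], u0 + shift, tolerance = 1e-8)
  d1 <- compute_deviation_scores(chart2, m2[m2$study == "B", ])$score
  expect_equal(d1, d0, tolerance = 1e-8)
})

test_that("scoring refuses unsupported ages and unknown studies", {
  truth <- small_truth(seed = 38L)
  b <- simulate_cohort(truth, n_term = 60L, n_preterm = 0L)
  chart <- fit_reference_charts(b$morphometry, seed = 1L)
  chart <- adapt_study_offset(chart, b$morphometry, "SYNTH")
  row <- b$morphometry[1, ]
  row$age <- 60   # far outside the fitted support
  expect_error(compute_deviation_scores(chart, row), row$subject_id)
  row2 <- b$morphometry[1, ]
  row2$study <- "UNKNOWN"
  expect_error(compute_deviation_scores(chart, row2), "offset")
  expect_warning(compute_deviation_scores(chart, row2,
                                          unknown_study = "zero"),
                 "using 0")
})

test_that("charts survive a JSON round trip", {
  fx <- recovery_fixture()
  path <- tempfile(fileext = ".json")
  write_chart(fx$chart, path)
  chart2 <- read_chart(path)
  m <- fx$bundle$morphometry[1:200, ]
  expect_equal(compute_deviation_scores(fx$chart, m)$score,
               compute_deviation_scores(chart2, m)$score,
               tolerance = 1e-12)
})
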