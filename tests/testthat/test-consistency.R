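test_that("strictly decreasing counts give rho = -1", {
  n <- 12L
  lab <- matrix("normal", n, 20)
  for (i in seq_len(n)) lab[i, seq_len(n - i + 1)] <- "infra"
  p <- make_profiles(lab, ga = seq(24, 35, length.out = n))
  res <- extent_vs_ga(p, directions = "infra", B = 0L)
  expect_equal(res$rho, -1)
})

test_that("constant counts yield a missing correlation", {
  lab <- matrix("normal", 12L, 8)
  lab[, 1] <- "infra"
  p <- make_profiles(lab, ga = runif(12, 24, 36))
  res <- suppressWarnings(extent_vs_ga(p, directions = "infra", B = 0L))
  expect_true(is.na(res$rho))
})

test_that("extent_vs_ga agrees with a naive double-loop Spearman", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 30L
    lab <- matrix("normal", n, 10)
    k <- rpois(n, 3)
    for (i in seq_len(n)) lab[i, seq_len(min(k[i], 10))] <- "supra"
    ga <- runif(n, 24, 36)
    p <- make_profiles(lab, ga = ga)
    res <- extent_vs_ga(p, directions = "supra", B = 0L)
    expect_equal(res$rho, naive_spearman(pmin(k, 10), ga),
                 tolerance = 1e-12)
  }
})

test_that("permuted GA gives uniform extent p-values", {
  set.seed(19)
  n <- 60L
  k <- rpois(n, 3)
  ga <- runif(n, 24, 36)
  ps <- vapply(1:500, function(i) {
    ibap:::spearman_test(k, sample(ga))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("GA subgrouping partitions subjects and skips empty bins", {
  lab <- matrix("normal", 20, 6)
  lab[, 1] <- "supra"
  p29 <- make_profiles(lab, ga = rep(29, 20))
  expect_warning(res <- ga_subgroup_overlap(p29), "empty")
  expect_identical(names(res$max_overlap), "GA<=30")

  ga <- runif(20, 24, 36)
  p <- make_profiles(lab, ga = ga)
  r1 <- ga_subgroup_overlap(p, scheme = "cut30")
  r2 <- ga_subgroup_overlap(p, scheme = "clinical")
  expect_identical(sum(tapply(r1$overlap$n, r1$overlap$subgroup, max)), 20L)
  expect_identical(sum(tapply(r2$overlap$n, r2$overlap$subgroup, max)), 20L)
})

test_that("earlier-born subgroup has higher maximal overlap under the default world", {
  fx <- recovery_fixture()
  res <- ga_subgroup_overlap(fx$profiles)
  expect_gt(res$max_overlap["GA<=30"], res$max_overlap["GA>30"])
})

test_that("longitudinal pair selection matches brute-force union logic", {
  set.seed(23)
  lab1 <- matrix(sample(c("infra", "normal", "supra"), 15 * 8, TRUE,
                        prob = c(0.15, 0.7, 0.15)), 15, 8,
                 dimnames = list(sprintf("s%02d", 1:15),
                                 sprintf("r%d", 1:8)))
  lab2 <- matrix(sample(c("infra", "normal", "supra"), 15 * 8, TRUE,
                        prob = c(0.15, 0.7, 0.15)), 15, 8,
                 dimnames = dimnames(lab1))
  p <- rbind(make_profiles(lab1, timepoint = 1L),
             make_profiles(lab2, timepoint = 2L))
  pairs <- select_longitudinal_extranormal(p)
  expect_identical(nrow(pairs), sum(lab1 != "normal" | lab2 != "normal"))
  # subject normal everywhere at both timepoints contributes no pairs
  quiet <- rownames(lab1)[rowSums(lab1 != "normal") +
                            rowSums(lab2 != "normal") == 0]
  expect_false(any(pairs$subject_id %in% quiet))
  # infra at t1 only -> included with t2 label normal
  one <- which(lab1 == "infra" & lab2 == "normal", arr.ind = TRUE)
  if (nrow(one)) {
    row <- pairs[pairs$subject_id == rownames(lab1)[one[1, 1]] &
                   pairs$region == colnames(lab1)[one[1, 2]], ]
    expect_identical(row$label_t1, "infra")
    expect_identical(row$label_t2, "normal")
  }
})

test_that("subjects missing a timepoint are excluded with a message", {
  lab <- matrix("supra", 4, 3, dimnames = list(sprintf("s%d", 1:4), NULL))
  p <- rbind(make_profiles(lab, timepoint = 1L),
             make_profiles(lab[1:3, ], timepoint = 2L))
  expect_message(pairs <- select_longitudinal_extranormal(p), "s4")
  expect_false("s4" %in% pairs$subject_id)
})

test_that("persistence fractions follow their definition", {
  pairs <- data.frame(
    subject_id = "s1", region = sprintf("r%d", 1:6),
    label_t1 = c("infra", "infra", "infra", "supra", "supra", "normal"),
    label_t2 = c("infra", "normal", "supra", "supra", "supra", "infra"))
  # 1 of 3 infra maintained; the infra->supra flip does not count
  expect_equal(persistence_fraction(pairs, "infra"), 100 / 3)
  expect_equal(persistence_fraction(pairs, "supra"), 100)
  expect_warning(
    pf <- persistence_fraction(pairs[pairs$label_t1 == "normal", ],
                               "supra"),
    "no pair")
  expect_true(is.na(pf))
  # identical labels at both timepoints -> 100%
  same <- data.frame(subject_id = "s", region = c("a", "b"),
                     label_t1 = c("infra", "supra"),
                     label_t2 = c("infra", "supra"))
  expect_equal(persistence_fraction(same, "infra"), 100)
})

test_that("ICC(3,1) matches the pre-computed ANOVA oracle", {
  t1 <- c(0.10, 0.40, 0.60, 0.90)
  t2 <- t1 + c(0.02, -0.02, 0.02, -0.02)
  res <- ibap:::icc31(t1, t2)
  # frozen from an independent aov() two-way decomposition
  expect_equal(res$icc, 0.997566909976, tolerance = 1e-10)
  expect_equal(res$p, 7.20083e-05, tolerance = 1e-4)
  # identical scores -> 1; constant shift -> 1 (consistency form)
  expect_equal(ibap:::icc31(t1, t1)$icc, 1)
  expect_equal(ibap:::icc31(t1, t1 + 0.3)$icc, 1)
  # zero between-subject variance -> 0 with flag
  z <- ibap:::icc31(rep(0.5, 6), rep(0.5, 6))
  expect_equal(z$icc, 0)
  expect_match(z$flag, "zero")
  expect_true(is.na(ibap:::icc31(t1[1], t2[1])$icc))
})

test_that("regional ICC reflects generator persistence and stability", {
  fx <- recovery_fixture()
  icc <- regional_icc(fx$profiles[fx$profiles$group == "preterm", ])
  expect_identical(nrow(icc), 34L)
  expect_true(all(icc$icc <= 1))
  expect_gt(median(icc$icc), 0.8)
  # selected-subset and binary variants run and stay bounded
  sel <- regional_icc(fx$profiles[fx$profiles$group == "preterm", ],
                      subset = "selected")
  expect_true(all(sel$icc <= 1, na.rm = TRUE))
})

test_that("ICC increases with the persistence probability", {
  mean_icc <- vapply(c(0.2, 0.6, 0.95), function(pp) {
    mean(vapply(1:15, function(s) {
      truth <- default_ground_truth(seed = 500L + s,
                                    persistence_prob = pp,
                                    stability = 0.3, global_factor = 0)
      b <- simulate_cohort(truth, n_term = 40L, n_preterm = 60L,
                           n_timepoints = 2L)
      pr <- compute_deviation_scores(truth$chart, b$morphometry)
      median(regional_icc(pr[pr$group == "preterm", ])$icc)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) > 0))
})
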