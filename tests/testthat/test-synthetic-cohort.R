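test_that("degenerate extent law injects no extranormal regions", {
  truth <- default_ground_truth(seed = 3L, lambda0 = 0, lambda1 = 0)
  b <- simulate_cohort(truth, n_term = 40L, n_preterm = 30L)
  expect_identical(nrow(b$injections), 0L)
})

test_that("injected counts follow the Poisson extent law (oracle)", {
  # Monte-Carlo oracle: near GA = 30 the mean injected count must sit
  # within 3 SE of lambda(30) = 0.5 + 0.8 * 10 = 8.5 (Poisson variance).
  counts <- c(); lam <- c()
  for (s in 1:5) {
    truth <- default_ground_truth(seed = s)
    b <- simulate_cohort(truth, n_term = 40L, n_preterm = 200L)
    m <- b$morphometry[!duplicated(b$morphometry$subject_id), ]
    pre <- m[m$group == "preterm" & abs(m$ga_weeks - 30) <= 1, ]
    k <- table(factor(b$injections$subject_id[b$injections$timepoint == 1L],
                      levels = pre$subject_id))
    counts <- c(counts, as.integer(k))
    lam <- c(lam, extent_lambda(truth, pre$ga_weeks))
  }
  se <- sqrt(mean(lam) / length(counts))
  expect_lt(abs(mean(counts) - mean(lam)), 3 * se)
  expect_lt(abs(mean(lam) - 8.5), 0.3)   # probe sits at the stated rate
})

test_that("persistence_prob = 1 retains every injection at timepoint 2", {
  truth <- default_ground_truth(seed = 5L, persistence_prob = 1)
  b <- simulate_cohort(truth, n_term = 40L, n_preterm = 40L,
                       n_timepoints = 2L)
  inj <- b$injections
  t1 <- inj[inj$timepoint == 1L, c("subject_id", "region", "direction")]
  t2 <- inj[inj$timepoint == 2L, c("subject_id", "region", "direction")]
  expect_identical(t1[order(t1$subject_id, t1$region), ],
                   t2[order(t2$subject_id, t2$region), ],
                   ignore_attr = TRUE)
})

test_that("identical seed reproduces the bundle bit-exactly", {
  truth <- default_ground_truth(seed = 9L)
  b1 <- simulate_bundle(truth, n_term = 40L, n_preterm = 20L,
                        n_timepoints = 2L)
  b2 <- simulate_bundle(truth, n_term = 40L, n_preterm = 20L,
                        n_timepoints = 2L)
  expect_identical(b1$morphometry, b2$morphometry)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$injections, b2$injections)
})

test_that("marginal calibration: without injection ~90% of scores sit in the body", {
  truth <- default_ground_truth(seed = 21L, lambda0 = 0, lambda1 = 0)
  b <- simulate_cohort(truth, n_term = 150L, n_preterm = 100L)
  sc <- compute_deviation_scores(truth$chart, b$morphometry)
  # cluster-robust check: per-subject body fraction, 99% band on the mean
  # (regions within a subject share the global factor)
  frac <- tapply(sc$score > 0.05 & sc$score < 0.95, sc$subject_id, mean)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.90), qnorm(0.995) * se + 1e-12)
})

test_that("injected counts correlate negatively with GA when lambda1 > 0", {
  neg <- vapply(1:10, function(s) {
    truth <- default_ground_truth(seed = 100L + s)
    b <- simulate_cohort(truth, n_term = 40L, n_preterm = 100L)
    m <- b$morphometry[!duplicated(b$morphometry$subject_id), ]
    pre <- m[m$group == "preterm", ]
    k <- table(factor(b$injections$subject_id, levels = pre$subject_id))
    cor(as.integer(k), pre$ga_weeks, method = "spearman") < 0
  }, logical(1))
  expect_true(all(neg))
})

test_that("noiseless marker genes reproduce their latent map exactly", {
  truth <- default_ground_truth(seed = 2L)
  ex <- simulate_expression(truth, genes_per_type = 3L, noise_sd = 0)
  for (ct in cell_type_names()) {
    for (g in ex$marker_sets[[ct]]) {
      expect_equal(cor(ex$expression[g, ], truth$latent_maps[ct, ],
                       method = "spearman"), 1)
    }
  }
  expect_error(simulate_expression(truth, noise_sd = -1), "nonnegative")
  expect_error(simulate_expression(truth, genes_per_type = 1L), ">= 2")
})

test_that("marker-set averaging beats single genes at recovering the latent map", {
  # averaging-reduces-noise oracle, averaged over seeds
  diffs <- vapply(1:40, function(s) {
    truth <- default_ground_truth(seed = 200L + s)
    ex <- simulate_expression(truth, genes_per_type = 10L, noise_sd = 0.5)
    mean(vapply(cell_type_names(), function(ct) {
      genes <- ex$marker_sets[[ct]]
      lat <- truth$latent_maps[ct, ]
      set_rho <- cor(colMeans(ex$expression[genes, ]), lat,
                     method = "spearman")
      gene_rho <- mean(vapply(genes, function(g) {
        cor(ex$expression[g, ], lat, method = "spearman")
      }, numeric(1)))
      set_rho - gene_rho
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("identical latent vectors give identical aggregated maps (noiseless)", {
  truth <- default_ground_truth(seed = 4L)
  truth$latent_maps["endo", ] <- truth$latent_maps["astro", ]
  ex <- simulate_expression(truth, genes_per_type = 4L, noise_sd = 0)
  maps <- aggregate_marker_sets(normalize_genes(ex$expression),
                                ex$marker_sets)
  expect_equal(cor(maps["astro", ], maps["endo", ], method = "spearman"), 1)
})

test_that("outcome injection is monotone in SES and null under b = 0", {
  truth <- default_ground_truth(seed = 6L,
                                ses_effect = c(a = 0.3, b = 0))
  b <- simulate_bundle(truth, n_term = 200L, n_preterm = 0L)
  sc <- compute_deviation_scores(truth$chart, b$morphometry)
  m <- tapply(sc$score, sc$ses_code, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))

  # b = 0: fitted interaction CI covers zero
  fx <- recovery_fixture()
  truth0 <- default_ground_truth(seed = 8L, ses_effect = c(a = 0.03, b = 0))
  b0 <- simulate_bundle(truth0, n_term = 100L, n_preterm = 120L)
  pr0 <- compute_deviation_scores(truth0$chart, b0$morphometry)
  pre <- pr0[pr0$group == "preterm", ]
  pc <- pc1_summary(pre)
  cnt <- count_extranormal(pre)
  cnt <- cnt[match(names(pc$scores), cnt$subject_id), ]
  mod <- moderation_ga_ses(pc$scores, cnt$ga_weeks, cnt$ses_code,
                           B = 1000L, seed = 2L)
  expect_true(mod$interaction$ci[1] <= 0 && mod$interaction$ci[2] >= 0)
})

test_that("zero cognition coupling leaves cognition unrelated to deviations", {
  rej <- vapply(1:60, function(s) {
    truth <- default_ground_truth(seed = 300L + s, cognition_coupling = 0)
    b <- simulate_bundle(truth, n_term = 40L, n_preterm = 40L)
    sc <- compute_deviation_scores(truth$chart, b$morphometry)
    cnt <- count_extranormal(sc)
    msum <- tapply(sc$score, sc$subject_id, mean)
    cg <- cnt$cognition[match(names(msum), cnt$subject_id)]
    ibap:::spearman_test(msum, cg)$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.05 + 2.6 * sqrt(0.05 * 0.95 / 60))
})

test_that("preterm GA < 37 <= term GA and covariates are complete", {
  fx <- recovery_fixture()
  m <- fx$bundle$morphometry
  expect_true(all(m$ga_weeks[m$group == "preterm"] < 37))
  expect_true(all(m$ga_weeks[m$group == "term"] >= 37))
  expect_false(anyNA(m[, c("age", "sex", "group", "ga_weeks", "study")]))
  expect_error(simulate_cohort(fx$truth, n_term = 10L), "n_term")
})

test_that("Poisson draws above the region count are clipped with a warning", {
  truth <- default_ground_truth(seed = 13L, lambda0 = 80, lambda1 = 0)
  expect_warning(b <- simulate_cohort(truth, n_term = 40L, n_preterm = 5L),
                 "clipped")
  k <- table(b$injections$subject_id)
  expect_true(all(k <= 34L))
  expect_true(any(k == 34L))
})
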