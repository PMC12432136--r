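# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Default-world bundle with two timepoints, fitted chart and scored
# profiles; drives the recovery tests and acceptance criterion 3.
recovery_fixture <- function() {
  fixture("recovery", function() {
    truth <- default_ground_truth(seed = 1L)
    bundle <- simulate_bundle(truth, n_term = 300L, n_preterm = 150L,
                              n_timepoints = 2L)
    chart <- fit_reference_charts(bundle$morphometry, seed = 1L)
    chart <- adapt_study_offset(chart, bundle$morphometry, "SYNTH")
    profiles <- compute_deviation_scores(chart, bundle$morphometry)
    # same truth and seed, cohort stage only (before the environment stage
    # shifts values; identical injections) and scored under the generating
    # chart, so the binomial persistence oracle applies exactly
    cohort <- simulate_cohort(truth, n_term = 300L, n_preterm = 150L,
                              n_timepoints = 2L)
    profiles_cohort <- compute_deviation_scores(truth$chart,
                                                cohort$morphometry)
    list(truth = truth, bundle = bundle, chart = chart,
         profiles = profiles, profiles_cohort = profiles_cohort)
  })
}

# Fabricate a minimal classified profiles table from a labels matrix
# (subjects x regions); scores are placed consistently with the labels.
make_profiles <- function(labels, ga = NULL, timepoint = 1L,
                          group = "preterm", measure = "CTh") {
  n <- nrow(labels); regs <- colnames(labels)
  if (is.null(regs)) regs <- paste0("r", seq_len(ncol(labels)))
  ids <- rownames(labels)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (is.null(ga)) ga <- rep(30, n)
  score_of <- c(infra = 0.01, normal = 0.5, supra = 0.99)
  df <- data.frame(
    subject_id = rep(ids, each = length(regs)),
    study = "SYNTH", timepoint = timepoint,
    age = 26, sex = "M", group = group,
    ga_weeks = rep(ga, each = length(regs)),
    measure = measure,
    region = rep(regs, n),
    score = ifelse(as.vector(t(labels)) == "missing", NA_real_,
                   score_of[as.vector(t(labels))]),
    stringsAsFactors = FALSE
  )
  classify_extranormal(df)
}

# Independent Spearman oracle: explicit midrank Pearson formula.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All permutations of 1..n (for exhaustive spin oracles).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}
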