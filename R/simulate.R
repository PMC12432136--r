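## Synthetic multi-cohort generator. Every draw is a deterministic function
## of truth$seed, so a bundle is bit-exactly reproducible.

#' Simulate a synthetic term/preterm cohort with known ground truth
#'
#' Term subjects are drawn from the ground-truth normative family at their
#' age and sex (study offset added), so their deviation scores are uniform
#' by construction. Each preterm subject receives `K ~ Poisson(lambda(GA))`
#' injected extranormal target regions, sampled without replacement with
#' probability proportional to a softmax of the GA-interpolated mixture of
#' latent cell maps; target values are placed in the distribution tails
#' (CDF value uniform in (0, 0.05) or (0.95, 1)). Non-target regions are
#' drawn from the full normative family. Across two timepoints the
#' underlying Gaussian percentile of non-target regions is correlated at
#' `truth$stability` (longitudinal anatomical stability) and each injected
#' target is retained with probability `truth$persistence_prob`.
#'
#' @param truth An [`ibap_truth`][default_ground_truth] object.
#' @param n_term,n_preterm Subject counts (sex balanced within group;
#'   `n_term` must give at least 20 subjects per sex so charts remain
#'   fittable).
#' @param n_timepoints 1 or 2.
#' @param age_range Age-at-scan interval at the first timepoint.
#' @param age_unit `"years"` or `"pmweeks"` (see [age_to_days()]).
#' @param t2_gap Gap between timepoints, in `age_unit` units.
#' @param measure Measure label for the generated values.
#' @return A list of class `ibap_bundle` with elements `morphometry` (tidy
#'   table), `injections` (ground-truth target regions with directions),
#'   `centroids`, `truth`, and `expression`/`marker_sets` slots filled by
#'   [simulate_expression()].
#' @export
simulate_cohort <- function(truth, n_term = 300L, n_preterm = 150L,
                            n_timepoints = 1L,
                            age_range = c(25.5, 28.9),
                            age_unit = "years", t2_gap = 2,
                            measure = "CTh") {
  stopifnot(inherits(truth, "ibap_truth"), n_timepoints %in% c(1L, 2L))
  if (n_term < 40L) stopf("need n_term >= 40 (20 per sex stratum)")
  regions <- truth$region_names
  nreg <- length(regions)
  studies <- names(truth$study_offsets)

  with_seed(derive_seed(truth$seed, 1L), {
    n <- n_term + n_preterm
    subjects <- data.frame(
      subject_id = c(sprintf("T%04d", seq_len(n_term)),
                     if (n_preterm) sprintf("P%04d", seq_len(n_preterm))),
      group = rep(c("term", "preterm"), c(n_term, n_preterm)),
      sex = c(rep_len(c("M", "F"), n_term),
              if (n_preterm) rep_len(c("M", "F"), n_preterm)),
      # period-4 interleaving keeps study balanced within sex strata
      study = rep_len(rep(studies, each = 2L), n),
      stringsAsFactors = FALSE
    )
    subjects$ga_weeks <- ifelse(subjects$group == "term",
                                stats::runif(n, 37, 42),
                                stats::runif(n, 23.5, 36.5))
    subjects$age1 <- stats::runif(n, age_range[1], age_range[2])

    # Latent Gaussian percentile per subject x region: a stable per-subject
    # global factor (share `global_factor` of variance, shared across
    # regions) plus a regional component stable across timepoints with
    # correlation `stability`. Marginals remain standard normal, so
    # deviation scores stay uniform when no injection occurs.
    z_base <- matrix(stats::rnorm(n * nreg), n, nreg)
    g_subj <- stats::rnorm(n)
    vg <- truth$global_factor
    rho <- truth$stability

    # Injected targets at timepoint 1 (preterm only).
    inj <- vector("list", n)
    pre_idx <- which(subjects$group == "preterm")
    clipped <- 0L
    for (i in pre_idx) {
      k <- stats::rpois(1L, extent_lambda(truth, subjects$ga_weeks[i]))
      if (k > nreg) { clipped <- clipped + 1L; k <- nreg }
      if (k > 0L) {
        pr <- placement_probs(truth, subjects$ga_weeks[i])
        tgt <- sample.int(nreg, k, prob = pr)
        dirs <- ifelse(stats::runif(k) < truth$direction_supra,
                       "supra", "infra")
        inj[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                               region_idx = tgt, direction = dirs,
                               stringsAsFactors = FALSE)
      }
    }
    if (clipped > 0L) {
      warnf("%d preterm subject(s) had Poisson draws above %d regions; clipped",
            clipped, nreg)
    }

    rows <- list()
    inj_rows <- list()
    for (tp in seq_len(n_timepoints)) {
      eps <- matrix(stats::rnorm(n * nreg), n, nreg)
      z <- sqrt(vg) * g_subj + sqrt(1 - vg) *
        (sqrt(rho) * z_base + sqrt(1 - rho) * eps)
      p <- stats::pnorm(z)
      # timepoint-2 retention of timepoint-1 targets
      for (i in pre_idx) {
        tgt <- inj[[i]]
        if (is.null(tgt)) next
        if (tp == 2L) {
          keep <- stats::runif(nrow(tgt)) < truth$persistence_prob
          tgt <- tgt[keep, , drop = FALSE]
          if (!nrow(tgt)) next
        }
        lo <- stats::runif(nrow(tgt), 0, 0.05)
        hi <- stats::runif(nrow(tgt), 0.95, 1)
        p[i, tgt$region_idx] <- ifelse(tgt$direction == "supra", hi, lo)
        tgt$timepoint <- tp
        inj_rows[[length(inj_rows) + 1L]] <- tgt
      }
      age <- subjects$age1 + (tp - 1L) * t2_gap
      days <- age_to_days(age, age_unit)
      df <- data.frame(
        subject_id = rep(subjects$subject_id, each = nreg),
        study = rep(subjects$study, each = nreg),
        timepoint = tp,
        age = rep(age, each = nreg),
        age_unit = age_unit,
        sex = rep(subjects$sex, each = nreg),
        group = rep(subjects$group, each = nreg),
        ga_weeks = rep(subjects$ga_weeks, each = nreg),
        ses = NA_character_, ses_code = NA_real_,
        piri = NA_real_, cognition = NA_real_,
        region = rep(regions, n),
        measure = measure,
        stringsAsFactors = FALSE
      )
      par <- chart_params(truth$chart, df$region, df$sex,
                          rep(days, each = nreg))
      pv <- as.vector(t(p))
      df$value <- qshash(pv, par$mu, par$sigma, par$nu) +
        unname(truth$study_offsets[df$study])
      rows[[tp]] <- df
    }
    morph <- do.call(rbind, rows)
    rownames(morph) <- NULL
    injections <- if (length(inj_rows)) {
      out <- do.call(rbind, inj_rows)
      out$region <- regions[out$region_idx]
      out$region_idx <- NULL
      rownames(out) <- NULL
      out[, c("subject_id", "timepoint", "region", "direction")]
    } else {
      data.frame(subject_id = character(0), timepoint = integer(0),
                 region = character(0), direction = character(0))
    }
    bundle <- list(morphometry = morph, injections = injections,
                   expression = NULL, marker_sets = NULL,
                   centroids = truth$geometry, truth = truth)
    class(bundle) <- "ibap_bundle"
    bundle
  })
}

#' Simulate marker-gene expression from latent cell-type maps
#'
#' Each of the 8 cell types owns a latent spatially autocorrelated 34-region
#' abundance map (stored in the ground truth); each marker gene equals its
#' type's latent map plus i.i.d. Gaussian noise.
#'
#' @param truth Ground truth (see [default_ground_truth()]).
#' @param genes_per_type Marker genes per cell type (>= 2).
#' @param noise_sd Nonnegative noise standard deviation.
#' @return List with `expression` (gene x region matrix) and `marker_sets`
#'   (named list of gene ids per cell type).
#' @export
simulate_expression <- function(truth, genes_per_type = 10L, noise_sd = 0.5) {
  stopifnot(inherits(truth, "ibap_truth"))
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (genes_per_type < 2L) stopf("genes_per_type must be >= 2")
  types <- rownames(truth$latent_maps)
  nreg <- ncol(truth$latent_maps)
  with_seed(derive_seed(truth$seed, 3L), {
    mats <- lapply(types, function(ct) {
      g <- matrix(rep(truth$latent_maps[ct, ], each = genes_per_type),
                  genes_per_type, nreg)
      g + matrix(stats::rnorm(genes_per_type * nreg, 0, noise_sd),
                 genes_per_type, nreg)
    })
    expr <- do.call(rbind, mats)
    ids <- unlist(lapply(types, function(ct) {
      sprintf("%s_g%02d", toupper(ct), seq_len(genes_per_type))
    }))
    dimnames(expr) <- list(ids, colnames(truth$latent_maps))
    marker_sets <- stats::setNames(
      lapply(types, function(ct) grep(paste0("^", toupper(ct), "_g"),
                                      ids, value = TRUE)),
      types)
    list(expression = expr, marker_sets = marker_sets)
  })
}

#' Inject social environment and cognition outcomes into a bundle
#'
#' Assigns socio-economic status (SES) multinomially (low/middle/high coded
#' 1/2/3), adds the global deviation shift
#' `delta = a * ses + b * ses * (40 - GA)` (in within-region SD units) to
#' all regional values, simulates the Parent-Infant Relationship Index
#' (PIRI, 0 good - 8 poor, worse on average at lower SES), and couples a
#' cognition score (mean 100, residual SD 10) to the standardised
#' per-subject mean deviation score under the generating chart.
#'
#' @param bundle An [`ibap_bundle`][simulate_cohort].
#' @param truth The ground truth used to generate `bundle`.
#' @return The bundle with `ses`, `ses_code`, `piri`, `cognition` filled and
#'   regional values shifted.
#' @export
simulate_outcomes <- function(bundle, truth = bundle$truth) {
  stopifnot(inherits(bundle, "ibap_bundle"))
  morph <- bundle$morphometry
  ids <- unique(morph$subject_id)
  n <- length(ids)
  with_seed(derive_seed(truth$seed, 2L), {
    ses_code <- sample.int(3L, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    ses <- c("low", "middle", "high")[ses_code]
    piri <- stats::rbinom(n, 8L, stats::plogis(-0.6 - 0.35 * (ses_code - 2)))
    idx <- match(morph$subject_id, ids)
    morph$ses <- ses[idx]
    morph$ses_code <- ses_code[idx]
    morph$piri <- piri[idx]

    a <- truth$ses_effect["a"]; b <- truth$ses_effect["b"]
    delta <- a * morph$ses_code + b * morph$ses_code * (40 - morph$ga_weeks)
    par <- chart_params(truth$chart, morph$region, morph$sex, mt_days(morph))
    morph$value <- morph$value + delta * par$sigma

    # Cognition coupled to the mean deviation score at timepoint 1 under the
    # generating chart.
    t1 <- morph[morph$timepoint == 1L, , drop = FALSE]
    sc <- compute_deviation_scores(truth$chart, t1)
    msum <- tapply(sc$score, sc$subject_id, mean, na.rm = TRUE)
    z <- as.numeric(scale(msum[ids]))
    if (all(is.na(z))) z <- rep(0, n)
    cognition <- 100 + truth$cognition_coupling * z + stats::rnorm(n, 0, 10)
    morph$cognition <- cognition[idx]
  })
  bundle$morphometry <- morph
  bundle
}

#' Generate a complete synthetic bundle (cohort, expression, outcomes)
#'
#' Convenience wrapper chaining [simulate_cohort()], [simulate_expression()]
#' and [simulate_outcomes()].
#'
#' @inheritParams simulate_cohort
#' @inheritParams simulate_expression
#' @return A fully populated `ibap_bundle`.
#' @export
simulate_bundle <- function(truth, n_term = 300L, n_preterm = 150L,
                            n_timepoints = 1L, age_range = c(25.5, 28.9),
                            age_unit = "years", t2_gap = 2,
                            measure = "CTh",
                            genes_per_type = 10L, noise_sd = 0.5) {
  bundle <- simulate_cohort(truth, n_term = n_term, n_preterm = n_preterm,
                            n_timepoints = n_timepoints,
                            age_range = age_range, age_unit = age_unit,
                            t2_gap = t2_gap, measure = measure)
  ex <- simulate_expression(truth, genes_per_type = genes_per_type,
                            noise_sd = noise_sd)
  bundle$expression <- ex$expression
  bundle$marker_sets <- ex$marker_sets
  simulate_outcomes(bundle, truth)
}

#' @export
print.ibap_bundle <- function(x, ...) {
  m <- x$morphometry
  cat("ibap synthetic bundle\n")
  cat(sprintf("  subjects: %d (%d term, %d preterm), timepoints: %d\n",
              length(unique(m$subject_id)),
              length(unique(m$subject_id[m$group == "term"])),
              length(unique(m$subject_id[m$group == "preterm"])),
              length(unique(m$timepoint))))
  cat(sprintf("  rows: %d, regions: %d, measure: %s\n", nrow(m),
              length(unique(m$region)),
              paste(unique(m$measure), collapse = ", ")))
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d genes x %d regions\n",
                nrow(x$expression), ncol(x$expression)))
  }
  invisible(x)
}

#' Write a bundle's components to plain-text files
#'
#' Writes `morphometry.csv`, `expression.csv`, `marker_sets.json`,
#' `centroids.csv`, `injections.csv` and `truth.json` under `dir`.
#'
#' @param bundle An `ibap_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$morphometry, file.path(dir, "morphometry.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$injections, file.path(dir, "injections.csv"),
                   row.names = FALSE)
  write_geometry(bundle$centroids, file.path(dir, "centroids.csv"))
  if (!is.null(bundle$expression)) {
    utils::write.csv(data.frame(gene = rownames(bundle$expression),
                                bundle$expression, check.names = FALSE),
                     file.path(dir, "expression.csv"), row.names = FALSE)
    jsonlite::write_json(bundle$marker_sets,
                         file.path(dir, "marker_sets.json"))
  }
  truth <- bundle$truth
  truth$chart <- unclass(truth$chart)
  truth$chart$offsets <- as.list(truth$chart$offsets)
  truth$latent_maps <- as.data.frame(t(truth$latent_maps))
  truth$geometry <- NULL
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
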