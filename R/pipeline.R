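## Pipeline driver: simulate/ingest -> fit -> adapt -> score ->
## heterogeneity -> consistency -> cell maps -> spin -> plasticity,
## with a JSON run manifest (seeds, parameters, per-file checksums).

#' Default run configuration
#'
#' Thresholds, replication counts and seeds for a full pipeline run.
#' Defaults: extranormal thresholds 0.05/0.95, 1000 spins, 10000 bootstrap
#' replicates for correlation CIs, 5000 for the moderation CI. When
#' `morphometry` is `NULL` the synthetic generator supplies all inputs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @param n_term,n_preterm,n_timepoints Generator sizes (used when no input
#'   paths are given).
#' @param morphometry,expression,marker_sets,centroids Optional input file
#'   paths; all four must be given to run on external data.
#' @param measure Measure to analyse.
#' @param lower,upper Extranormal thresholds.
#' @param n_spins Spin count.
#' @param boot_ci,boot_moderation Bootstrap replicate counts.
#' @param exclude_regions Regions to drop from charts and all downstream
#'   stages.
#' @return Named list (class `ibap_config`).
#' @export
default_config <- function(out_dir = "ibap_run", seed = 7L,
                           n_term = 300L, n_preterm = 150L,
                           n_timepoints = 2L,
                           morphometry = NULL, expression = NULL,
                           marker_sets = NULL, centroids = NULL,
                           measure = "CTh",
                           lower = 0.05, upper = 0.95,
                           n_spins = 1000L,
                           boot_ci = 10000L, boot_moderation = 5000L,
                           exclude_regions = character(0)) {
  stopifnot(lower > 0, upper < 1, lower < upper)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_term = n_term, n_preterm = n_preterm,
              n_timepoints = n_timepoints,
              morphometry = morphometry, expression = expression,
              marker_sets = marker_sets, centroids = centroids,
              measure = measure, lower = lower, upper = upper,
              n_spins = n_spins, boot_ci = boot_ci,
              boot_moderation = boot_moderation,
              exclude_regions = exclude_regions)
  class(cfg) <- c("ibap_config", "list")
  cfg
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of [default_config()] fields.
#' @return `ibap_config` list with defaults filled in.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  stopifnot(cfg$lower > 0, cfg$upper < 1, cfg$lower < cfg$upper)
  cfg
}

#' Run the full IBAP pipeline
#'
#' Executes every stage on either a synthetic bundle (default) or external
#' inputs, writes all stage outputs as plain CSV/JSON under
#' `config$out_dir`, and finishes with a manifest recording package
#' version, configuration, per-stage seeds and MD5 checksums of every
#' output file. Re-running with the same configuration reproduces the
#' outputs bit-exactly. On a stage failure, outputs written so far are
#' moved under a `failed/` prefix and the error names the stage.
#'
#' @param config An [`ibap_config`][default_config].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out, name)
    if (is.matrix(obj)) {
      utils::write.csv(data.frame(id = rownames(obj), obj,
                                  check.names = FALSE),
                       path, row.names = FALSE)
    } else if (is.data.frame(obj)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      faildir <- file.path(out, "failed")
      dir.create(faildir, showWarnings = FALSE)
      for (f in written) {
        file.rename(f, file.path(faildir, basename(f)))
      }
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  seeds <- list(simulate = derive_seed(config$seed, 101L),
                fit = derive_seed(config$seed, 102L),
                spin = derive_seed(config$seed, 103L),
                boot = derive_seed(config$seed, 104L))

  ## ingest / simulate -------------------------------------------------
  external <- !is.null(config$morphometry)
  bundle <- stage("simulate", {
    if (external) {
      list(morphometry = read_morphometry(config$morphometry),
           expression = read_expression(config$expression),
           marker_sets = read_marker_sets(config$marker_sets),
           centroids = read_geometry(config$centroids))
    } else {
      truth <- default_ground_truth(seed = seeds$simulate)
      b <- simulate_bundle(truth, n_term = config$n_term,
                           n_preterm = config$n_preterm,
                           n_timepoints = config$n_timepoints,
                           measure = config$measure)
      emit(b$morphometry, "morphometry.csv")
      emit(b$injections, "injections.csv")
      b
    }
  })
  morph <- bundle$morphometry

  ## fit + adapt + score ------------------------------------------------
  chart <- stage("fit-normative", {
    ch <- fit_reference_charts(
      morph, measure = config$measure,
      exclude_regions = config$exclude_regions, seed = seeds$fit)
    for (s in unique(morph$study)) ch <- adapt_study_offset(ch, morph, s)
    emit(unclass_chart_json(ch), "chart.json")
    ch
  })
  profiles <- stage("score", {
    pr <- compute_deviation_scores(chart, morph, lower = config$lower,
                                   upper = config$upper)
    emit(as.data.frame(pr)[, c("subject_id", "study", "timepoint",
                               "measure", "region", "score", "label")],
         "profiles.csv")
    pr
  })

  ## heterogeneity ------------------------------------------------------
  stage("heterogeneity", {
    emit(group_average_dysmaturation(morph, measure = config$measure),
         "group_average.csv")
    ov <- rbind(overlap_percentages(profiles, direction = "either"),
                overlap_percentages(profiles, direction = "infra"),
                overlap_percentages(profiles, direction = "supra"))
    emit(ov, "overlap.csv")
    bm <- binarize_profiles(
      profiles[profiles$group == "preterm", , drop = FALSE])
    sim <- suppressMessages(profile_similarity(bm))
    emit(sim$matrix, "similarity_matrix.csv")
    emit(data.frame(subject_id = names(sim$mean),
                    mean_similarity = unname(sim$mean)),
         "similarity_means.csv")
    NULL
  })

  ## consistency --------------------------------------------------------
  stage("consistency", {
    emit(extent_vs_ga(profiles, B = config$boot_ci, seed = seeds$boot),
         "extent_vs_ga.csv")
    gs <- ga_subgroup_overlap(profiles)
    emit(gs$overlap, "ga_subgroup_overlap.csv")
    if (config$n_timepoints == 2L) {
      pairs <- suppressMessages(select_longitudinal_extranormal(profiles))
      emit(pairs, "longitudinal_pairs.csv")
      emit(data.frame(
        direction = c("infra", "supra"),
        pct = c(suppressWarnings(persistence_fraction(pairs, "infra")),
                suppressWarnings(persistence_fraction(pairs, "supra")))),
        "persistence.csv")
      emit(regional_icc(profiles), "icc.csv")
    }
    NULL
  })

  ## cell maps + spin ----------------------------------------------------
  maps <- stage("cellmaps", {
    m <- cell_type_maps(bundle$expression, bundle$marker_sets)
    emit(m, "cell_maps.csv")
    m
  })
  stage("spin", {
    geom <- bundle$centroids
    geom <- geom[!(geom$region %in% config$exclude_regions), , drop = FALSE]
    schedule <- build_spin_schedule(geom, n_spins = config$n_spins,
                                    seed = seeds$spin)
    sc <- subject_cellmap_correlations(
      profiles, maps, schedule, group = "preterm")
    emit(sc$rho, "cellmap_rho.csv")
    emit(sc$p_spin, "cellmap_pspin.csv")
    emit(cell_alignment_vs_ga(sc$rho, sc$subjects$ga_weeks,
                              B = config$boot_ci, seed = seeds$boot),
         "cell_alignment_vs_ga.csv")
    NULL
  })

  ## plasticity / outcomes ----------------------------------------------
  stage("plasticity", {
    pre <- profiles[profiles$group == "preterm" &
                      profiles$timepoint == 1L, , drop = FALSE]
    pc <- pc1_summary(pre)
    emit(data.frame(region = names(pc$loadings),
                    loading = unname(pc$loadings)), "pc1_loadings.csv")
    emit(data.frame(subject_id = names(pc$scores),
                    pc1 = unname(pc$scores)), "pc1_scores.csv")
    counts <- count_extranormal(pre)
    counts <- counts[match(names(pc$scores), counts$subject_id), ]
    have_env <- all(c("ses_code", "piri", "cognition") %in% names(counts)) &&
      any(is.finite(counts$ses_code))
    if (have_env) {
      vars <- list(ses = counts$ses_code, piri = counts$piri,
                   cognition = counts$cognition,
                   n_infra = counts$n_infra)
      emit(env_outcome_correlations(pc$scores, vars, B = config$boot_ci,
                                    seed = seeds$boot),
           "env_correlations.csv")
      mod <- moderation_ga_ses(pc$scores, counts$ga_weeks,
                               counts$ses_code,
                               B = config$boot_moderation,
                               seed = seeds$boot)
      emit(list(interaction = mod$interaction,
                conditional = mod$conditional, n = mod$n,
                alternative = mod$alternative), "moderation.json")
    }
    NULL
  })

  ## manifest -----------------------------------------------------------
  manifest <- list(
    package = as.character(utils::packageVersion("ibap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    seeds = seeds,
    checksums = as.list(tools::md5sum(sort(written)))
  )
  names(manifest$checksums) <- basename(sort(written))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_chart_json <- function(chart) {
  obj <- unclass(chart)
  obj$offsets <- as.list(obj$offsets)
  obj
}
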