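## Normative chart fitting, study-offset adaptation and deviation scoring.
##
## A chart stores, per (region, sex), the coefficients of
##   mu(t)       = b0 + b1 t + ... (polynomial of degree df_location)
##   log sigma(t) = g0 + g1 t + ...            (degree df_scale)
##   nu           = constant skewness
## on the standardised log-age axis t = (log(days since conception) -
## center) / scale, plus per-study additive location offsets, the fitted age
## support and an excluded-region mask.

new_chart <- function(coef, family, center, scale, df_location, df_scale,
                      support, offsets = numeric(0),
                      excluded = character(0), age_tol = 0.02,
                      measure = NA_character_) {
  chart <- list(coef = coef, family = family, center = center, scale = scale,
                df_location = as.integer(df_location),
                df_scale = as.integer(df_scale),
                support = as.numeric(support), offsets = offsets,
                excluded = excluded, age_tol = age_tol, measure = measure)
  class(chart) <- "ibap_chart"
  chart
}

#' @export
print.ibap_chart <- function(x, ...) {
  cat(sprintf("ibap normative chart (%s family)\n", x$family))
  cat(sprintf("  regions: %d fitted, %d excluded\n",
              length(unique(x$coef$region)), length(x$excluded)))
  cat(sprintf("  age support: %.0f-%.0f days since conception\n",
              x$support[1], x$support[2]))
  if (length(x$offsets)) {
    cat("  study offsets:",
        paste(sprintf("%s = %+.4f", names(x$offsets), x$offsets),
              collapse = ", "), "\n")
  }
  invisible(x)
}

chart_t <- function(chart, days) (log(days) - chart$center) / chart$scale

poly_basis <- function(t, degree) {
  vapply(0:degree, function(k) t^k, numeric(length(t)))
}

# Evaluate polynomial with coefficients `co` at t, linearly extended beyond
# [t_lo, t_hi] (first-order Taylor at the nearer boundary).
poly_eval_extend <- function(co, t, t_lo, t_hi) {
  deg <- length(co) - 1L
  tb <- pmin(pmax(t, t_lo), t_hi)
  val <- drop(poly_basis(tb, deg) %*% co)
  if (deg >= 1L) {
    dco <- co[-1L] * seq_len(deg)
    dval <- drop(poly_basis(tb, deg - 1L) %*% dco)
    val <- val + dval * (t - tb)
  }
  val
}

# Per-observation (mu, sigma, nu) for aligned vectors region/sex/days.
chart_params <- function(chart, region, sex, days) {
  t <- chart_t(chart, days)
  tb <- chart_t(chart, chart$support)
  key <- paste(region, sex)
  co <- chart$coef
  idx <- match(key, paste(co$region, co$sex))
  if (anyNA(idx)) {
    stopf("no chart parameters for: %s",
          paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  bcols <- paste0("b", 0:chart$df_location)
  gcols <- paste0("g", 0:chart$df_scale)
  n <- length(idx)
  mu <- numeric(n); ls <- numeric(n)
  for (g in split(seq_len(n), idx)) {
    i <- idx[g[1]]
    mu[g] <- poly_eval_extend(as.numeric(co[i, bcols]), t[g], tb[1], tb[2])
    ls[g] <- poly_eval_extend(as.numeric(co[i, gcols]), t[g], tb[1], tb[2])
  }
  list(mu = mu, sigma = exp(ls), nu = co$nu[idx],
       converged = co$converged[idx])
}

required_mt_cols <- function() {
  c("subject_id", "study", "timepoint", "age", "sex", "group", "ga_weeks",
    "region", "measure", "value")
}

mt_days <- function(data) {
  unit <- if ("age_unit" %in% names(data)) data$age_unit else "years"
  unit <- rep_len(unit, nrow(data))
  ifelse(unit == "pmweeks", data$age * 7, 280 + data$age * 365.25)
}

#' Fit simplified normative reference charts on term-born data
#'
#' Fits, per region and sex, a sinh-arcsinh location-scale-skew model with
#' the location a polynomial (default quadratic) and the log scale a
#' polynomial (default linear) in standardised log-age, by numerical maximum
#' likelihood with random restarts. Only `group == "term"` rows enter the
#' fit. Regions whose fit does not converge in any sex stratum are flagged
#' and added to the excluded mask: their deviation scores are undefined
#' downstream and no subject can be extranormal there.
#'
#' @param data Morphometry table (see [read_morphometry()]) containing
#'   term-born rows for one measure.
#' @param measure Measure to fit (default the single measure present).
#' @param family `"shash"` or `"gaussian"` (skewness fixed at 0).
#' @param df_location Polynomial degree of the location curve.
#' @param df_scale Polynomial degree of the log-scale curve (0 = constant).
#' @param exclude_regions Regions to exclude a priori (e.g. a missing-chart
#'   analogue such as entorhinal surface area).
#' @param restarts Number of jittered restarts of the optimiser.
#' @param seed Seed for restart jitter.
#' @return An object of class `ibap_chart`.
#' @export
fit_reference_charts <- function(data, measure = NULL,
                                 family = c("shash", "gaussian"),
                                 df_location = 2L, df_scale = 1L,
                                 exclude_regions = character(0),
                                 restarts = 3L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(all(required_mt_cols() %in% names(data)))
  if (is.null(measure)) {
    measure <- unique(data$measure)
    if (length(measure) != 1L) {
      stopf("multiple measures present; pass `measure`")
    }
  }
  data <- data[data$group == "term" & data$measure == measure, , drop = FALSE]
  if (!nrow(data)) stopf("no term-born rows to fit")
  per_sex <- tapply(data$subject_id, data$sex, function(s) length(unique(s)))
  for (sx in c("M", "F")) {
    if (is.na(per_sex[sx]) || per_sex[sx] == 0) {
      stopf("empty sex stratum '%s'", sx)
    }
    if (per_sex[sx] < 20) {
      stopf("need >= 20 term subjects per sex stratum (got %d for '%s')",
            per_sex[sx], sx)
    }
  }
  days <- mt_days(data)
  la <- log(days)
  center <- mean(la)
  scale <- stats::sd(la)
  if (!is.finite(scale) || scale < 1e-12) scale <- 1
  t <- (la - center) / scale

  regions <- sort(unique(data$region))
  regions <- setdiff(regions, exclude_regions)
  bcols <- paste0("b", 0:df_location)
  gcols <- paste0("g", 0:df_scale)
  rows <- list()
  failed <- character(0)
  fix_nu <- family == "gaussian"
  for (reg in regions) {
    ok_region <- TRUE
    reg_rows <- list()
    for (sx in c("M", "F")) {
      sel <- data$region == reg & data$sex == sx
      y <- data$value[sel]
      Xl <- poly_basis(t[sel], df_location)
      Xs <- poly_basis(t[sel], df_scale)
      if (qr(Xl)$rank < ncol(Xl)) {
        stopf("singular age design for region '%s' (%s)", reg, sx)
      }
      fit <- fit_shash_one(y, Xl, Xs, fix_nu, restarts,
                           derive_seed(seed, match(reg, regions) * 2L +
                                         (sx == "F")))
      if (is.null(fit)) { ok_region <- FALSE; break }
      reg_rows[[sx]] <- data.frame(
        region = reg, sex = sx,
        as.list(stats::setNames(fit$beta, bcols)),
        as.list(stats::setNames(fit$gamma, gcols)),
        nu = fit$nu, converged = TRUE, stringsAsFactors = FALSE)
    }
    if (ok_region) {
      rows <- c(rows, reg_rows)
    } else {
      failed <- c(failed, reg)
    }
  }
  if (length(failed)) {
    warnf("non-convergent regions excluded from chart: %s",
          paste(failed, collapse = ", "))
  }
  if (!length(rows)) stopf("no region converged")
  new_chart(
    coef = do.call(rbind, rows), family = family,
    center = center, scale = scale,
    df_location = df_location, df_scale = df_scale,
    support = range(days),
    offsets = numeric(0),
    excluded = union(exclude_regions, failed),
    measure = measure
  )
}

# ML fit of one region-sex stratum; NULL on failure.
fit_shash_one <- function(y, Xl, Xs, fix_nu, restarts, seed) {
  beta0 <- tryCatch(stats::lm.fit(Xl, y)$coefficients,
                    error = function(e) NULL)
  if (is.null(beta0) || anyNA(beta0)) return(NULL)
  res <- y - drop(Xl %*% beta0)
  s0 <- max(stats::sd(res), 1e-6)
  gamma0 <- c(log(s0), rep(0, ncol(Xs) - 1L))
  p0 <- c(beta0, gamma0, if (!fix_nu) 0)
  best <- NULL
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(k) {
      if (k == 1L) p0 else p0 + stats::rnorm(length(p0), 0, 0.05 * (1 + abs(p0)))
    })
  })
  for (p in starts) {
    fit <- tryCatch(
      stats::optim(p, shash_negll, y = y, Xl = Xl, Xs = Xs, fix_nu = fix_nu,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$convergence != 0) return(NULL)
  kl <- ncol(Xl); ks <- ncol(Xs)
  gamma <- best$par[kl + seq_len(ks)]
  # Predictive small-sample correction: the plug-in ML scale understates the
  # spread of a new observation (df bias of sigma-hat plus unpropagated
  # parameter uncertainty), which deflates tail coverage by O(p/n). Inflate
  # sigma by the standard predictive factor, the analogue of
  # s * sqrt(1 + h) with t_(n-p) quantiles in Gaussian regression.
  n <- length(y)
  p_all <- kl + ks + as.integer(!fix_nu)
  if (n > p_all + 1L) {
    gamma[1L] <- gamma[1L] +
      0.5 * (log(n / (n - p_all)) + log1p(kl / n))
  }
  list(beta = best$par[seq_len(kl)],
       gamma = gamma,
       nu = if (fix_nu) 0 else best$par[kl + ks + 1L])
}

#' Adapt a per-study location offset from term-born data
#'
#' Estimates the additive location shift of a new study as the median of the
#' term-born residuals on the location scale (observed value minus chart
#' location at the subject's age and sex, pooled over regions). Preterm
#' subjects never enter the estimate. The offset plays the role of a random
#' intercept of study; no scale offset is estimated.
#'
#' @param chart A fitted [`ibap_chart`][fit_reference_charts].
#' @param data Morphometry table containing term rows of the study.
#' @param study Study label to adapt.
#' @return The chart with the offset registered in `chart$offsets`.
#' @export
adapt_study_offset <- function(chart, data, study) {
  stopifnot(inherits(chart, "ibap_chart"))
  data <- data[data$study == study &
                 (is.na(chart$measure) | data$measure == chart$measure), ,
               drop = FALSE]
  if (!nrow(data)) stopf("no rows for study '%s'", study)
  term <- data[data$group == "term", , drop = FALSE]
  if (!nrow(term)) stopf("offset requires term-born data (study '%s')", study)
  term <- term[!(term$region %in% chart$excluded), , drop = FALSE]
  if (length(unique(term$subject_id)) < 10) {
    stopf("need >= 10 term subjects from study '%s'", study)
  }
  par <- chart_params(chart, term$region, term$sex, mt_days(term))
  u <- stats::median(term$value - par$mu)
  chart$offsets[study] <- u
  chart
}

#' Compute percentile deviation scores against an adapted chart
#'
#' The deviation score of a subject-region observation is the chart family's
#' CDF value of the observation (minus the study offset) at the subject's
#' age and sex: a number in (0, 1) giving the percentile of the value within
#' the normative range. Scores are classified with
#' [classify_extranormal()] before returning. Excluded regions yield missing
#' scores (label `"missing"`, never extranormal).
#'
#' @param chart A fitted, offset-adapted [`ibap_chart`][fit_reference_charts].
#' @param data Morphometry table to score.
#' @param unknown_study `"error"` to refuse studies without a registered
#'   offset, `"zero"` to use a zero offset with a warning.
#' @param lower,upper Extranormal thresholds (strict), default 0.05/0.95.
#' @return The input rows with `score` and `label` columns appended
#'   (class `ibap_profiles`).
#' @export
compute_deviation_scores <- function(chart, data,
                                     unknown_study = c("error", "zero"),
                                     lower = 0.05, upper = 0.95) {
  stopifnot(inherits(chart, "ibap_chart"))
  unknown_study <- match.arg(unknown_study)
  if (!is.na(chart$measure)) {
    data <- data[data$measure == chart$measure, , drop = FALSE]
  }
  if (!nrow(data)) stopf("no rows to score")
  days <- mt_days(data)
  tol <- chart$age_tol * diff(chart$support)
  bad <- days < chart$support[1] - tol | days > chart$support[2] + tol
  if (any(bad)) {
    stopf("age outside chart support (beyond tolerance) for subject(s): %s",
          paste(unique(data$subject_id[bad]), collapse = ", "))
  }
  u <- rep(0, nrow(data))
  known <- data$study %in% names(chart$offsets)
  if (any(!known)) {
    if (unknown_study == "error") {
      stopf("no study offset registered for: %s",
            paste(unique(data$study[!known]), collapse = ", "))
    }
    warnf("no offset for study(ies) %s; using 0",
          paste(unique(data$study[!known]), collapse = ", "))
  }
  u[known] <- chart$offsets[data$study[known]]

  score <- rep(NA_real_, nrow(data))
  inc <- !(data$region %in% chart$excluded)
  if (any(inc)) {
    par <- chart_params(chart, data$region[inc], data$sex[inc], days[inc])
    s <- pshash(data$value[inc] - u[inc], par$mu, par$sigma, par$nu)
    score[inc] <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  }
  out <- data
  out$score <- score
  classify_extranormal(out, lower = lower, upper = upper)
}

#' Classify deviation scores as infra-, supra- or normal
#'
#' Strict thresholds: a score is `infra` iff `score < lower` and `supra` iff
#' `score > upper`; scores exactly at a threshold are `normal`. Missing
#' scores (excluded regions) are labelled `missing` and are never
#' extranormal.
#'
#' @param profiles Profiles `data.frame` with a `score` column.
#' @param lower,upper Thresholds, default 0.05 and 0.95.
#' @return `profiles` with a `label` column, class `ibap_profiles`.
#' @seealso [count_extranormal()]
#' @export
classify_extranormal <- function(profiles, lower = 0.05, upper = 0.95) {
  stopifnot(is.data.frame(profiles), "score" %in% names(profiles),
            lower > 0, upper < 1, lower < upper)
  s <- profiles$score
  lab <- ifelse(is.na(s), "missing",
                ifelse(s < lower, "infra", ifelse(s > upper, "supra",
                                                 "normal")))
  profiles$label <- lab
  if (!inherits(profiles, "ibap_profiles")) {
    class(profiles) <- c("ibap_profiles", class(profiles))
  }
  attr(profiles, "thresholds") <- c(lower = lower, upper = upper)
  profiles
}

#' Count extranormal regions per subject and timepoint
#'
#' @param profiles Classified profiles (see [classify_extranormal()]).
#' @return `data.frame` with one row per (subject, timepoint, measure) and
#'   columns `n_infra`, `n_supra`, `n_extra`, plus the subject covariates.
#' @export
count_extranormal <- function(profiles) {
  stopifnot(all(c("subject_id", "timepoint", "measure", "label") %in%
                  names(profiles)))
  key <- interaction(profiles$subject_id, profiles$timepoint,
                     profiles$measure, drop = TRUE)
  first <- !duplicated(key)
  keep <- intersect(c("subject_id", "study", "timepoint", "age", "sex",
                      "group", "ga_weeks", "ses", "ses_code", "piri",
                      "cognition", "measure"), names(profiles))
  out <- profiles[first, keep, drop = FALSE]
  out$n_infra <- as.integer(tapply(profiles$label == "infra", key,
                                   sum)[key[first]])
  out$n_supra <- as.integer(tapply(profiles$label == "supra", key,
                                   sum)[key[first]])
  out$n_extra <- out$n_infra + out$n_supra
  rownames(out) <- NULL
  out
}

#' Serialise / restore a normative chart as JSON
#'
#' @param chart An `ibap_chart`.
#' @param path File path.
#' @return `read_chart` returns the chart.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "ibap_chart"))
  obj <- unclass(chart)
  obj$offsets <- as.list(obj$offsets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_chart
#' @export
read_chart <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_chart(coef = as.data.frame(obj$coef, stringsAsFactors = FALSE),
            family = obj$family, center = obj$center, scale = obj$scale,
            df_location = obj$df_location, df_scale = obj$df_scale,
            support = obj$support,
            offsets = unlist(obj$offsets) %||% numeric(0),
            excluded = as.character(obj$excluded %||% character(0)),
            age_tol = obj$age_tol, measure = obj$measure %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
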