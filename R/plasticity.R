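## Deviation summary (PC1), environment/behaviour associations, and the
## SES x GA moderation model.

#' Reshape profiles into a subjects x regions matrix
#'
#' @param profiles Classified profiles (one timepoint/measure).
#' @param value Column to spread (default `"score"`).
#' @return Numeric matrix, rownames subject ids, colnames regions.
#' @export
profiles_matrix <- function(profiles, value = "score") {
  stopifnot(value %in% names(profiles))
  ids <- unique(profiles$subject_id)
  regs <- unique(profiles$region)
  m <- matrix(NA_real_, length(ids), length(regs),
              dimnames = list(ids, regs))
  m[cbind(match(profiles$subject_id, ids),
          match(profiles$region, regs))] <- profiles[[value]]
  m
}

#' First principal component of the deviation-score matrix
#'
#' Column-centred (not scaled: scores already share the (0, 1) percentile
#' scale) singular value decomposition of the subjects x regions deviation
#' matrix. The loading sign is fixed so the mean loading is positive, making
#' scores comparable across linear-algebra backends; with a shared global
#' deviation factor all loadings then come out positive and higher PC1
#' means higher deviation scores overall. Missing-region columns are
#' dropped.
#'
#' @param x Subjects x regions matrix (see [profiles_matrix()]), or
#'   classified profiles to reshape first.
#' @param scale. Standardise columns as well (non-default).
#' @return List of class `ibap_pca`: `scores` (PC1 per subject),
#'   `loadings` (per region, unit norm), `explained` (variance ratio per
#'   component), `center` (column means).
#' @export
pc1_summary <- function(x, scale. = FALSE) {
  if (is.data.frame(x)) x <- profiles_matrix(x)
  keep <- colSums(is.na(x)) == 0L
  x <- x[, keep, drop = FALSE]
  if (!ncol(x)) stopf("no complete region columns")
  if (nrow(x) < ncol(x) + 1L) {
    warnf("fewer subjects (%d) than regions + 1 (%d)", nrow(x),
          ncol(x) + 1L)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (scale.) {
    s <- apply(xc, 2L, stats::sd)
    if (any(s == 0)) stopf("zero-variance region column under scaling")
    xc <- sweep(xc, 2L, s, "/")
  }
  sv <- svd(xc)
  if (max(sv$d) < 1e-12) stopf("deviation matrix has rank 0")
  expl <- sv$d^2 / sum(sv$d^2)
  load1 <- sv$v[, 1L]
  if (mean(load1) < 0) load1 <- -load1
  scores <- drop(xc %*% load1)
  out <- list(scores = stats::setNames(scores, rownames(x)),
              loadings = stats::setNames(load1, colnames(x)),
              explained = expl, center = ctr)
  class(out) <- "ibap_pca"
  out
}

#' @export
print.ibap_pca <- function(x, ...) {
  cat(sprintf("ibap PC summary: %d subjects x %d regions\n",
              length(x$scores), length(x$loadings)))
  cat(sprintf("  PC1 explained variance ratio: %.3f\n", x$explained[1]))
  cat(sprintf("  PC1 loadings all one sign: %s\n",
              all(x$loadings > 0) || all(x$loadings < 0)))
  invisible(x)
}

#' Spearman associations of a deviation summary with external variables
#'
#' Correlates a per-subject summary (typically PC1 scores, the infranormal
#' count, or the mean deviation score) with each supplied variable:
#' Spearman rho, two-sided p, Benjamini-Hochberg adjustment across the
#' pairs tested in this one call, percentile bootstrap 95% CI.
#'
#' @param summary_scores Named numeric vector per subject.
#' @param vars Named list (or data.frame) of numeric vectors aligned with
#'   `summary_scores`.
#' @param B Bootstrap replicates (default 10000; 0 skips CIs).
#' @param seed Bootstrap seed.
#' @return `data.frame` with columns `variable`, `rho`, `p`, `p_fdr`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
env_outcome_correlations <- function(summary_scores, vars, B = 10000L,
                                     seed = 1L) {
  vars <- as.list(vars)
  stopifnot(length(vars) >= 1L, !is.null(names(vars)))
  rows <- lapply(seq_along(vars), function(j) {
    v <- as.numeric(vars[[j]])
    stopifnot(length(v) == length(summary_scores))
    ok <- is.finite(v) & is.finite(summary_scores)
    if (sum(ok) < 10L) stopf("need >= 10 paired values for '%s'",
                             names(vars)[j])
    if (stats::sd(v[ok]) == 0) {
      return(data.frame(variable = names(vars)[j], rho = NA_real_,
                        p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    s <- summary_scores[ok]; vv <- v[ok]
    tst <- spearman_test(s, vv)
    ci <- boot_ci(length(s), function(i) spearman_rho(s[i], vv[i]),
                  B = B, seed = derive_seed(seed, j))
    data.frame(variable = names(vars)[j], rho = tst$rho, p = tst$p,
               ci_lo = ci[1], ci_hi = ci[2], n = tst$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("variable", "rho", "p", "p_fdr", "ci_lo", "ci_hi", "n")]
}

#' Moderation of the gestational-age effect on PC1 by SES
#'
#' Ordinary least squares `PC1 ~ GA + SES + GA:SES` with raw (not
#' mean-centred) predictors and SES on its ordinal numeric code
#' (low = 1, middle = 2, high = 3). The interaction is tested one-sided
#' (directional hypothesis; default `alternative = "less"`, i.e. the GA
#' effect shrinks as SES improves); conditional effects of GA at each
#' observed SES level are `beta_GA + code * beta_int` with pointwise
#' one-sided tests, and a seeded percentile bootstrap CI (default B = 5000)
#' is reported for the interaction.
#'
#' @param pc1 Numeric PC1 scores per subject.
#' @param ga Gestational age (weeks) per subject.
#' @param ses Ordinal SES codes per subject (numeric, e.g. 1/2/3).
#' @param B Bootstrap replicates (default 5000; 0 skips the CI).
#' @param seed Bootstrap seed.
#' @param alternative Direction of the one-sided interaction test.
#' @return List of class `ibap_moderation`: `coefficients` (OLS table),
#'   `interaction` (beta, se, one-sided p, CI), `conditional` (effect of GA
#'   at each SES level with one-sided p), `n`, `alternative`, `seed`.
#' @export
moderation_ga_ses <- function(pc1, ga, ses, B = 5000L, seed = 1L,
                              alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(pc1) & is.finite(ga) & is.finite(ses)
  pc1 <- pc1[ok]; ga <- ga[ok]; ses <- as.numeric(ses[ok])
  levels_ <- sort(unique(ses))
  if (length(levels_) < 2L) stopf("only one SES level present")
  fit <- stats::lm(pc1 ~ ga * ses)
  sm <- summary(fit)$coefficients
  b <- sm["ga:ses", "Estimate"]
  se <- sm["ga:ses", "Std. Error"]
  df <- fit$df.residual
  tval <- b / se
  p_one <- if (alternative == "less") stats::pt(tval, df) else
    stats::pt(tval, df, lower.tail = FALSE)
  ci <- boot_ci(length(pc1), function(i) {
    cf <- tryCatch(stats::coef(stats::lm(pc1[i] ~ ga[i] * ses[i])),
                   error = function(e) rep(NA_real_, 4L))
    cf[length(cf)]
  }, B = B, seed = seed)
  V <- stats::vcov(fit)
  cond <- do.call(rbind, lapply(levels_, function(cc) {
    eff <- stats::coef(fit)["ga"] + cc * b
    vse <- sqrt(V["ga", "ga"] + cc^2 * V["ga:ses", "ga:ses"] +
                  2 * cc * V["ga", "ga:ses"])
    tv <- eff / vse
    p <- stats::pt(tv, df, lower.tail = FALSE)   # H1: positive GA effect
    data.frame(ses = cc, effect = unname(eff), se = vse, p = unname(p))
  }))
  out <- list(coefficients = sm,
              interaction = list(beta = b, se = se, p = unname(p_one),
                                 ci = ci),
              conditional = cond, n = length(pc1),
              alternative = alternative, seed = seed)
  class(out) <- "ibap_moderation"
  out
}

#' @export
print.ibap_moderation <- function(x, ...) {
  cat(sprintf("SES x GA moderation (n = %d)\n", x$n))
  cat(sprintf("  interaction beta = %+.4f (se %.4f), one-sided p = %.4g, 95%% CI [%.4f, %.4f]\n",
              x$interaction$beta, x$interaction$se, x$interaction$p,
              x$interaction$ci[1], x$interaction$ci[2]))
  for (i in seq_len(nrow(x$conditional))) {
    cat(sprintf("  GA effect at SES = %g: %+.4f (p = %.4g)\n",
                x$conditional$ses[i], x$conditional$effect[i],
                x$conditional$p[i]))
  }
  invisible(x)
}
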