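## Extent consistency (counts vs GA) and anatomical location consistency
## (longitudinal persistence, per-region ICC(3,1)).

#' Spearman association of extranormal count with gestational age
#'
#' Per direction (and optionally per study), correlates each preterm
#' subject's number of extranormal regions with gestational age (Spearman,
#' two-sided p via the t approximation), with a percentile bootstrap CI over
#' subject resampling and Benjamini-Hochberg adjustment across all rows
#' tested in the one call.
#'
#' @param profiles Classified profiles (preterm rows are used).
#' @param directions Directions to test, subset of
#'   `c("infra", "supra", "either")`.
#' @param by_study Also stratify by study label?
#' @param timepoint Timepoint (default 1).
#' @param B Bootstrap replicates (default 10000; 0 skips the CI).
#' @param seed Bootstrap seed.
#' @return `data.frame` with columns `study`, `direction`, `rho`, `p`,
#'   `p_fdr`, `ci_lo`, `ci_hi`, `n`.
#' @export
extent_vs_ga <- function(profiles, directions = c("infra", "supra"),
                         by_study = FALSE, timepoint = 1L,
                         B = 10000L, seed = 1L) {
  stopifnot(all(directions %in% c("infra", "supra", "either")))
  counts <- count_extranormal(
    profiles[profiles$group == "preterm" &
               profiles$timepoint == timepoint, , drop = FALSE])
  if (nrow(counts) < 10L) stopf("need >= 10 preterm subjects with GA")
  strata <- if (by_study) split(counts, counts$study) else list(all = counts)
  rows <- list()
  for (sname in names(strata)) {
    d <- strata[[sname]]
    for (dir in directions) {
      y <- switch(dir, infra = d$n_infra, supra = d$n_supra,
                  either = d$n_extra)
      tst <- spearman_test(y, d$ga_weeks)
      ci <- c(NA_real_, NA_real_)
      if (!is.na(tst$rho) && B > 0) {
        ci <- boot_ci(nrow(d),
                      function(i) spearman_rho(y[i], d$ga_weeks[i]),
                      B = B, seed = derive_seed(seed, length(rows)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        study = sname, direction = dir, rho = tst$rho, p = tst$p,
        ci_lo = ci[1], ci_hi = ci[2], n = nrow(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("study", "direction", "rho", "p", "p_fdr", "ci_lo", "ci_hi", "n")]
}

#' Overlap percentages within gestational-age subgroups
#'
#' Splits preterm subjects into earlier/later birth (cut at 30 weeks) or the
#' clinical bins (GA <= 28, 28 < GA <= 32, GA > 32 weeks) and computes
#' per-region overlap percentages within each subgroup, plus each
#' subgroup's maximum per-region overlap.
#'
#' @param profiles Classified profiles (preterm rows are used).
#' @param scheme `"cut30"` or `"clinical"`.
#' @param direction Passed to [overlap_percentages()].
#' @param timepoint Timepoint (default 1).
#' @return List with `overlap` (per-region table with `subgroup` column) and
#'   `max_overlap` (per-subgroup maximum percentage).
#' @export
ga_subgroup_overlap <- function(profiles, scheme = c("cut30", "clinical"),
                                direction = "either", timepoint = 1L) {
  scheme <- match.arg(scheme)
  p <- profiles[profiles$group == "preterm", , drop = FALSE]
  bins <- if (scheme == "cut30") {
    cut(p$ga_weeks, c(-Inf, 30, Inf), labels = c("GA<=30", "GA>30"))
  } else {
    cut(p$ga_weeks, c(-Inf, 28, 32, Inf),
        labels = c("GA<=28", "28<GA<=32", "GA>32"))
  }
  out <- list()
  for (lev in levels(bins)) {
    sub <- p[!is.na(bins) & bins == lev, , drop = FALSE]
    if (!nrow(sub)) {
      warnf("empty gestational-age bin '%s' skipped", lev)
      next
    }
    ov <- overlap_percentages(sub, direction = direction,
                              timepoint = timepoint)
    ov$subgroup <- lev
    out[[lev]] <- ov
  }
  if (!length(out)) stopf("all gestational-age bins empty")
  overlap <- do.call(rbind, out)
  rownames(overlap) <- NULL
  mx <- tapply(overlap$pct, overlap$subgroup, max, na.rm = TRUE)
  list(overlap = overlap, max_overlap = mx[!is.na(mx)])
}

#' Select subject-region pairs extranormal at either timepoint
#'
#' Restricts to subjects observed at both timepoints and returns every
#' (subject, region) pair that is extranormal at a minimum of one of the two
#' timepoints, with the direction label at each.
#'
#' @param profiles Classified profiles with timepoints 1 and 2.
#' @param measure Measure (default the single one present).
#' @return `data.frame` with columns `subject_id`, `region`, `label_t1`,
#'   `label_t2`.
#' @export
select_longitudinal_extranormal <- function(profiles, measure = NULL) {
  if (is.null(measure)) {
    measure <- unique(profiles$measure)
    if (length(measure) != 1L) stopf("multiple measures; pass `measure`")
  }
  p <- profiles[profiles$measure == measure, , drop = FALSE]
  tps <- sort(unique(p$timepoint))
  if (!all(c(1L, 2L) %in% tps)) stopf("need timepoints 1 and 2")
  t1 <- p[p$timepoint == 1L, c("subject_id", "region", "label")]
  t2 <- p[p$timepoint == 2L, c("subject_id", "region", "label")]
  both <- intersect(unique(t1$subject_id), unique(t2$subject_id))
  dropped <- setdiff(union(unique(t1$subject_id), unique(t2$subject_id)),
                     both)
  if (length(dropped)) {
    message(sprintf("%d subject(s) missing a timepoint excluded: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  }
  t1 <- t1[t1$subject_id %in% both, ]
  t2 <- t2[t2$subject_id %in% both, ]
  m <- merge(t1, t2, by = c("subject_id", "region"),
             suffixes = c("_t1", "_t2"))
  ex <- m$label_t1 %in% c("infra", "supra") |
    m$label_t2 %in% c("infra", "supra")
  out <- m[ex, c("subject_id", "region", "label_t1", "label_t2")]
  out <- out[order(out$subject_id, out$region), ]
  rownames(out) <- NULL
  out
}

#' Fraction of extranormal deviations maintained across timepoints
#'
#' Of the selected pairs extranormal in `direction` at timepoint 1, the
#' percentage that are extranormal in the same direction at timepoint 2.
#' A direction flip (infra to supra, or vice versa) counts as not
#' maintained.
#'
#' @param pairs Output of [select_longitudinal_extranormal()].
#' @param direction `"infra"` or `"supra"`.
#' @return Percentage (0-100), or `NA` with a warning if no pair is
#'   extranormal in `direction` at timepoint 1.
#' @export
persistence_fraction <- function(pairs, direction = c("infra", "supra")) {
  direction <- match.arg(direction)
  at1 <- pairs$label_t1 == direction
  if (!any(at1)) {
    warnf("no pair extranormal ('%s') at timepoint 1", direction)
    return(NA_real_)
  }
  100 * sum(at1 & pairs$label_t2 == direction) / sum(at1)
}

# Core ICC(3,1): two-way mixed, single rater, consistency. Timepoints are
# fixed effects, subjects random; computed from the two-way ANOVA mean
# squares, ICC = (MSR - MSE) / (MSR + (k - 1) MSE) with k = 2.
icc31 <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x <- cbind(x1[ok], x2[ok])
  n <- nrow(x); k <- 2L
  if (n < 2L) return(list(icc = NA_real_, p = NA_real_, n = n,
                          flag = "n<2"))
  gm <- mean(x)
  mi <- rowMeans(x)
  mk <- colMeans(x)
  ssr <- k * sum((mi - gm)^2)
  ssc <- n * sum((mk - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) return(list(icc = 0, p = NA_real_, n = n,
                            flag = "zero between-subject variance"))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  fval <- msr / max(mse, .Machine$double.eps)
  p <- stats::pf(fval, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p, n = n, flag = "")
}

#' Per-region ICC(3,1) of deviation scores across two timepoints
#'
#' Quantifies longitudinal stability of continuous deviation scores with the
#' two-way mixed-effects, single-measurement, consistency intraclass
#' correlation (timepoints fixed, subjects random). By default all subjects
#' with both timepoints enter; `subset = "selected"` restricts to subjects
#' extranormal in the region at either timepoint. A binary-agreement
#' variant (`values = "binary"`) is exposed but non-default.
#'
#' @param profiles Classified profiles with timepoints 1 and 2.
#' @param measure Measure (default the single one present).
#' @param subset `"all"` or `"selected"`.
#' @param values `"score"` (continuous, default) or `"binary"`.
#' @return `data.frame` with columns `region`, `icc`, `p`, `n`, `flag`.
#' @export
regional_icc <- function(profiles, measure = NULL,
                         subset = c("all", "selected"),
                         values = c("score", "binary")) {
  subset <- match.arg(subset)
  values <- match.arg(values)
  if (is.null(measure)) {
    measure <- unique(profiles$measure)
    if (length(measure) != 1L) stopf("multiple measures; pass `measure`")
  }
  p <- profiles[profiles$measure == measure, , drop = FALSE]
  v <- if (values == "score") p$score else
    as.numeric(p$label %in% c("infra", "supra"))
  t1 <- p$timepoint == 1L
  t2 <- p$timepoint == 2L
  # excluded regions (all scores missing) drop out of the report
  has_data <- tapply(!is.na(p$score), p$region, any)
  regions <- sort(names(has_data)[has_data])
  rows <- lapply(regions, function(reg) {
    r1 <- p$region == reg & t1
    r2 <- p$region == reg & t2
    ids <- intersect(p$subject_id[r1], p$subject_id[r2])
    x1 <- v[r1][match(ids, p$subject_id[r1])]
    x2 <- v[r2][match(ids, p$subject_id[r2])]
    if (subset == "selected") {
      lab1 <- p$label[r1][match(ids, p$subject_id[r1])]
      lab2 <- p$label[r2][match(ids, p$subject_id[r2])]
      sel <- lab1 %in% c("infra", "supra") | lab2 %in% c("infra", "supra")
      x1 <- x1[sel]; x2 <- x2[sel]
    }
    res <- icc31(x1, x2)
    if (res$n < 5L) {   # too few complete subjects to report
      res$icc <- NA_real_; res$p <- NA_real_; res$flag <- "n<5"
    }
    data.frame(region = reg, icc = res$icc, p = res$p, n = res$n,
               flag = res$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
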