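## Group-average dysmaturation vs individual heterogeneity.

#' Group-average dysmaturation per region
#'
#' Per region, fits ordinary least squares
#' `value ~ group + age + sex` and reports the preterm-vs-term group
#' coefficient with Benjamini-Hochberg adjustment across regions
#' (significance at `p_fdr < 0.05`).
#'
#' @param data Morphometry table with both groups present.
#' @param measure Measure to analyse (default the single one present).
#' @param timepoint Timepoint to analyse (default 1).
#' @return `data.frame` with columns `region`, `beta_group`, `se`, `p`,
#'   `p_fdr`, `significant`, `n`.
#' @export
group_average_dysmaturation <- function(data, measure = NULL,
                                        timepoint = 1L) {
  stopifnot(all(required_mt_cols() %in% names(data)))
  if (is.null(measure)) {
    measure <- unique(data$measure)
    if (length(measure) != 1L) stopf("multiple measures; pass `measure`")
  }
  data <- data[data$measure == measure & data$timepoint == timepoint, ,
               drop = FALSE]
  if (length(unique(data$group)) < 2L) stopf("need both groups present")
  if (anyNA(data$age) || anyNA(data$sex)) stopf("missing covariates")
  data$group <- factor(data$group, levels = c("term", "preterm"))
  regions <- sort(unique(data$region))
  res <- lapply(regions, function(reg) {
    d <- data[data$region == reg, , drop = FALSE]
    X <- stats::model.matrix(~ group + age + sex, d)
    if (qr(X)$rank < ncol(X)) {
      stopf("collinear design in region '%s'", reg)
    }
    fit <- stats::lm(value ~ group + age + sex, data = d)
    co <- summary(fit)$coefficients["grouppreterm", ]
    data.frame(region = reg, beta_group = co[1], se = co[2], p = co[4],
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < 0.05
  rownames(out) <- NULL
  out[, c("region", "beta_group", "se", "p", "p_fdr", "significant", "n")]
}

#' Percentage of subjects extranormal per region
#'
#' For each region, the percentage of subjects in a group carrying an
#' extranormal deviation in the requested direction. Subjects with a missing
#' score in a region are excluded from both numerator and denominator for
#' that region.
#'
#' @param profiles Classified profiles.
#' @param group Group label(s) to tabulate (default all groups present).
#' @param direction `"either"`, `"infra"` or `"supra"`.
#' @param timepoint Timepoint (default 1).
#' @return `data.frame` with columns `region`, `group`, `measure`,
#'   `direction`, `pct`, `n`.
#' @export
overlap_percentages <- function(profiles, group = NULL,
                                direction = c("either", "infra", "supra"),
                                timepoint = 1L) {
  direction <- match.arg(direction)
  p <- profiles[profiles$timepoint == timepoint, , drop = FALSE]
  if (!is.null(group)) p <- p[p$group %in% group, , drop = FALSE]
  if (!nrow(p)) stopf("empty group")
  hit <- switch(direction,
                either = p$label %in% c("infra", "supra"),
                infra = p$label == "infra",
                supra = p$label == "supra")
  ok <- p$label != "missing"
  key <- interaction(p$region, p$group, p$measure, drop = TRUE)
  num <- tapply(hit & ok, key, sum)
  den <- tapply(ok, key, sum)
  parts <- do.call(rbind, strsplit(names(num), ".", fixed = TRUE))
  out <- data.frame(region = parts[, 1], group = parts[, 2],
                    measure = parts[, 3], direction = direction,
                    pct = 100 * as.numeric(num) / pmax(as.numeric(den), 1),
                    n = as.integer(den), stringsAsFactors = FALSE)
  out <- out[out$n > 0L, , drop = FALSE]   # excluded regions drop out
  out <- out[order(out$group, out$region), ]
  rownames(out) <- NULL
  out
}

#' Binarise deviation profiles into a subjects x regions matrix
#'
#' Extranormal deviations (infra- or supranormal) become 1, all others 0.
#' Regions with missing scores for every subject (excluded regions) are
#' dropped; sporadic missing scores become `NA`.
#'
#' @param profiles Classified profiles.
#' @param timepoint Timepoint (default 1).
#' @param measure Measure (default the single one present).
#' @return Integer matrix, rownames subject ids, colnames regions.
#' @export
binarize_profiles <- function(profiles, timepoint = 1L, measure = NULL) {
  p <- profiles[profiles$timepoint == timepoint, , drop = FALSE]
  if (is.null(measure)) {
    measure <- unique(p$measure)
    if (length(measure) != 1L) stopf("multiple measures; pass `measure`")
  }
  p <- p[p$measure == measure, , drop = FALSE]
  if (!nrow(p)) stopf("no rows to binarise")
  b <- ifelse(p$label == "missing", NA_integer_,
              as.integer(p$label %in% c("infra", "supra")))
  ids <- unique(p$subject_id)
  regs <- unique(p$region)
  mat <- matrix(NA_integer_, length(ids), length(regs),
                dimnames = list(ids, regs))
  mat[cbind(match(p$subject_id, ids), match(p$region, regs))] <- b
  keep <- colSums(!is.na(mat)) > 0L
  mat[, keep, drop = FALSE]
}

#' Cross-subject similarity of binarised deviation profiles
#'
#' Pairwise Spearman correlation (midrank ties, equivalent to the phi
#' coefficient on binary data) between subjects' binarised profiles, plus
#' each subject's mean correlation to all others (self excluded). Subjects
#' with zero-variance profiles (e.g. no extranormal region) have undefined
#' correlations: their entries are `NA` and they are excluded from means.
#'
#' @param bmat Binary subjects x regions matrix from [binarize_profiles()].
#' @return List with `matrix` (subject x subject, diagonal `NA`),
#'   `mean` (named per-subject mean correlation) and `zero_variance`
#'   (ids of excluded subjects).
#' @export
profile_similarity <- function(bmat) {
  stopifnot(is.matrix(bmat), nrow(bmat) >= 2L)
  v <- apply(bmat, 1L, function(r) stats::sd(r, na.rm = TRUE))
  zero <- !is.finite(v) | v == 0
  if (all(zero)) stopf("all profiles have zero variance")
  if (sum(!zero) < 2L) stopf("need >= 2 subjects with nonzero variance")
  cm <- suppressWarnings(stats::cor(t(bmat), method = "spearman",
                                    use = "pairwise.complete.obs"))
  cm[zero, ] <- NA_real_
  cm[, zero] <- NA_real_
  diag(cm) <- NA_real_
  means <- rowMeans(cm, na.rm = TRUE)
  means[zero] <- NA_real_
  if (any(zero)) {
    message(sprintf("%d zero-variance profile(s) excluded from similarity: %s",
                    sum(zero),
                    paste(utils::head(rownames(bmat)[zero], 5L),
                          collapse = ", ")))
  }
  list(matrix = cm, mean = means, zero_variance = rownames(bmat)[zero])
}
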