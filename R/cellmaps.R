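## Regional cell-type abundance maps from marker-gene expression.

#' Scaled robust sigmoid normalisation of a gene x region matrix
#'
#' Each gene is normalised across regions with the scaled robust sigmoid:
#' with median `m` and interquartile range `IQR` of the gene's values,
#' `s = 1 / (1 + exp(-(x - m) / (IQR / 1.35)))`, then min-max rescaled to
#' `[0, 1]` per gene. The constant 1.35 is the normal-consistent IQR-to-SD
#' factor. The transform is strictly increasing, so region rankings per
#' gene are preserved; genes with zero IQR are dropped with a warning.
#'
#' @param expr Numeric gene x region matrix (rownames gene ids).
#' @return Normalised matrix (possibly fewer rows).
#' @export
normalize_genes <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n_ok <- rowSums(is.finite(expr))
  if (any(n_ok < 3L)) {
    stopf("genes with < 3 non-missing values: %s",
          paste(utils::head(rownames(expr)[n_ok < 3L], 5L), collapse = ", "))
  }
  med <- apply(expr, 1L, stats::median, na.rm = TRUE)
  iqr <- apply(expr, 1L, stats::IQR, na.rm = TRUE)
  drop <- iqr == 0
  if (any(drop)) {
    warnf("%d gene(s) with zero IQR dropped: %s", sum(drop),
          paste(utils::head(rownames(expr)[drop], 5L), collapse = ", "))
    expr <- expr[!drop, , drop = FALSE]
    med <- med[!drop]; iqr <- iqr[!drop]
  }
  s <- 1 / (1 + exp(-(expr - med) / (iqr / 1.35)))
  mn <- apply(s, 1L, min, na.rm = TRUE)
  mx <- apply(s, 1L, max, na.rm = TRUE)
  (s - mn) / (mx - mn)
}

#' Aggregate marker-gene sets into cell-type abundance maps
#'
#' Per cell type, the unweighted mean over its marker genes' normalised
#' region vectors. Genes absent from the expression matrix are dropped and
#' reported; a cell type with no gene present is an error.
#'
#' @param expr_norm Normalised gene x region matrix
#'   (see [normalize_genes()]).
#' @param marker_sets Named list of gene-id vectors per cell type.
#' @return Cell type x region matrix with attributes `set_sizes` (genes
#'   used) and `dropped` (genes not found).
#' @export
aggregate_marker_sets <- function(expr_norm, marker_sets) {
  stopifnot(is.matrix(expr_norm), is.list(marker_sets),
            !is.null(names(marker_sets)))
  maps <- lapply(names(marker_sets), function(ct) {
    genes <- marker_sets[[ct]]
    present <- genes[genes %in% rownames(expr_norm)]
    if (!length(present)) {
      stopf("no marker gene of cell type '%s' present in expression", ct)
    }
    colMeans(expr_norm[present, , drop = FALSE])
  })
  out <- do.call(rbind, maps)
  rownames(out) <- names(marker_sets)
  attr(out, "set_sizes") <- vapply(names(marker_sets), function(ct) {
    sum(marker_sets[[ct]] %in% rownames(expr_norm))
  }, integer(1))
  attr(out, "dropped") <- lapply(marker_sets, function(g) {
    setdiff(g, rownames(expr_norm))
  })
  out
}

#' Average homologous hemispheres of a 68-region expression matrix
#'
#' Collapses `lh_<region>` / `rh_<region>` column pairs to their arithmetic
#' mean, yielding a bilateral 34-region matrix. If only one hemisphere is
#' present for a region, that hemisphere is used and the region flagged;
#' regions with neither hemisphere are dropped.
#'
#' @param expr Gene x region matrix with `lh_` / `rh_` prefixed columns.
#' @param regions Bilateral region names to produce (default the 34
#'   Desikan-Killiany regions).
#' @return Gene x region matrix with attribute `single_hemisphere` naming
#'   regions backed by one hemisphere only.
#' @export
collapse_hemispheres <- function(expr, regions = dk_region_names()) {
  stopifnot(is.matrix(expr))
  cols <- colnames(expr)
  out <- list()
  single <- character(0)
  for (reg in regions) {
    lh <- paste0("lh_", reg); rh <- paste0("rh_", reg)
    has <- c(lh, rh)[c(lh, rh) %in% cols]
    if (!length(has)) next
    if (length(has) == 1L) single <- c(single, reg)
    out[[reg]] <- rowMeans(expr[, has, drop = FALSE])
  }
  if (!length(out)) stopf("no resolvable hemisphere pairs")
  m <- do.call(cbind, out)
  if (length(single)) {
    warnf("single-hemisphere region(s): %s", paste(single, collapse = ", "))
  }
  attr(m, "single_hemisphere") <- single
  m
}

#' Build cell-type maps from raw expression and marker sets
#'
#' Convenience chain: optional hemisphere collapse, scaled robust sigmoid
#' gene normalisation, marker-set aggregation.
#'
#' @param expr Gene x region matrix (34 bilateral columns, or 68 with
#'   `lh_`/`rh_` prefixes).
#' @param marker_sets Named list of marker gene ids per cell type.
#' @return Cell type x region matrix.
#' @export
cell_type_maps <- function(expr, marker_sets) {
  if (any(grepl("^(lh|rh)_", colnames(expr)))) {
    expr <- collapse_hemispheres(expr)
  }
  aggregate_marker_sets(normalize_genes(expr), marker_sets)
}
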