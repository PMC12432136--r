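## Readers and writers for the tidy interchange formats.

#' Read and validate a morphometry table
#'
#' Tidy long CSV/TSV with one row per (subject, timepoint, region, measure)
#' observation. Required columns: `subject_id, study, timepoint, age, sex,
#' group, ga_weeks, region, measure, value`; optional: `age_unit`
#' (`"years"`/`"pmweeks"`, default years), `ses`, `ses_code`, `piri`,
#' `cognition`. Duplicated observation keys, sexes outside M/F, groups
#' outside term/preterm and non-positive values are errors.
#'
#' @param path File path (`.csv` or tab-separated).
#' @return Validated `data.frame`.
#' @export
read_morphometry <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  validate_morphometry(data)
}

#' @rdname read_morphometry
#' @param data A data.frame to validate in place.
#' @export
validate_morphometry <- function(data) {
  missing_cols <- setdiff(required_mt_cols(), names(data))
  if (length(missing_cols)) {
    stopf("missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bad_sex <- setdiff(unique(data$sex), c("M", "F"))
  if (length(bad_sex)) {
    stopf("sex value(s) outside {M, F}: %s", paste(bad_sex, collapse = ", "))
  }
  bad_grp <- setdiff(unique(data$group), c("term", "preterm"))
  if (length(bad_grp)) {
    stopf("group value(s) outside {term, preterm}: %s",
          paste(bad_grp, collapse = ", "))
  }
  key <- paste(data$subject_id, data$timepoint, data$region, data$measure)
  if (anyDuplicated(key)) {
    stopf("duplicated (subject, timepoint, region, measure) row(s), e.g.: %s",
          key[duplicated(key)][1])
  }
  bad_val <- which(!is.finite(data$value) | data$value <= 0)
  if (length(bad_val)) {
    stopf("non-positive or missing value(s) in row(s): %s",
          paste(utils::head(bad_val, 10L), collapse = ", "))
  }
  pp <- data$group == "preterm" & data$ga_weeks >= 37
  tt <- data$group == "term" & data$ga_weeks < 37
  if (any(pp | tt, na.rm = TRUE)) {
    stopf("group/GA mismatch (preterm requires GA < 37, term GA >= 37) in %d row(s)",
          sum(pp | tt, na.rm = TRUE))
  }
  data
}

#' Write deviation profiles to tidy CSV
#'
#' @param profiles Classified profiles.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  cols <- intersect(c("subject_id", "study", "timepoint", "measure",
                      "region", "score", "label"), names(profiles))
  utils::write.csv(as.data.frame(profiles)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read marker-gene sets from JSON
#'
#' Expected shape: `{"astro": ["GENE1", ...], ...}`.
#'
#' @param path JSON file path.
#' @return Named list of character vectors.
#' @export
read_marker_sets <- function(path) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(sets, as.character)
}

#' Read a gene x region expression matrix from CSV
#'
#' First column must hold gene ids; remaining columns are regions.
#'
#' @param path CSV file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
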