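# Readers and writers for the tabular formats the pipeline touches.
# All files are UTF-8 with a mandatory header row; missing values (missing
# beta, undetermined Ct) are encoded as empty fields so they survive
# CSV/TSV round trips unambiguously. Row and column order is preserved
# exactly as given.

#' Write / read a beta-value matrix as TSV
#'
#' The on-disk layout is tab-separated with a first column `cpg_id`
#' (`cg`-prefixed probe ids) and one column per sample. Missing beta values
#' are empty fields. `read_beta_matrix()` validates identifiers and value
#' bounds; errors name the offending CpG and sample.
#'
#' @param beta Numeric matrix (CpG x sample) with row and column names;
#'   non-missing values must lie in `[0, 1]`.
#' @param path File path.
#' @return `read_beta_matrix()` returns the numeric matrix;
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  if (!is.matrix(beta) || is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort_format("beta must be a matrix with CpG row names and sample column names")
  }
  df <- data.frame(cpg_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL, fileEncoding = "UTF-8")
  require_columns(df, "cpg_id", "beta matrix")
  if (ncol(df) < 2L) abort_format("beta matrix has no sample columns")
  cpg <- df[[1L]]
  dup <- unique(cpg[duplicated(cpg)])
  if (length(dup)) {
    abort_format(sprintf("duplicate CpG id(s): %s", oxford(utils::head(dup, 5))))
  }
  samples <- names(df)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    abort_format(sprintf("duplicate sample id(s): %s", oxford(dup_s)))
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
              dimnames = list(cpg, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    empty <- !nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      abort_format(sprintf(
        "non-numeric beta value '%s' at CpG %s, sample %s",
        raw[i], cpg[i], samples[j]))
    }
    out <- !is.na(val) & (val < 0 | val > 1)
    if (any(out)) {
      i <- which(out)[1L]
      abort_format(sprintf(
        "beta value %s out of [0, 1] at CpG %s, sample %s",
        raw[i], cpg[i], samples[j]))
    }
    val[empty] <- NA_real_
    m[, j] <- val
  }
  m
}

#' Write / read a sample annotation table as CSV
#'
#' Columns: `sample_id`, `group` (one of the five tissue groups), optional
#' `subtype` free text. Unknown group tokens are rejected with the list of
#' allowed values.
#'
#' @param annotation Data frame with `sample_id`, `group` and optionally
#'   `subtype`.
#' @param path File path.
#' @return `read_sample_annotation()` returns the validated data frame.
#' @export
write_sample_annotation <- function(annotation, path) {
  require_columns(annotation, c("sample_id", "group"), "sample annotation")
  write.csv(annotation, path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_annotation
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("sample_id", "group"), "sample annotation")
  if (!"subtype" %in% names(df)) df$subtype <- ""
  bad <- !df$group %in% TISSUE_GROUPS
  if (any(bad)) {
    i <- which(bad)[1L]
    abort_format(sprintf(
      "row %d (sample %s): unknown group '%s'; allowed groups are: %s",
      i, df$sample_id[i], df$group[i], oxford(TISSUE_GROUPS)))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    abort_format(sprintf("duplicate sample annotation row(s) for: %s",
                         oxford(utils::head(dup, 5))))
  }
  df[, c("sample_id", "group", "subtype")]
}

#' Cross-validate a beta matrix against its sample annotation
#'
#' @param beta Beta matrix as returned by [read_beta_matrix()].
#' @param annotation Annotation as returned by [read_sample_annotation()].
#' @return Invisibly, the character vector of annotated sample ids, in
#'   matrix column order.
#' @export
validate_annotation <- function(beta, annotation) {
  unannotated <- setdiff(colnames(beta), annotation$sample_id)
  if (length(unannotated)) {
    abort_format(sprintf("sample(s) in matrix without annotation: %s",
                         oxford(utils::head(unannotated, 10))))
  }
  invisible(colnames(beta))
}

#' Write / read a qMSP plate export as CSV
#'
#' Columns: `well`, `sample_id`, `target`, `role` (one of `unknown`,
#' `standard`, `pos_ctrl`, `neg_ctrl_wga`, `neg_ctrl_water`), `replicate`
#' (1-3), `ct` (empty field = undetermined) and `known_quantity` (true
#' template quantity for standard and positive-control wells, empty
#' otherwise). Sample-target combinations loading with fewer than three
#' replicate wells are accepted; a note is recorded in the `io_warnings`
#' attribute so the downstream QC ledger can pick it up.
#'
#' @param plate Data frame of wells.
#' @param path File path.
#' @return `read_qmsp_plate()` returns the validated data frame with an
#'   `io_warnings` character attribute.
#' @export
write_qmsp_plate <- function(plate, path) {
  require_columns(plate, c("well", "sample_id", "target", "role", "replicate",
                           "ct"), "qMSP plate")
  write.csv(plate, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_qmsp_plate
#' @export
read_qmsp_plate <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("well", "sample_id", "target", "role", "replicate",
                        "ct"), "qMSP plate")
  bad_role <- !df$role %in% PLATE_ROLES
  if (any(bad_role)) {
    i <- which(bad_role)[1L]
    abort_format(sprintf(
      "well %s: unknown role '%s'; allowed roles are: %s",
      df$well[i], df$role[i], oxford(PLATE_ROLES)))
  }
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (any(is.na(rep_num) | rep_num < 1L | rep_num > 3L)) {
    i <- which(is.na(rep_num) | rep_num < 1L | rep_num > 3L)[1L]
    abort_format(sprintf("well %s: replicate index '%s' not in 1..3",
                         df$well[i], df$replicate[i]))
  }
  df$replicate <- rep_num
  empty <- !nzchar(trimws(df$ct))
  ct <- suppressWarnings(as.numeric(df$ct))
  bad_ct <- !empty & is.na(ct)
  if (any(bad_ct)) {
    i <- which(bad_ct)[1L]
    abort_format(sprintf("well %s: Ct value '%s' is not numeric or empty",
                         df$well[i], df$ct[i]))
  }
  out <- !is.na(ct) & (ct <= 0 | ct >= 60)
  if (any(out)) {
    i <- which(out)[1L]
    abort_format(sprintf("well %s: Ct value %s outside (0, 60)",
                         df$well[i], df$ct[i]))
  }
  ct[empty] <- NA_real_
  df$ct <- ct
  if ("known_quantity" %in% names(df)) {
    df$known_quantity <- suppressWarnings(as.numeric(df$known_quantity))
  } else {
    df$known_quantity <- NA_real_
  }

  warnings <- character(0)
  unk <- df[df$role == "unknown", , drop = FALSE]
  if (nrow(unk)) {
    counts <- table(paste(unk$sample_id, unk$target, sep = " / "))
    short <- names(counts)[counts < 3L]
    if (length(short)) {
      warnings <- sprintf("incomplete triplicate (%d of 3 wells) for %s",
                          counts[short], short)
    }
  }
  attr(df, "io_warnings") <- warnings
  df
}

#' Write / read a patient survival table as CSV
#'
#' The table carries one row per patient with marker levels,
#' clinicopathological covariates, follow-up time in months and the
#' biochemical-recurrence event flag. Rows with non-positive follow-up time
#' are rejected as degenerate unless `allow_degenerate = TRUE`.
#'
#' @param table Data frame with at least `patient_id`, `time_months`,
#'   `event`.
#' @param path File path.
#' @param allow_degenerate Accept rows with `time_months <= 0` (all-censored
#'   degenerate cohorts); default `FALSE`.
#' @return `read_survival_table()` returns the validated data frame.
#' @export
write_survival_table <- function(table, path) {
  require_columns(table, c("patient_id", "time_months", "event"),
                  "survival table")
  write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survival_table
#' @export
read_survival_table <- function(path, allow_degenerate = FALSE) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  require_columns(df, c("patient_id", "time_months", "event"),
                  "survival table")
  if (!is.numeric(df$time_months) || any(is.na(df$time_months))) {
    abort_format("time_months must be numeric and non-missing")
  }
  if (!all(df$event %in% c(0, 1))) {
    i <- which(!df$event %in% c(0, 1))[1L]
    abort_format(sprintf("row %d (patient %s): event must be 0 or 1",
                         i, df$patient_id[i]))
  }
  if (!allow_degenerate && any(df$time_months <= 0)) {
    i <- which(df$time_months <= 0)[1L]
    abort_format(sprintf(
      "row %d (patient %s): degenerate follow-up time %s <= 0",
      i, df$patient_id[i], df$time_months[i]))
  }
  df
}
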