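# CpG candidate-selection cascade: blood pre-filter, two search strings,
# candidate summary statistics.
#
# All "beta > c" comparisons and all "more than X%" bounds are strict, so a
# CpG sitting exactly at an exclusion bound is retained. Missing beta values
# are excluded from both numerator and denominator (per-CpG complete case).

#' Thresholds of the discovery cascade
#'
#' Default values implement the published cascade: the blood pre-filter
#' removes CpGs with detectable methylation (beta > 0.2) in more than 1% of
#' peripheral-blood samples; search string 1 (pan-cancer candidates) selects
#' CpGs hypermethylated (beta > 0.5) in more than 80% of prostate-cancer
#' samples and excludes CpGs with beta > 0.2 in more than 19% of normal
#' prostate samples; search string 2 (PCa-specific candidates) selects CpGs
#' with beta > 0.5 in more than 60% of prostate-cancer samples and excludes
#' CpGs with beta > 0.2 in more than 8% of other-cancer samples or in more
#' than 30% of normal prostate samples.
#'
#' @param beta_detect Detectable-methylation beta cutoff (default 0.2).
#' @param beta_hyper Hypermethylation beta cutoff (default 0.5).
#' @param blood_max_frac Maximum tolerated fraction of blood samples above
#'   `beta_detect` (default 0.01).
#' @param s1_pca_min_frac,s1_normal_max_frac String-1 bounds (0.80, 0.19).
#' @param s2_pca_min_frac,s2_othercancer_max_frac,s2_normal_max_frac
#'   String-2 bounds (0.60, 0.08, 0.30).
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(beta_detect = 0.2, beta_hyper = 0.5,
                              blood_max_frac = 0.01,
                              s1_pca_min_frac = 0.80,
                              s1_normal_max_frac = 0.19,
                              s2_pca_min_frac = 0.60,
                              s2_othercancer_max_frac = 0.08,
                              s2_normal_max_frac = 0.30) {
  t <- list(beta_detect = beta_detect, beta_hyper = beta_hyper,
            blood_max_frac = blood_max_frac,
            s1_pca_min_frac = s1_pca_min_frac,
            s1_normal_max_frac = s1_normal_max_frac,
            s2_pca_min_frac = s2_pca_min_frac,
            s2_othercancer_max_frac = s2_othercancer_max_frac,
            s2_normal_max_frac = s2_normal_max_frac)
  for (nm in c("beta_detect", "beta_hyper")) {
    if (!is_scalar_number(t[[nm]]) || t[[nm]] <= 0 || t[[nm]] >= 1) {
      abort_config(sprintf("%s must be in (0, 1)", nm))
    }
  }
  for (nm in setdiff(names(t), c("beta_detect", "beta_hyper"))) {
    if (!is_scalar_number(t[[nm]]) || t[[nm]] < 0 || t[[nm]] > 1) {
      abort_config(sprintf("%s must be in [0, 1]", nm))
    }
  }
  structure(t, class = "filter_thresholds")
}

#' Fraction of values strictly above a cutoff
#'
#' The primitive every cascade rule uses: the number of non-missing values
#' strictly greater than `cutoff`, divided by the number of non-missing
#' values.
#'
#' @param values Numeric vector of beta values, possibly with `NA`.
#' @param cutoff Scalar cutoff.
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_above(c(0.25, 0.15, NA, 0.30), 0.2)  # 2/3
#' fraction_above(c(0.2, 0.2), 0.2)              # 0: strictly above
#' @export
fraction_above <- function(values, cutoff) {
  den <- sum(!is.na(values))
  if (den == 0L) {
    abort_degenerate("fraction_above: all values missing (undefined denominator)")
  }
  sum(values > cutoff, na.rm = TRUE) / den
}

# Row-wise fraction_above over a matrix; errors name the first CpG whose
# denominator vanishes.
.frac_above_rows <- function(m, cutoff) {
  den <- rowSums(!is.na(m))
  if (any(den == 0L)) {
    abort_degenerate(sprintf(
      "all values missing for CpG %s within one group (undefined denominator)",
      rownames(m)[which(den == 0L)[1L]]))
  }
  rowSums(m > cutoff, na.rm = TRUE) / den
}

.group_cols <- function(beta, annotation, group) {
  ids <- annotation$sample_id[annotation$group == group]
  intersect(colnames(beta), ids)
}

.require_group <- function(beta, annotation, group) {
  cols <- .group_cols(beta, annotation, group)
  if (!length(cols)) {
    abort_config(sprintf("no samples annotated as '%s' in the matrix", group))
  }
  cols
}

#' Blood pre-filter
#'
#' Retains a CpG iff the fraction of peripheral-blood samples with
#' detectable methylation (beta > `beta_detect`) is at most
#' `blood_max_frac`; "more than 1%" removal is strict, so exactly 1% is
#' retained.
#'
#' @param beta Beta matrix (CpG x sample).
#' @param annotation Sample annotation data frame.
#' @param thresholds A [filter_thresholds()].
#' @return Character vector of retained CpG ids, in matrix row order.
#' @export
blood_filter <- function(beta, annotation, thresholds = filter_thresholds()) {
  cols <- .require_group(beta, annotation, "peripheral_blood")
  frac <- .frac_above_rows(beta[, cols, drop = FALSE], thresholds$beta_detect)
  rownames(beta)[frac <= thresholds$blood_max_frac]
}

#' Search string 1: pan-cancer candidates
#'
#' Selects a CpG iff beta > `beta_hyper` in more than `s1_pca_min_frac` of
#' prostate-cancer samples and beta > `beta_detect` in at most
#' `s1_normal_max_frac` of normal prostate samples.
#'
#' @inheritParams blood_filter
#' @param cpgs CpG ids to consider (normally the blood-filter survivors).
#' @return Character vector of selected CpG ids.
#' @export
select_pan_cancer <- function(beta, annotation,
                              thresholds = filter_thresholds(),
                              cpgs = rownames(beta)) {
  pca <- .require_group(beta, annotation, "prostate_cancer")
  np <- .require_group(beta, annotation, "normal_prostate")
  m <- beta[cpgs, , drop = FALSE]
  sel <- .frac_above_rows(m[, pca, drop = FALSE], thresholds$beta_hyper) >
    thresholds$s1_pca_min_frac &
    .frac_above_rows(m[, np, drop = FALSE], thresholds$beta_detect) <=
    thresholds$s1_normal_max_frac
  cpgs[sel]
}

#' Search string 2: PCa-specific candidates
#'
#' Selects a CpG iff beta > `beta_hyper` in more than `s2_pca_min_frac` of
#' prostate-cancer samples, beta > `beta_detect` in at most
#' `s2_othercancer_max_frac` of other-cancer samples, and beta >
#' `beta_detect` in at most `s2_normal_max_frac` of normal prostate samples.
#'
#' @inheritParams select_pan_cancer
#' @return Character vector of selected CpG ids.
#' @export
select_pca_specific <- function(beta, annotation,
                                thresholds = filter_thresholds(),
                                cpgs = rownames(beta)) {
  pca <- .require_group(beta, annotation, "prostate_cancer")
  oc <- .require_group(beta, annotation, "other_cancer")
  np <- .require_group(beta, annotation, "normal_prostate")
  m <- beta[cpgs, , drop = FALSE]
  sel <- .frac_above_rows(m[, pca, drop = FALSE], thresholds$beta_hyper) >
    thresholds$s2_pca_min_frac &
    .frac_above_rows(m[, oc, drop = FALSE], thresholds$beta_detect) <=
    thresholds$s2_othercancer_max_frac &
    .frac_above_rows(m[, np, drop = FALSE], thresholds$beta_detect) <=
    thresholds$s2_normal_max_frac
  cpgs[sel]
}

#' Summary statistics for candidate CpGs
#'
#' For each candidate: the median beta per tissue group over non-missing
#' values, the median difference (prostate-cancer median minus the maximum
#' of the other four group medians), and a two-sided Mann-Whitney test of
#' prostate cancer versus normal prostate. A candidate passes the effect
#' criterion when the median difference exceeds `min_median_diff` and the
#' Mann-Whitney p-value is below `max_p`. CpGs for which some group has no
#' non-missing values are flagged `incomplete` rather than dropped.
#'
#' @inheritParams blood_filter
#' @param cpgs Non-empty character vector of candidate CpG ids.
#' @param min_median_diff Median-difference bound (default 0.30, strict).
#' @param max_p Mann-Whitney p-value bound (default 0.001, strict).
#' @return Data frame with one row per candidate.
#' @export
summarize_candidates <- function(beta, annotation, cpgs,
                                 min_median_diff = 0.30, max_p = 0.001) {
  if (!length(cpgs)) abort_config("candidate set must be non-empty")
  group_cols <- lapply(TISSUE_GROUPS, .group_cols, beta = beta,
                       annotation = annotation)
  names(group_cols) <- TISSUE_GROUPS

  rows <- lapply(cpgs, function(cg) {
    vals <- lapply(group_cols, function(cols) {
      v <- beta[cg, cols]
      v[!is.na(v)]
    })
    meds <- vapply(vals, function(v) {
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    incomplete <- any(vapply(vals, length, integer(1)) == 0L)
    others <- meds[setdiff(TISSUE_GROUPS, "prostate_cancer")]
    med_diff <- if (incomplete) NA_real_ else
      meds[["prostate_cancer"]] - max(others)
    if (length(vals$prostate_cancer) && length(vals$normal_prostate)) {
      mw <- mann_whitney(vals$prostate_cancer, vals$normal_prostate)
      mw_u <- mw$statistic; mw_p <- mw$p_value
    } else {
      mw_u <- NA_real_; mw_p <- NA_real_
    }
    passes <- !incomplete && !is.na(mw_p) &&
      med_diff > min_median_diff && mw_p < max_p
    data.frame(cpg_id = cg,
               median_peripheral_blood = meds[["peripheral_blood"]],
               median_normal_prostate = meds[["normal_prostate"]],
               median_prostate_cancer = meds[["prostate_cancer"]],
               median_other_normal = meds[["other_normal"]],
               median_other_cancer = meds[["other_cancer"]],
               median_difference = med_diff,
               mw_u = mw_u, mw_p = mw_p,
               incomplete = incomplete,
               passes_effect_criterion = passes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full discovery cascade
#'
#' Executes the stages in order: blood pre-filter, then search strings 1 and
#' 2 in parallel on the survivors, then candidate summaries on the union of
#' the two candidate sets. Stage bookkeeping satisfies
#' `in - excluded = out` at every stage.
#'
#' @inheritParams blood_filter
#' @param min_median_diff,max_p Effect-criterion bounds passed to
#'   [summarize_candidates()].
#' @return A `filter_report` object: stage counts, the retained/selected CpG
#'   sets (`blood_retained`, `pan_cancer`, `pca_specific`, `union`), the
#'   candidate summary table, and the thresholds used.
#' @examples
#' sim <- generate_beta_matrix(simulation_config(
#'   group_sizes = c(peripheral_blood = 60, normal_prostate = 10,
#'                   prostate_cancer = 20, other_normal = 20,
#'                   other_cancer = 60),
#'   cpgs_per_archetype = 5, seed = 11))
#' rep <- run_discovery(sim$beta, sim$annotation)
#' rep$stages
#' @export
run_discovery <- function(beta, annotation, thresholds = filter_thresholds(),
                          min_median_diff = 0.30, max_p = 0.001) {
  for (g in TISSUE_GROUPS) .require_group(beta, annotation, g)
  validate_annotation(beta, annotation)

  n_total <- nrow(beta)
  blood_retained <- blood_filter(beta, annotation, thresholds)
  s1 <- select_pan_cancer(beta, annotation, thresholds, cpgs = blood_retained)
  s2 <- select_pca_specific(beta, annotation, thresholds,
                            cpgs = blood_retained)
  cand_union <- rownames(beta)[rownames(beta) %in% union(s1, s2)]

  stages <- data.frame(
    stage = c("blood_filter", "string1_pan_cancer", "string2_pca_specific"),
    n_in = c(n_total, length(blood_retained), length(blood_retained)),
    n_excluded = c(n_total - length(blood_retained),
                   length(blood_retained) - length(s1),
                   length(blood_retained) - length(s2)),
    n_out = c(length(blood_retained), length(s1), length(s2)),
    stringsAsFactors = FALSE)

  summaries <- if (length(cand_union)) {
    summarize_candidates(beta, annotation, cand_union,
                         min_median_diff = min_median_diff, max_p = max_p)
  } else {
    summarize_empty()
  }
  summaries$source_string <- if (nrow(summaries)) {
    ifelse(summaries$cpg_id %in% s1 & summaries$cpg_id %in% s2, "both",
           ifelse(summaries$cpg_id %in% s1, "pan-cancer", "PCa-specific"))
  } else character(0)

  structure(list(stages = stages,
                 blood_retained = blood_retained,
                 pan_cancer = s1,
                 pca_specific = s2,
                 union = cand_union,
                 summaries = summaries,
                 thresholds = thresholds),
            class = "filter_report")
}

# zero-row summary table with the full column layout
summarize_empty <- function() {
  data.frame(cpg_id = character(0),
             median_peripheral_blood = numeric(0),
             median_normal_prostate = numeric(0),
             median_prostate_cancer = numeric(0),
             median_other_normal = numeric(0),
             median_other_cancer = numeric(0),
             median_difference = numeric(0),
             mw_u = numeric(0), mw_p = numeric(0),
             incomplete = logical(0),
             passes_effect_criterion = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("candidates: %d pan-cancer, %d PCa-specific, %d in union\n",
              length(x$pan_cancer), length(x$pca_specific), length(x$union)))
  if (nrow(x$summaries)) {
    cat(sprintf("%d of %d candidates pass the effect criterion\n",
                sum(x$summaries$passes_effect_criterion, na.rm = TRUE),
                nrow(x$summaries)))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A `filter_report` from [run_discovery()].
#' @param path File path for the JSON output.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  if (!inherits(report, "filter_report")) {
    abort_config("report must be a filter_report")
  }
  payload <- list(stages = report$stages,
                  pan_cancer = report$pan_cancer,
                  pca_specific = report$pca_specific,
                  union = report$union,
                  summaries = report$summaries,
                  thresholds = unclass(report$thresholds))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
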