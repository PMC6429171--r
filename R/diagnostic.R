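# Diagnostic comparison of marker levels between malignant and
# non-malignant groups: Mann-Whitney rank test, ROC/AUC, sensitivity at
# fixed specificity, and detection-based sensitivity/specificity.

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j`,
#' counting ties as 1/2 (the U statistic of `x` over `y`). The p-value is
#' exact -- full enumeration of all arrangements of the combined sample,
#' which handles ties exactly -- when `n_x + n_y <= 12` (or when
#' `exact = TRUE`), and otherwise uses the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y Numeric vectors of marker levels, both non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact iff `length(x) + length(y) <= 12`.
#' @return List of class `mw_test`: `statistic` (U of `x` over `y`),
#'   `p_value`, `method`, `n_x`, `n_y`.
#' @examples
#' mann_whitney(c(2, 3, 4), c(1, 2, 3))$statistic  # 7 of 9 pairs
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort_degenerate("mann_whitney: both groups must be non-empty")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  combined <- c(x, y)
  r <- rank(combined)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (is.null(exact)) exact <- n <= 12L
  if (exact) {
    idx_sets <- combn(n, nx)
    obs_dev <- abs(u - mu)
    u_all <- apply(idx_sets, 2L, function(idx) {
      sum(r[idx]) - nx * (nx + 1) / 2
    })
    p <- mean(abs(u_all - mu) >= obs_dev - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(combined)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n_x = nx, n_y = ny),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g (n = %d vs %d), p = %.4g [%s]\n",
              x$statistic, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Orientation is fixed as "higher level = positive (malignant)", matching
#' hypermethylation markers; an inverted marker shows up as `auc < 0.5` and
#' is reported, never silently flipped. Candidate thresholds are the
#' midpoints between consecutive distinct sorted levels plus `-Inf`/`Inf`
#' sentinels; a case is called positive when its level is strictly greater
#' than the threshold. The AUC is the trapezoidal area, identical (to
#' numerical precision) to the Mann-Whitney U of positives over negatives
#' divided by `n_pos * n_neg`.
#'
#' @param levels Numeric marker levels.
#' @param labels Logical/0-1 vector: `TRUE`/1 = positive class.
#' @return A `roc_curve` object: `points` (data frame of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
roc <- function(levels, labels) {
  if (length(levels) != length(labels)) {
    abort_config("levels and labels must have the same length")
  }
  keep <- !is.na(levels) & !is.na(labels)
  levels <- levels[keep]
  labels <- as.logical(labels[keep])
  pos <- sort(levels[labels]); neg <- sort(levels[!labels])
  if (!length(pos) || !length(neg)) {
    abort_degenerate("roc: both classes must be present")
  }
  v <- sort(unique(levels))
  thresholds <- c(-Inf, if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2, Inf)
  # counts strictly above each threshold; thresholds never coincide with
  # observed levels except the sentinels, where the strict rule is exact
  sens <- (length(pos) - findInterval(thresholds, pos)) / length(pos)
  spec <- findInterval(thresholds, neg) / length(neg)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)
  structure(list(points = data.frame(threshold = thresholds,
                                     sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Sensitivity at a fixed specificity floor
#'
#' The maximum sensitivity among thresholds whose specificity is at least
#' `min_specificity`. The specificity bound is a floor, not a nearest
#' point, which is conservative for sensitivity claims; the `Inf` sentinel
#' guarantees a threshold with specificity 1 always exists.
#'
#' @param curve A [roc()] result.
#' @param min_specificity Specificity floor (default 0.95).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(curve, min_specificity = 0.95) {
  if (!inherits(curve, "roc_curve")) abort_config("curve must be a roc_curve")
  ok <- curve$points$specificity >= min_specificity
  max(curve$points$sensitivity[ok])
}

#' Detection-based sensitivity and specificity
#'
#' A sample is called marker-positive iff its normalized methylation level
#' is strictly greater than zero. Only QC-passing sample-targets enter;
#' sensitivity is the positive-call rate among malignant samples and
#' specificity the negative-call rate among non-malignant samples.
#'
#' @param results qMSP results data frame (from [process_plate()]`$results`)
#'   restricted to one marker target, with `sample_id`,
#'   `normalized_level`, `qc_status`.
#' @param labels Named logical vector (names = sample ids): `TRUE` =
#'   malignant.
#' @return List with `sensitivity`, `specificity`, `n_malignant`,
#'   `n_benign`.
#' @export
detection_performance <- function(results, labels) {
  require_columns(results, c("sample_id", "normalized_level", "qc_status"),
                  "qMSP results")
  res <- results[results$qc_status == "pass" &
                   results$sample_id %in% names(labels), , drop = FALSE]
  lab <- labels[res$sample_id]
  detected <- res$normalized_level > 0
  n_mal <- sum(lab); n_ben <- sum(!lab)
  if (n_mal == 0L || n_ben == 0L) {
    abort_degenerate(
      "detection_performance: need QC-passing samples in both classes")
  }
  list(sensitivity = sum(detected & lab) / n_mal,
       specificity = sum(!detected & !lab) / n_ben,
       n_malignant = n_mal, n_benign = n_ben)
}
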