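# Prognostic evaluation for the biochemical-recurrence (BCR) endpoint:
# horizon dichotomization via ROC, Kaplan-Meier, log-rank, Cox proportional
# hazards, Harrell's concordance, stepwise backward selection, multiplicity
# adjustment and risk-subgroup analysis. Kaplan-Meier, log-rank and Cox
# fitting are delegated to the survival package (Efron ties by default);
# the wrappers pin the contracts (error classes, medians, Wald CIs, the
# concordance pair-counting convention) this pipeline relies on.

#' Biochemical-recurrence status at a follow-up horizon
#'
#' A patient is horizon-positive iff recurrence was observed at or before
#' the horizon, horizon-negative iff followed (with or without a later
#' event) to at least the horizon, and excluded (`NA`) iff censored before
#' the horizon -- their status at the horizon is unknowable.
#'
#' @param time Follow-up times in months.
#' @param event Event indicators (1 = recurrence, 0 = censored).
#' @param horizon Horizon in months (default 36).
#' @return Integer vector: 1 (recurrence by horizon), 0 (recurrence-free at
#'   horizon), `NA` (excluded).
#' @export
bcr_status_at_horizon <- function(time, event, horizon = 36) {
  if (length(time) != length(event)) {
    abort_config("time and event must have the same length")
  }
  status <- rep(NA_integer_, length(time))
  status[time >= horizon] <- 0L
  # an event at exactly the horizon counts as horizon-positive
  status[event == 1 & time <= horizon] <- 1L
  status
}

#' Derive a high/low methylation cutoff from horizon-status ROC
#'
#' Patients with known horizon status enter a ROC of marker level against
#' status; the cutoff is the candidate threshold maximizing Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher specificity
#' (the higher threshold). Patients censored before the horizon are
#' excluded from cutoff derivation only.
#'
#' @param levels Marker levels (one per patient).
#' @param statuses Horizon statuses from [bcr_status_at_horizon()] (`NA` =
#'   excluded).
#' @param marker Marker name recorded in the rule.
#' @param horizon Horizon recorded in the rule (months).
#' @return A `dichotomy_rule`: `marker`, `cutoff`, `horizon`, `youden_j`,
#'   `n_positive`, `n_negative`, `n_excluded`. Patients are classified
#'   high-methylation iff `level > cutoff`.
#' @export
derive_cutoff <- function(levels, statuses, marker = "marker", horizon = 36) {
  if (length(levels) != length(statuses)) {
    abort_config("levels and statuses must have the same length")
  }
  keep <- !is.na(statuses) & !is.na(levels)
  lv <- levels[keep]; st <- statuses[keep]
  if (!any(st == 1) || !any(st == 0)) {
    abort_degenerate("derive_cutoff: both horizon statuses must be present")
  }
  if (length(unique(lv)) < 2L) {
    abort_degenerate("derive_cutoff: all levels identical, no informative threshold")
  }
  rc <- roc(lv, st)
  pts <- rc$points[is.finite(rc$points$threshold), , drop = FALSE]
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[order(pts$specificity[best], pts$threshold[best],
                     decreasing = TRUE)][1L]
  structure(list(marker = marker,
                 cutoff = pts$threshold[pick],
                 horizon = horizon,
                 youden_j = j[pick],
                 n_positive = sum(st == 1),
                 n_negative = sum(st == 0),
                 n_excluded = sum(!keep)),
            class = "dichotomy_rule")
}

#' @export
print.dichotomy_rule <- function(x, ...) {
  cat(sprintf(
    "<dichotomy_rule> %s > %.4g at %g-month horizon (J = %.3f; %d+/%d-, %d excluded)\n",
    x$marker, x$cutoff, x$horizon, x$youden_j, x$n_positive, x$n_negative,
    x$n_excluded))
  invisible(x)
}

.check_surv_input <- function(time, event, require_positive = TRUE) {
  if (length(time) != length(event) || !length(time)) {
    abort_degenerate("empty or mismatched survival input")
  }
  if (any(is.na(time)) || any(is.na(event))) {
    abort_degenerate("survival input contains missing values")
  }
  if (!all(event %in% c(0, 1))) {
    abort_degenerate("event indicators must be 0 or 1")
  }
  if (require_positive && any(time <= 0)) {
    abort_degenerate("follow-up times must be > 0")
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times in months (`> 0`).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A `km_curve`: `steps` (data frame `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`), `median` (smallest time with `S(t) <= 0.5`, `NA`
#'   if never reached), `n`, `n_events`.
#' @examples
#' kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))$median  # 2
#' @export
kaplan_meier <- function(time, event) {
  .check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  reached <- steps$time[steps$surv <= 0.5 + 1e-12]
  structure(list(steps = steps,
                 median = if (length(reached)) min(reached) else NA_real_,
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s months\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-sided log-rank test
#'
#' Standard observed-minus-expected chi-square over the shared event times,
#' with the two-sided p-value from the chi-square distribution on
#' (number of groups - 1) degrees of freedom.
#'
#' @param time,event As in [kaplan_meier()].
#' @param group Group membership (>= 2 non-empty groups).
#' @return List of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   `n_per_group`, `events_per_group`.
#' @export
logrank <- function(time, event, group) {
  .check_surv_input(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    abort_degenerate("logrank: need at least two non-empty groups")
  }
  if (sum(event) == 0) {
    abort_degenerate("logrank: no events in any group")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_per_group = as.vector(sd$n),
                 events_per_group = as.vector(sd$obs)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit with Wald intervals and Harrell's C
#'
#' Maximizes the partial likelihood (Efron tie handling by default) and
#' reports, per covariate, the log-hazard coefficient, hazard ratio,
#' 95% Wald confidence interval (normal quantile 1.959964) and Wald
#' p-value, plus the model's Harrell's concordance computed from the linear
#' predictor. Non-convergence and diverging coefficients (complete
#' separation) raise errors rather than returning unusable fits.
#'
#' @param covariates Data frame (or matrix) of numeric covariates.
#' @param time,event As in [kaplan_meier()]; at least one event, and more
#'   observations than covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: `coefficients` (data frame with `term`, `coef`,
#'   `se`, `hr`, `ci_lower`, `ci_upper`, `p_value`), `loglik`,
#'   `concordance`, `linear_predictor`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_surv_input(time, event)
  d <- as.data.frame(covariates)
  if (!nrow(d) || nrow(d) != length(time)) {
    abort_config("covariates must have one row per observation")
  }
  if (nrow(d) <= ncol(d)) {
    abort_degenerate("need more observations than covariates")
  }
  if (sum(event) < 1) abort_degenerate("need at least one event")
  d$.time <- time; d$.event <- event
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(d), c(".time", ".event"))),
          collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = d, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite",
                conditionMessage(w))) {
        abort_degenerate(sprintf("Cox fit failed: %s", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    abort_degenerate(
      "Cox fit: diverging coefficient suggests complete separation")
  }
  se <- sqrt(diag(fit$var))
  z975 <- 1.959964
  lp <- unname(fit$linear.predictors)
  coefs <- data.frame(term = names(beta),
                      coef = unname(beta),
                      se = se,
                      hr = exp(unname(beta)),
                      ci_lower = exp(unname(beta) - z975 * se),
                      ci_upper = exp(unname(beta) + z975 * se),
                      p_value = 2 * pnorm(-abs(unname(beta) / se)),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 loglik = fit$loglik[length(fit$loglik)],
                 concordance = harrells_c(lp, time, event),
                 linear_predictor = lp,
                 n = nrow(d), n_events = sum(event),
                 ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, C = %.3f\n",
              x$n, x$n_events, x$ties, x$concordance))
  df <- x$coefficients
  df$hr_ci <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_lower, df$ci_upper)
  print(df[, c("term", "coef", "hr_ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Harrell's concordance index
#'
#' A pair of patients is comparable iff the smaller observed time carries an
#' event (the patient known to fail first); it is concordant when the
#' higher risk score accompanies the shorter time, and score ties count
#' 1/2. `C = (concordant + 0.5 * tied) / comparable`.
#'
#' @param risk Risk scores (higher = predicted earlier failure).
#' @param time,event As in [kaplan_meier()] (times may include zeros here;
#'   only the ordering matters).
#' @return Concordance in `[0, 1]`.
#' @export
harrells_c <- function(risk, time, event) {
  if (length(risk) != length(time) || length(time) != length(event)) {
    abort_config("risk, time and event must have the same length")
  }
  if (length(time) < 2L) abort_degenerate("harrells_c: need n >= 2")
  # comparable: time_i < time_j (strict) and patient i had the event
  cmp <- outer(time, time, "<") & (event == 1)
  concordant <- sum(cmp & outer(risk, risk, ">"))
  tied <- sum(cmp & outer(risk, risk, "=="))
  n_cmp <- sum(cmp)
  if (n_cmp == 0L) {
    abort_degenerate("harrells_c: no comparable pairs")
  }
  (concordant + 0.5 * tied) / n_cmp
}

#' Stepwise backward selection for a multivariate Cox model
#'
#' Starting from the full model, iteratively removes the covariate with the
#' largest Wald p-value above `alpha` and refits, until every remaining
#' covariate has `p <= alpha`. The elimination trace records each removal.
#' When `marker_vars` is given, the report also carries the concordance of
#' the final model refit without the marker covariates, quantifying what
#' the markers add to the clinicopathological baseline.
#'
#' @inheritParams cox_fit
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param marker_vars Names of the marker covariates (subset of
#'   `colnames(covariates)`), used only for the paired concordance.
#' @return List of class `backward_selection`: `final` ([cox_fit]),
#'   `trace` (data frame `step`, `removed`, `p_value`), `retained`,
#'   `c_index_full` (final model), `c_index_clinical` (final model without
#'   markers; `NA` when nothing remains).
#' @export
backward_select <- function(covariates, time, event, alpha = 0.05,
                            marker_vars = character(0),
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- as.data.frame(covariates)
  vars <- names(d)
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  fit <- cox_fit(d[, vars, drop = FALSE], time, event, ties = ties)
  step <- 0L
  while (length(vars) > 1L) {
    p <- fit$coefficients$p_value
    worst <- which.max(p)
    if (p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = fit$coefficients$term[worst],
                                     p_value = p[worst],
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, fit$coefficients$term[worst])
    fit <- cox_fit(d[, vars, drop = FALSE], time, event, ties = ties)
  }
  clinical <- setdiff(vars, marker_vars)
  c_clinical <- if (length(clinical) && length(clinical) < length(vars)) {
    cox_fit(d[, clinical, drop = FALSE], time, event, ties = ties)$concordance
  } else if (length(clinical) == length(vars)) {
    fit$concordance  # no marker survived; the models coincide
  } else {
    NA_real_
  }
  structure(list(final = fit, trace = trace, retained = vars,
                 c_index_full = fit$concordance,
                 c_index_clinical = c_clinical),
            class = "backward_selection")
}

#' @export
print.backward_selection <- function(x, ...) {
  cat(sprintf("<backward_selection> retained: %s\n", oxford(x$retained)))
  if (nrow(x$trace)) {
    cat("removed in order:\n"); print(x$trace, row.names = FALSE)
  }
  cat(sprintf("C-index: %.3f (full), %s (clinical only)\n", x$c_index_full,
              if (is.na(x$c_index_clinical)) "NA" else
                sprintf("%.3f", x$c_index_clinical)))
  invisible(x)
}

#' Multiplicity adjustment (step-up procedures)
#'
#' Benjamini-Hochberg (false-discovery rate) or Hochberg (family-wise
#' error) step-up adjustment; adjusted values are monotone, at least the
#' raw values, and capped at 1.
#'
#' @param ps Raw p-values in `(0, 1]`.
#' @param method `"benjamini_hochberg"` (default) or `"hochberg"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(ps, method = c("benjamini_hochberg", "hochberg")) {
  method <- match.arg(method)
  if (!length(ps)) return(numeric(0))
  if (any(is.na(ps)) || any(ps <= 0) || any(ps > 1)) {
    abort_config("p-values must lie in (0, 1]")
  }
  p.adjust(ps, method = switch(method, benjamini_hochberg = "BH",
                               hochberg = "hochberg"))
}

#' Dichotomized survival analysis within strata
#'
#' Applies a full-cohort [derive_cutoff()] rule within each stratum (for
#' example D'Amico risk groups), producing per-stratum Kaplan-Meier curves
#' for the high- and low-methylation groups, their medians and the log-rank
#' p-value. Strata in which only one dichotomy class occurs (or with no
#' events) are reported as untestable rather than failing the analysis;
#' patients with missing or `"unknown"` stratum labels are skipped.
#'
#' @param table Survival table with `time_months`, `event`, the marker
#'   column named by `rule$marker`, and `stratum_field`.
#' @param stratum_field Column name to stratify by.
#' @param rule A [derive_cutoff()] rule derived on the full cohort.
#' @return List of class `subgroup_analysis`, one entry per stratum:
#'   `stratum`, `n`, `n_high`, `n_low`, `testable`, and (when testable)
#'   `logrank_p`, `median_high`, `median_low`.
#' @export
subgroup_analysis <- function(table, stratum_field, rule) {
  require_columns(table, c("time_months", "event", stratum_field,
                           rule$marker), "survival table")
  strata <- table[[stratum_field]]
  keep <- !is.na(strata) & strata != "unknown"
  tab <- table[keep, , drop = FALSE]
  out <- lapply(unique(tab[[stratum_field]]), function(s) {
    st <- tab[tab[[stratum_field]] == s, , drop = FALSE]
    high <- st[[rule$marker]] > rule$cutoff
    entry <- list(stratum = s, n = nrow(st),
                  n_high = sum(high), n_low = sum(!high))
    if (!any(high) || all(high) || sum(st$event) == 0) {
      entry$testable <- FALSE
      return(entry)
    }
    lr <- logrank(st$time_months, st$event, ifelse(high, "high", "low"))
    entry$testable <- TRUE
    entry$logrank_p <- lr$p_value
    entry$median_high <- kaplan_meier(st$time_months[high],
                                      st$event[high])$median
    entry$median_low <- kaplan_meier(st$time_months[!high],
                                     st$event[!high])$median
    entry
  })
  names(out) <- vapply(out, `[[`, character(1), "stratum")
  structure(out, class = "subgroup_analysis")
}
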