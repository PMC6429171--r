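# Reduction of raw qMSP plates to per-sample normalized methylation levels:
# standard curves, triplicate outlier removal, zero rules, reference-gene QC
# and ALUC4 normalization, with a complete audit ledger.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10 quantity over the serial-dilution
#' standards. Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1`, so a slope of -3.3219 cycles per decade corresponds
#' to 100% efficiency (perfect doubling).
#'
#' @param ct Numeric Ct values (undetermined wells as `NA` are dropped).
#' @param log10_quantity Known log10 quantities, same length as `ct`.
#' @return A `standard_curve` object with `slope`, `intercept`, `r_squared`,
#'   `efficiency` and `n_points`.
#' @examples
#' q <- rep(c(5, 4, 3, 2), each = 3)
#' fit_standard_curve(38 - 3.3219 * q, q)
#' @export
fit_standard_curve <- function(ct, log10_quantity) {
  if (length(ct) != length(log10_quantity)) {
    abort_config("ct and log10_quantity must have the same length")
  }
  ok <- is.finite(ct) & is.finite(log10_quantity)
  ct <- ct[ok]; lq <- log10_quantity[ok]
  if (length(unique(lq)) < 3L) {
    abort(sprintf(
      "standard curve needs >= 3 distinct dilution points with numeric Ct (got %d)",
      length(unique(lq))), "methmark_curve_error")
  }
  if (var(lq) == 0) {
    abort("standard-curve quantities have zero variance", "methmark_curve_error")
  }
  fit <- lm(ct ~ lq)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    abort(sprintf(
      "standard-curve slope %.3f is not negative; Ct must fall as quantity rises",
      slope), "methmark_curve_error")
  }
  # R^2 computed directly; a noiseless curve (zero residual sum) is R^2 = 1
  sst <- sum((ct - mean(ct))^2)
  ssr <- sum(fit$residuals^2)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 efficiency = 10^(-1 / slope) - 1,
                 n_points = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.3f %+.4f * log10(q); R^2 = %.4f; efficiency = %.1f%% (n = %d)\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency, x$n_points))
  invisible(x)
}

#' Remove an outlier replicate from a triplicate of Ct values
#'
#' A replicate is an outlier when its Ct deviates by more than 2 cycles from
#' the median of the other numeric replicates. At most one replicate is
#' removed per triplicate (the most deviant); undetermined (`NA`) values
#' pass through untouched, as absent amplification is handled by the zero
#' rules, not by outlier removal. With fewer than three numeric values no
#' removal is attempted: a pair that disagrees cannot be adjudicated.
#'
#' @param cts Numeric vector of up to 3 Ct values, possibly with `NA`.
#' @return The retained Ct values, with the removed position (if any) in the
#'   `removed` attribute.
#' @examples
#' remove_outlier_replicates(c(30.0, 30.2, 35.1))  # drops 35.1
#' remove_outlier_replicates(c(30.0, 31.0, 32.0))  # unchanged
#' @export
remove_outlier_replicates <- function(cts) {
  num <- which(is.finite(cts))
  if (length(num) < 3L) {
    return(structure(cts, removed = integer(0)))
  }
  dev <- vapply(num, function(i) {
    abs(cts[i] - median(cts[setdiff(num, i)]))
  }, numeric(1))
  if (max(dev) > 2) {
    drop <- num[which.max(dev)]
    structure(cts[-drop], removed = drop)
  } else {
    structure(cts, removed = integer(0))
  }
}

# Per-replicate quantities and zero-rule bookkeeping. Returns a data frame
# with ct, quantity and the name of the rule that zeroed the replicate ("").
.replicate_quantities <- function(cts, curve, neg_ctrl_min_ct, mode) {
  cap <- if (mode == "small_scale") 37 else 40
  cap_rule <- if (mode == "small_scale") "ct_above_37" else "ct_above_40"
  n <- length(cts)
  quantity <- numeric(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    ct <- cts[i]
    if (!is.finite(ct)) {
      quantity[i] <- 0; rule[i] <- "undetermined"
    } else if (ct > cap) {
      quantity[i] <- 0; rule[i] <- cap_rule
    } else if (ct > neg_ctrl_min_ct) {
      quantity[i] <- 0; rule[i] <- "above_negative_control"
    } else {
      quantity[i] <- 10^((ct - curve$intercept) / curve$slope)
      rule[i] <- ""
    }
  }
  data.frame(ct = cts, quantity = quantity, zero_rule = rule,
             stringsAsFactors = FALSE)
}

#' Quantity of one sample-target from its replicate Ct values
#'
#' Applies the zero rules per replicate, inverts the standard curve for the
#' surviving replicates, and averages on the linear (quantity) scale so
#' zeroed replicates average in. A replicate is zeroed when its Ct is
#' undetermined, exceeds the cycle cap (40 in `large_scale` mode, 37 in
#' `small_scale` mode), or exceeds the minimum Ct observed among the
#' negative controls of the same run.
#'
#' @param cts Ct values (outlier removal already applied).
#' @param curve A [fit_standard_curve()] result for the target.
#' @param neg_ctrl_min_ct Minimum numeric Ct across the run's negative
#'   controls for this target; `Inf` when no negative control amplified.
#' @param mode `"large_scale"` (cap 40) or `"small_scale"` (cap 37).
#' @return Mean quantity (`>= 0`).
#' @export
replicate_quantity <- function(cts, curve, neg_ctrl_min_ct = Inf,
                               mode = c("large_scale", "small_scale")) {
  mode <- match.arg(mode)
  if (!inherits(curve, "standard_curve")) {
    abort("replicate_quantity needs a standard_curve for the target",
          "methmark_processing_error")
  }
  if (!length(cts)) {
    abort_degenerate("replicate_quantity: no replicates")
  }
  mean(.replicate_quantities(cts, curve, neg_ctrl_min_ct, mode)$quantity)
}

#' Reference-gene and replicate quality control for one sample
#'
#' A sample fails when the post-outlier-removal mean ALUC4 Ct exceeds 24
#' (insufficient DNA input), when it has no ALUC4 wells at all, when no
#' MYOD1 well amplified (failed bisulfite conversion), or when a reference
#' assay has fewer than 2 amplified replicates. Additionally, per marker
#' target, a sample-target with exactly one amplified replicate fails on its
#' own (a single surviving reaction cannot be confirmed) while zero amplified
#' replicates is a valid quantity-0 result, not a failure. All triggered
#' reasons are reported.
#'
#' @param wells Data frame of this sample's wells (`target`, `ct`).
#' @return List with `qc_status` (`"pass"`/`"fail"` at sample level),
#'   `sample_reasons` (character vector) and `target_status` (data frame
#'   with per-target `qc_status` and `reasons`).
#' @export
sample_qc <- function(wells) {
  require_columns(wells, c("target", "ct"), "sample wells")
  reasons <- character(0)

  aluc <- wells$ct[wells$target == "ALUC4"]
  if (!length(aluc)) {
    reasons <- c(reasons, "missing_reference_ALUC4")
  } else {
    kept <- remove_outlier_replicates(aluc)
    amp <- kept[is.finite(kept)]
    if (length(amp) < 2L) {
      reasons <- c(reasons, "reference_replicates_ALUC4")
    } else if (mean(amp) > 24) {
      reasons <- c(reasons, "aluc4_ct_above_24")
    }
  }
  myod <- wells$ct[wells$target == "MYOD1"]
  if (!length(myod)) {
    reasons <- c(reasons, "missing_reference_MYOD1")
  } else {
    kept <- remove_outlier_replicates(myod)
    amp <- kept[is.finite(kept)]
    if (length(amp) == 0L) {
      reasons <- c(reasons, "myod1_not_amplified")
    } else if (length(amp) < 2L) {
      reasons <- c(reasons, "reference_replicates_MYOD1")
    }
  }
  sample_fail <- length(reasons) > 0L

  markers <- setdiff(unique(wells$target), REFERENCE_TARGETS)
  target_rows <- lapply(markers, function(tg) {
    kept <- remove_outlier_replicates(wells$ct[wells$target == tg])
    n_amp <- sum(is.finite(kept))
    t_reasons <- reasons
    if (n_amp == 1L) t_reasons <- c(t_reasons, "insufficient_replicates")
    data.frame(target = tg,
               qc_status = if (length(t_reasons)) "fail" else "pass",
               reasons = paste(t_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  list(qc_status = if (sample_fail) "fail" else "pass",
       sample_reasons = reasons,
       target_status = if (length(target_rows)) do.call(rbind, target_rows)
       else data.frame(target = character(0), qc_status = character(0),
                       reasons = character(0), stringsAsFactors = FALSE))
}

#' Process a qMSP plate into normalized methylation levels
#'
#' Order of operations per sample-target: triplicate outlier removal, then
#' per-replicate zero rules (undetermined / cycle cap / negative-control
#' bound), then standard-curve inversion and linear-scale averaging, then
#' sample QC, then normalization of marker quantities to the sample's ALUC4
#' quantity. Samples or sample-targets failing QC get `qc_status = "fail"`
#' and no normalized level, but remain in the output and the ledger.
#'
#' @param plate Plate data frame as produced by [generate_qmsp_plate()] or
#'   [read_qmsp_plate()].
#' @param mode `"large_scale"` (zero rule at Ct > 40 and above the negative
#'   controls) or `"small_scale"` (zero rule at Ct > 37).
#' @return A `qmsp_run` object: \describe{
#'   \item{results}{data frame with `sample_id`, `target`, `quantity`,
#'     `normalized_level`, `qc_status`, `qc_reasons` (marker targets;
#'     reference targets carry `NA` normalized levels).}
#'   \item{curves}{named list of per-target [fit_standard_curve()] results.}
#'   \item{neg_ctrl_ct}{named vector of per-target negative-control minimum
#'     Ct values.}
#'   \item{ledger}{data frame recording every outlier removal, zeroed
#'     replicate and QC failure with its reason.}
#' }
#' @export
process_plate <- function(plate, mode = c("large_scale", "small_scale")) {
  mode <- match.arg(mode)
  require_columns(plate, c("well", "sample_id", "target", "role", "replicate",
                           "ct"), "qMSP plate")
  if (!"known_quantity" %in% names(plate)) plate$known_quantity <- NA_real_

  unknowns <- plate[plate$role == "unknown", , drop = FALSE]
  if (!nrow(unknowns)) abort_degenerate("plate has no unknown (sample) wells")
  targets <- unique(unknowns$target)

  curves <- list()
  neg_ctrl_ct <- setNames(rep(Inf, length(targets)), targets)
  for (tg in targets) {
    std <- plate[plate$role == "standard" & plate$target == tg, , drop = FALSE]
    if (!nrow(std)) {
      abort(sprintf("no standard-curve wells for target %s", tg),
            "methmark_processing_error")
    }
    if (all(is.na(std$known_quantity))) {
      abort(sprintf("standard wells for target %s lack known quantities", tg),
            "methmark_processing_error")
    }
    curves[[tg]] <- fit_standard_curve(std$ct, log10(std$known_quantity))
    neg <- plate$ct[plate$target == tg &
                      plate$role %in% c("neg_ctrl_wga", "neg_ctrl_water")]
    neg <- neg[is.finite(neg)]
    if (length(neg)) neg_ctrl_ct[[tg]] <- min(neg)
  }

  ledger <- list(); L <- 0L
  note <- function(sample_id, target, well, event, detail) {
    L <<- L + 1L
    ledger[[L]] <<- data.frame(sample_id = sample_id, target = target,
                               well = well, event = event, detail = detail,
                               stringsAsFactors = FALSE)
  }
  for (w in attr(plate, "io_warnings") %||% character(0)) {
    note("", "", "", "io_warning", w)
  }

  results <- list(); R <- 0L
  for (sid in unique(unknowns$sample_id)) {
    swells <- unknowns[unknowns$sample_id == sid, , drop = FALSE]
    qc <- sample_qc(swells)
    for (r in qc$sample_reasons) note(sid, "", "", "sample_qc_fail", r)

    quantities <- setNames(rep(NA_real_, length(targets)), targets)
    for (tg in intersect(targets, unique(swells$target))) {
      tw <- swells[swells$target == tg, , drop = FALSE]
      kept <- remove_outlier_replicates(tw$ct)
      removed <- attr(kept, "removed")
      keep_idx <- setdiff(seq_len(nrow(tw)), removed)
      if (length(removed)) {
        note(sid, tg, tw$well[removed], "outlier_removed",
             sprintf("ct %.2f deviates > 2 cycles from replicate median",
                     tw$ct[removed]))
      }
      reps <- .replicate_quantities(tw$ct[keep_idx], curves[[tg]],
                                    neg_ctrl_ct[[tg]], mode)
      zeroed <- which(nzchar(reps$zero_rule))
      for (z in zeroed) {
        note(sid, tg, tw$well[keep_idx][z], "replicate_zeroed",
             reps$zero_rule[z])
      }
      quantities[[tg]] <- mean(reps$quantity)
    }

    aluc_q <- quantities[["ALUC4"]]
    for (tg in setdiff(targets, REFERENCE_TARGETS)) {
      if (!tg %in% swells$target) next
      ts <- qc$target_status
      trow <- ts[ts$target == tg, , drop = FALSE]
      status <- if (nrow(trow)) trow$qc_status else qc$qc_status
      t_reasons <- if (nrow(trow)) trow$reasons else
        paste(qc$sample_reasons, collapse = ";")
      if (nrow(trow) && grepl("insufficient_replicates", trow$reasons)) {
        note(sid, tg, "", "target_qc_fail", "insufficient_replicates")
      }
      q <- quantities[[tg]]
      norm <- if (status == "pass" && is.finite(aluc_q) && aluc_q > 0) {
        q / aluc_q
      } else {
        NA_real_
      }
      R <- R + 1L
      results[[R]] <- data.frame(sample_id = sid, target = tg,
                                 quantity = q,
                                 normalized_level = norm,
                                 qc_status = status,
                                 qc_reasons = t_reasons,
                                 stringsAsFactors = FALSE)
    }
    for (tg in intersect(REFERENCE_TARGETS, targets)) {
      if (!tg %in% swells$target) next
      R <- R + 1L
      results[[R]] <- data.frame(sample_id = sid, target = tg,
                                 quantity = quantities[[tg]],
                                 normalized_level = NA_real_,
                                 qc_status = qc$qc_status,
                                 qc_reasons = paste(qc$sample_reasons,
                                                    collapse = ";"),
                                 stringsAsFactors = FALSE)
    }
  }

  structure(list(results = do.call(rbind, results),
                 curves = curves,
                 neg_ctrl_ct = neg_ctrl_ct,
                 ledger = if (L) do.call(rbind, ledger) else
                   data.frame(sample_id = character(0), target = character(0),
                              well = character(0), event = character(0),
                              detail = character(0), stringsAsFactors = FALSE),
                 mode = mode),
            class = "qmsp_run")
}

#' @export
print.qmsp_run <- function(x, ...) {
  res <- x$results
  markers <- !res$target %in% REFERENCE_TARGETS
  cat(sprintf("<qmsp_run> %s: %d samples, %d marker targets, %d ledger entries\n",
              x$mode, length(unique(res$sample_id)),
              length(unique(res$target[markers])), nrow(x$ledger)))
  cat(sprintf("  QC: %d/%d marker sample-targets pass\n",
              sum(res$qc_status[markers] == "pass"), sum(markers)))
  invisible(x)
}
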