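# End-to-end orchestration: simulate (or load) -> discover -> qMSP ->
# diagnose -> prognose, with central seed management, per-stage error
# capture and a self-contained JSON report. All stage randomness derives
# from the single pipeline seed through named substreams, so reruns with
# the same seed and configuration reproduce every deterministic artifact
# byte-identically (wall-clock timings live in a separate timings.json).

PIPELINE_CONFIG_FIELDS <- c("beta_matrix", "annotation", "survival_table",
                            "plate", "simulation", "thresholds", "qmsp_mode",
                            "horizon", "adjust", "cohort", "plate_sim",
                            "min_median_diff", "max_p")

.validate_pipeline_config <- function(out_dir, seed, config) {
  errors <- character(0)
  unknown <- setdiff(names(config), PIPELINE_CONFIG_FIELDS)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config field(s): %s", oxford(unknown)))
  }
  if (!is_count(seed)) errors <- c(errors, "seed must be a single integer")
  for (f in c("beta_matrix", "annotation", "survival_table", "plate")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      errors <- c(errors, sprintf("config field '%s': no such file: %s", f, p))
    }
  }
  if (!is.null(config[["qmsp_mode"]]) &&
      !config[["qmsp_mode"]] %in% c("large_scale", "small_scale")) {
    errors <- c(errors, "qmsp_mode must be 'large_scale' or 'small_scale'")
  }
  if (!is.null(config[["adjust"]]) &&
      !config[["adjust"]] %in% c("benjamini_hochberg", "hochberg")) {
    errors <- c(errors, "adjust must be 'benjamini_hochberg' or 'hochberg'")
  }
  if (xor(is.null(config[["beta_matrix"]]), is.null(config[["annotation"]]))) {
    errors <- c(errors,
                "beta_matrix and annotation must be provided together")
  }
  if (length(errors)) {
    abort_config(paste(c("pipeline configuration invalid:", errors),
                       collapse = "\n  - "))
  }
  invisible(TRUE)
}

# default synthetic qMSP layer: a tissue validation set plus a blood panel
.default_plate_sim <- function() {
  list(markers = c("marker_1", "marker_2"),
       n_pca = 47, n_benign = 37, n_blood = 40,
       detect_prob_pca = 0.85, detect_prob_benign = 0.10,
       noise_sd = 0.25, outlier_rate = 0.05)
}

.simulate_plate_truth <- function(ps, seed) {
  ids <- c(sprintf("pca_%03d", seq_len(ps$n_pca)),
           sprintf("benign_%03d", seq_len(ps$n_benign)),
           sprintf("blood_%03d", seq_len(ps$n_blood)))
  cls <- rep(c("pca", "benign", "blood"),
             c(ps$n_pca, ps$n_benign, ps$n_blood))
  with_seed(seed, {
    rows <- list()
    for (m in ps$markers) {
      detect <- ifelse(cls == "pca", runif(length(ids)) < ps$detect_prob_pca,
                       ifelse(cls == "benign",
                              runif(length(ids)) < ps$detect_prob_benign,
                              FALSE))
      q <- ifelse(detect,
                  ifelse(cls == "pca", rlnorm(length(ids), log(50), 0.7),
                         rlnorm(length(ids), log(2), 0.5)),
                  0)
      rows[[m]] <- data.frame(sample_id = ids, target = m, quantity = q,
                              stringsAsFactors = FALSE)
    }
    rows$ALUC4 <- data.frame(sample_id = ids, target = "ALUC4",
                             quantity = rlnorm(length(ids), log(1e5), 0.3),
                             stringsAsFactors = FALSE)
    rows$MYOD1 <- data.frame(sample_id = ids, target = "MYOD1",
                             quantity = rlnorm(length(ids), log(5e4), 0.3),
                             stringsAsFactors = FALSE)
    list(truth = do.call(rbind, rows), class_of = setNames(cls, ids))
  })
}

#' Run the full synthetic-to-prognosis pipeline
#'
#' Executes, in dependency order: (1) beta-matrix simulation (or loading)
#' and the discovery cascade; (2) qMSP plate simulation, plate reduction
#' and diagnostic evaluation of the marker panel (tumor versus benign
#' tissue, plus a blood-donor false-positive panel); (3) survival-cohort
#' simulation (or loading) and prognostic evaluation (horizon cutoff,
#' Kaplan-Meier, log-rank, uni- and multivariate Cox with backward
#' selection and paired concordance, risk-subgroup analysis). A stage
#' failure aborts dependent stages but still emits a partial report with
#' the failure reason.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it.
#' @param config Optional named list: `beta_matrix`/`annotation`/`plate`/
#'   `survival_table` (paths to use instead of simulation), `simulation`
#'   and `cohort` (argument lists for [simulation_config()] /
#'   [cohort_config()]), `plate_sim` (overrides for the qMSP layer),
#'   `thresholds` (a [filter_thresholds()]), `qmsp_mode`, `horizon`,
#'   `adjust`, `min_median_diff`, `max_p`. Validation errors are reported
#'   all at once.
#' @return A `pipeline_report` (also written to `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = list()) {
  .validate_pipeline_config(out_dir, seed, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  report <- list(package = "methmark",
                 version = as.character(packageVersion("methmark")),
                 seed = seed,
                 config = config[lengths(config) > 0],
                 stages = list())
  timings <- list()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped",
                                     reason = "earlier stage failed")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     reason = conditionMessage(res))
      invisible(NULL)
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
      invisible(res)
    }
  }

  thresholds <- config[["thresholds"]] %||% filter_thresholds()
  horizon <- config[["horizon"]] %||% 36
  adjust_method <- config[["adjust"]] %||% "benjamini_hochberg"
  qmsp_mode <- config[["qmsp_mode"]] %||% "large_scale"

  ## Stage 1: discovery -------------------------------------------------
  run_stage("discovery", function() {
    if (!is.null(config[["beta_matrix"]])) {
      beta <- read_beta_matrix(config[["beta_matrix"]])
      ann <- read_sample_annotation(config[["annotation"]])
      truth <- NULL
    } else {
      sim_args <- config[["simulation"]] %||% list()
      sim_args$seed <- substream_seed(seed, "stage_beta")
      sim <- generate_beta_matrix(do.call(simulation_config, sim_args))
      beta <- sim$beta; ann <- sim$annotation; truth <- sim$truth
      write_beta_matrix(beta, file.path(out_dir, "beta_matrix.tsv"))
      write_sample_annotation(ann, file.path(out_dir, "annotation.csv"))
      jsonlite::write_json(truth, file.path(out_dir, "cpg_truth.json"),
                           digits = NA)
    }
    rep <- run_discovery(beta, ann, thresholds,
                         min_median_diff = config[["min_median_diff"]] %||% 0.30,
                         max_p = config[["max_p"]] %||% 0.001)
    write_filter_report(rep, file.path(out_dir, "filter_report.json"))
    cand <- rep$summaries
    write.csv(cand, file.path(out_dir, "candidates.csv"), row.names = FALSE,
              na = "")
    list(stages = rep$stages,
         n_pan_cancer = length(rep$pan_cancer),
         n_pca_specific = length(rep$pca_specific),
         n_union = length(rep$union),
         n_pass_effect = sum(cand$passes_effect_criterion, na.rm = TRUE))
  })

  ## Stage 2: qMSP + diagnostics ----------------------------------------
  run_stage("qmsp_diagnostics", function() {
    if (!is.null(config[["plate"]])) {
      plate <- read_qmsp_plate(config[["plate"]])
      class_of <- NULL
    } else {
      ps <- utils::modifyList(.default_plate_sim(), config[["plate_sim"]] %||% list())
      sim <- .simulate_plate_truth(ps, substream_seed(seed, "stage_plate_truth"))
      class_of <- sim$class_of
      pcfg <- plate_config(sim$truth, noise_sd = ps$noise_sd,
                           outlier_rate = ps$outlier_rate,
                           seed = substream_seed(seed, "stage_plate"))
      gen <- generate_qmsp_plate(pcfg)
      plate <- gen$plate
      write_qmsp_plate(plate, file.path(out_dir, "plate.csv"))
      write.csv(gen$truth, file.path(out_dir, "plate_truth.csv"),
                row.names = FALSE, na = "")
    }
    run <- process_plate(plate, mode = qmsp_mode)
    write.csv(run$results, file.path(out_dir, "qmsp_results.csv"),
              row.names = FALSE, na = "")
    jsonlite::write_json(run$ledger, file.path(out_dir, "qc_ledger.json"),
                         digits = NA, pretty = TRUE)
    if (is.null(class_of)) {
      return(list(n_results = nrow(run$results),
                  n_ledger = nrow(run$ledger)))
    }
    markers <- setdiff(unique(run$results$target), REFERENCE_TARGETS)
    diag <- lapply(markers, function(m) {
      res <- run$results[run$results$target == m &
                           run$results$qc_status == "pass", , drop = FALSE]
      cls <- class_of[res$sample_id]
      tissue <- res[cls %in% c("pca", "benign"), , drop = FALSE]
      tcls <- class_of[tissue$sample_id]
      mw <- mann_whitney(tissue$normalized_level[tcls == "pca"],
                         tissue$normalized_level[tcls == "benign"])
      rc <- roc(tissue$normalized_level, tcls == "pca")
      rocfile <- file.path(out_dir, sprintf("roc_%s.csv", m))
      write.csv(rc$points, rocfile, row.names = FALSE)
      det <- detection_performance(tissue,
                                   setNames(tcls == "pca", tissue$sample_id))
      blood <- res[cls == "blood", , drop = FALSE]
      list(marker = m,
           mw_p = mw$p_value,
           auc = rc$auc,
           sens_at_95_spec = sensitivity_at_specificity(rc, 0.95),
           detection_sensitivity = det$sensitivity,
           detection_specificity = det$specificity,
           blood_false_positive_rate =
             if (nrow(blood)) mean(blood$normalized_level > 0) else NA_real_,
           n_tissue = nrow(tissue), n_blood = nrow(blood))
    })
    names(diag) <- markers
    jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(qc_pass_fraction =
           mean(run$results$qc_status[!run$results$target %in%
                                        REFERENCE_TARGETS] == "pass"),
         diagnostics = diag)
  })

  ## Stage 3: prognostics ------------------------------------------------
  run_stage("prognostics", function() {
    if (!is.null(config[["survival_table"]])) {
      tab <- read_survival_table(config[["survival_table"]])
      truth <- NULL
    } else {
      coh_args <- config[["cohort"]] %||% list()
      coh_args$seed <- substream_seed(seed, "stage_cohort")
      coh <- generate_survival_cohort(do.call(cohort_config, coh_args))
      tab <- coh$table; truth <- coh$truth
      write_survival_table(tab, file.path(out_dir, "survival_table.csv"))
    }
    marker <- "marker"
    clinical <- intersect(c("margin_positive", "psa_high", "gleason_high",
                            "pt_high"), names(tab))
    if (!marker %in% names(tab)) {
      abort_config("survival table lacks the 'marker' column")
    }

    status <- bcr_status_at_horizon(tab$time_months, tab$event, horizon)
    rule <- derive_cutoff(tab[[marker]], status, marker = marker,
                          horizon = horizon)
    jsonlite::write_json(unclass(rule), file.path(out_dir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    high <- tab[[marker]] > rule$cutoff
    km_high <- kaplan_meier(tab$time_months[high], tab$event[high])
    km_low <- kaplan_meier(tab$time_months[!high], tab$event[!high])
    km_df <- rbind(cbind(group = "high", km_high$steps),
                   cbind(group = "low", km_low$steps))
    write.csv(km_df, file.path(out_dir, sprintf("km_%s.csv", marker)),
              row.names = FALSE)
    lr <- logrank(tab$time_months, tab$event,
                  ifelse(high, "high", "low"))

    uni_vars <- c(marker, clinical)
    uni <- lapply(uni_vars, function(v) {
      f <- cox_fit(tab[, v, drop = FALSE], tab$time_months, tab$event)
      cbind(f$coefficients, c_index = f$concordance)
    })
    uni <- do.call(rbind, uni)
    # markers form the adjustment family (clinical rows keep raw p-values)
    uni$adjusted_p <- uni$p_value
    is_marker <- uni$term %in% marker
    uni$adjusted_p[is_marker] <- adjust_pvalues(uni$p_value[is_marker],
                                                adjust_method)
    write.csv(uni, file.path(out_dir, "univariate.csv"), row.names = FALSE)

    bs <- backward_select(tab[, uni_vars, drop = FALSE], tab$time_months,
                          tab$event, alpha = 0.05, marker_vars = marker)
    multi <- bs$final$coefficients
    multi$c_index_full <- bs$c_index_full
    multi$c_index_clinical <- bs$c_index_clinical
    write.csv(multi, file.path(out_dir, "multivariate.csv"),
              row.names = FALSE)
    jsonlite::write_json(bs$trace, file.path(out_dir,
                                             "elimination_trace.json"),
                         digits = NA, pretty = TRUE)

    subgroups <- if ("damico" %in% names(tab)) {
      sg <- subgroup_analysis(tab, "damico", rule)
      jsonlite::write_json(lapply(sg, unclass),
                           file.path(out_dir, "subgroups.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      lapply(sg, function(e) {
        e[c("stratum", "n", "testable",
            intersect("logrank_p", names(e)))]
      })
    }

    list(n_patients = nrow(tab),
         n_events = sum(tab$event),
         cutoff = rule$cutoff,
         km_median_high = km_high$median,
         km_median_low = km_low$median,
         logrank_p = lr$p_value,
         marker_hr_univariate = uni$hr[match(marker, uni$term)],
         marker_p_adjusted = uni$adjusted_p[match(marker, uni$term)],
         retained = bs$retained,
         c_index_full = bs$c_index_full,
         c_index_clinical = bs$c_index_clinical,
         truth_coefficients = if (!is.null(truth)) as.list(truth),
         subgroups = subgroups)
  })

  report$status <- if (failed) "failed" else "ok"
  class(report) <- "pipeline_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s v%s, seed %d: %s\n", x$package,
              x$version, x$seed, x$status))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-18s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  invisible(x)
}
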