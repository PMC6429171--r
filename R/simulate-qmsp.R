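#' Configuration for qMSP plate simulation
#'
#' Describes one simulated 384-well-style qMSP run: which sample-target
#' combinations are on the plate with what true template quantity, the
#' standard-curve dilution series, and the Ct noise model. Ct values derive
#' from true quantity through the standard log-linear qPCR relation
#' `Ct = intercept + slope * log10(quantity)`; the default slope of
#' -log2(10) = -3.3219 cycles per decade corresponds to 100% amplification
#' efficiency (template doubling each cycle).
#'
#' @param true_quantities Data frame with columns `sample_id`, `target`,
#'   `quantity` (arbitrary units, `>= 0`; 0 means no methylated template and
#'   yields undetermined Ct values). Every sample must carry rows for the
#'   reference assays `ALUC4` and `MYOD1` in addition to its marker assays.
#' @param standard_log10_quantities Decreasing vector of log10 quantities for
#'   the serial-dilution standards (default 1e5 down to 1e2 in 10-fold steps).
#' @param curve_intercept,curve_slope Parameters of the Ct-quantity relation;
#'   `curve_slope` must be negative.
#' @param noise_sd Standard deviation (cycles) of Gaussian Ct noise.
#' @param outlier_rate Probability that a triplicate receives one injected
#'   outlier replicate, displaced by 3-5 cycles so it always deviates by
#'   more than 2 cycles from its siblings.
#' @param max_cycles Cycle ceiling of the instrument; computed Ct values
#'   beyond it are reported as undetermined (default 40).
#' @param seed Integer seed.
#' @return A `plate_config` object.
#' @export
plate_config <- function(true_quantities,
                         standard_log10_quantities = c(5, 4, 3, 2),
                         curve_intercept = 38,
                         curve_slope = -1 / log10(2), # -3.3219: 100% efficiency
                         noise_sd = 0.25,
                         outlier_rate = 0,
                         max_cycles = 40,
                         seed = 1L) {
  tq <- true_quantities
  require_columns(tq, c("sample_id", "target", "quantity"), "true_quantities")
  if (!nrow(tq)) abort_config("true_quantities must have at least one row")
  if (any(!is.finite(tq$quantity)) || any(tq$quantity < 0)) {
    abort_config("true quantities must be finite and >= 0")
  }
  if (anyDuplicated(tq[, c("sample_id", "target")])) {
    abort_config("true_quantities must have one row per sample-target")
  }
  targets <- unique(tq$target)
  if (!length(setdiff(targets, REFERENCE_TARGETS))) {
    abort_config("true_quantities must include at least one marker target")
  }
  for (ref in REFERENCE_TARGETS) {
    lacking <- setdiff(unique(tq$sample_id),
                       tq$sample_id[tq$target == ref])
    if (length(lacking)) {
      abort_config(sprintf("sample(s) without a %s reference row: %s",
                           ref, oxford(utils::head(lacking, 5))))
    }
  }
  d <- diff(standard_log10_quantities)
  if (length(standard_log10_quantities) < 3 || any(d >= 0)) {
    abort_config("standard_log10_quantities must be >= 3 strictly decreasing points")
  }
  if (!is_scalar_number(curve_slope) || curve_slope >= 0) {
    abort_config("curve_slope must be negative")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_config("noise_sd must be >= 0")
  }
  if (!is_scalar_number(outlier_rate) || outlier_rate < 0 || outlier_rate > 1) {
    abort_config("outlier_rate must be in [0, 1]")
  }
  if (!is_count(seed)) abort_config("seed must be a single integer")
  structure(list(true_quantities = tq,
                 targets = targets,
                 standard_log10_quantities = standard_log10_quantities,
                 curve_intercept = curve_intercept,
                 curve_slope = curve_slope,
                 noise_sd = noise_sd,
                 outlier_rate = outlier_rate,
                 max_cycles = max_cycles,
                 seed = as.integer(seed)),
            class = "plate_config")
}

#' Simulate a qMSP plate with known true quantities
#'
#' Lays out, for every sample-target pair, a triplicate of wells plus, per
#' target, a triplicate standard-curve dilution series, a fully methylated
#' positive control, a fully unmethylated (whole-genome amplified) negative
#' control and a water control. Numeric Ct values follow the configured
#' log-linear relation plus Gaussian noise; wells with zero template, or
#' whose computed Ct exceeds the cycle ceiling, are undetermined (`NA`).
#'
#' @param cfg A [plate_config()].
#' @return List with components:
#'   \describe{
#'     \item{plate}{data frame of wells: `well`, `sample_id`, `target`,
#'       `role`, `replicate`, `ct` (`NA` = undetermined), `known_quantity`
#'       (filled for standards and positive controls).}
#'     \item{truth}{data frame of true per-sample marker quantities and
#'       ALUC4-normalized levels.}
#'   }
#' @seealso [process_plate()] for the reduction that inverts this generator.
#' @export
generate_qmsp_plate <- function(cfg) {
  if (!inherits(cfg, "plate_config")) abort_config("cfg must be a plate_config")
  tq <- cfg$true_quantities
  targets <- cfg$targets
  std_q <- 10^cfg$standard_log10_quantities

  rows <- list(); k <- 0L
  add <- function(sample_id, target, role, quantity) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(sample_id = sample_id, target = target,
                             role = role, replicate = 1:3,
                             true_quantity = quantity,
                             stringsAsFactors = FALSE)
  }
  for (tg in targets) {
    for (j in seq_along(std_q)) {
      add(sprintf("std_%s_%d", tg, j), tg, "standard", std_q[j])
    }
    add(sprintf("pos_ctrl_%s", tg), tg, "pos_ctrl", std_q[1])
    add(sprintf("neg_ctrl_wga_%s", tg), tg, "neg_ctrl_wga", 0)
    add(sprintf("neg_ctrl_water_%s", tg), tg, "neg_ctrl_water", 0)
  }
  for (i in seq_len(nrow(tq))) {
    add(tq$sample_id[i], tq$target[i], "unknown", tq$quantity[i])
  }
  wells <- do.call(rbind, rows)
  n <- nrow(wells)

  clean_ct <- ifelse(wells$true_quantity > 0,
                     cfg$curve_intercept +
                       cfg$curve_slope * log10(wells$true_quantity),
                     NA_real_)
  ct <- with_seed(substream_seed(cfg$seed, "ct_noise"), {
    clean_ct + if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  })

  if (cfg$outlier_rate > 0) {
    ct <- with_seed(substream_seed(cfg$seed, "outliers"), {
      key <- paste(wells$sample_id, wells$target)
      for (kk in unique(key[wells$role == "unknown"])) {
        idx <- which(key == kk)
        if (all(is.na(clean_ct[idx]))) next
        if (runif(1) < cfg$outlier_rate) {
          hit <- sample(idx, 1L)
          # displace the clean value by 3-5 cycles: always > 2 cycles away
          # from the other replicates' (noisy) values
          ct[hit] <- clean_ct[hit] + sample(c(-1, 1), 1L) * runif(1, 3, 5)
        }
      }
      ct
    })
  }
  ct[!is.na(ct) & ct > cfg$max_cycles] <- NA_real_
  ct[!is.na(ct) & ct <= 0] <- NA_real_

  plate <- data.frame(
    well = sprintf("W%04d", seq_len(n)),
    sample_id = wells$sample_id,
    target = wells$target,
    role = wells$role,
    replicate = wells$replicate,
    ct = ct,
    known_quantity = ifelse(wells$role %in% c("standard", "pos_ctrl"),
                            wells$true_quantity, NA_real_),
    stringsAsFactors = FALSE)

  marker_targets <- setdiff(targets, REFERENCE_TARGETS)
  ref_q <- tq[tq$target == "ALUC4", c("sample_id", "quantity")]
  truth <- tq[tq$target %in% marker_targets, , drop = FALSE]
  truth$normalized_level <- truth$quantity /
    ref_q$quantity[match(truth$sample_id, ref_q$sample_id)]
  truth$normalized_level[truth$quantity == 0] <- 0
  rownames(truth) <- NULL

  list(plate = plate, truth = truth)
}
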