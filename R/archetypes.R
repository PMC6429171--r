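#' Marker archetype for beta-value simulation
#'
#' An archetype describes one class of CpG site by the per-tissue-group Beta
#' distributions its beta values are drawn from, together with its intended
#' fate under the discovery cascade (pass or fail the blood pre-filter, be
#' selected by search string 1 and/or search string 2). The intent fields
#' make every planted CpG machine-checkable against the cascade's verdict.
#'
#' @param name Archetype name, one of `"pca_specific"`, `"pan_cancer"`,
#'   `"blood_methylated"`, `"globally_methylated"`,
#'   `"globally_unmethylated"`, `"near_miss"` (free names are allowed for
#'   custom archetypes).
#' @param shapes Named list with one entry per tissue group
#'   (`peripheral_blood`, `normal_prostate`, `prostate_cancer`,
#'   `other_normal`, `other_cancer`), each a numeric vector `c(a, b)` of
#'   strictly positive Beta shape parameters.
#' @param passes_blood_filter Logical: should a CpG of this archetype survive
#'   the blood pre-filter?
#' @param selected_string1,selected_string2 Logical: should it be selected by
#'   the pan-cancer / PCa-specific search string?
#' @return An object of class `marker_archetype`.
#' @seealso [default_archetypes()], [generate_beta_matrix()]
#' @export
marker_archetype <- function(name, shapes, passes_blood_filter,
                             selected_string1, selected_string2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_config("archetype name must be a non-empty string")
  }
  missing <- setdiff(TISSUE_GROUPS, names(shapes))
  if (length(missing)) {
    abort_config(sprintf("archetype '%s' lacks shape parameters for group(s): %s",
                         name, oxford(missing)))
  }
  for (g in TISSUE_GROUPS) {
    ab <- shapes[[g]]
    if (!is.numeric(ab) || length(ab) != 2L || any(!is.finite(ab)) ||
        any(ab <= 0)) {
      abort_config(sprintf(
        "archetype '%s', group '%s': shape parameters must be two positive numbers",
        name, g))
    }
  }
  for (flag in list(passes_blood_filter, selected_string1, selected_string2)) {
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag)) {
      abort_config("archetype intent flags must be TRUE or FALSE")
    }
  }
  structure(
    list(name = name, shapes = shapes[TISSUE_GROUPS],
         passes_blood_filter = passes_blood_filter,
         selected_string1 = selected_string1,
         selected_string2 = selected_string2),
    class = "marker_archetype")
}

#' Calibrated default archetype set
#'
#' Six CpG classes spanning the outcomes the discovery cascade separates.
#' Shape parameters are calibrated so that, at realistic group sizes, each
#' archetype's cascade verdict matches its declared intent with per-CpG
#' probability well above 0.99:
#'
#' * `pca_specific` — hypermethylated in prostate cancer (Beta(8, 2)),
#'   unmethylated everywhere else; selected by both search strings.
#' * `pan_cancer` — hypermethylated in prostate cancer *and* other cancers;
#'   selected by string 1 only (string 2's other-cancer exclusion removes it).
#' * `blood_methylated` — a would-be marker that is methylated in blood
#'   leukocytes (Beta(5, 5)); removed by the blood pre-filter.
#' * `globally_methylated` — methylated in every group; removed by the blood
#'   pre-filter.
#' * `globally_unmethylated` — unmethylated everywhere (Beta(1, 50));
#'   survives the blood filter but fails both hypermethylation selections.
#' * `near_miss` — hypermethylated in prostate cancer but with appreciable
#'   normal-prostate methylation (Beta(3, 3)); fails exactly one predicate of
#'   each search string (the normal-prostate exclusion).
#'
#' @return Named list of [marker_archetype] objects.
#' @export
default_archetypes <- function() {
  lo  <- c(1, 20)   # essentially unmethylated tissue
  bg  <- c(1, 50)   # blood background: P(beta > 0.2) ~ 1.4e-5
  hi  <- c(8, 2)    # hypermethylated: P(beta > 0.5) ~ 0.98
  mid <- c(3, 3)    # intermediate methylation, P(beta > 0.2) ~ 0.94
  list(
    pca_specific = marker_archetype(
      "pca_specific",
      list(peripheral_blood = bg, normal_prostate = lo, prostate_cancer = hi,
           other_normal = lo, other_cancer = lo),
      passes_blood_filter = TRUE, selected_string1 = TRUE,
      selected_string2 = TRUE),
    pan_cancer = marker_archetype(
      "pan_cancer",
      list(peripheral_blood = bg, normal_prostate = lo, prostate_cancer = hi,
           other_normal = lo, other_cancer = hi),
      passes_blood_filter = TRUE, selected_string1 = TRUE,
      selected_string2 = FALSE),
    blood_methylated = marker_archetype(
      "blood_methylated",
      list(peripheral_blood = c(5, 5), normal_prostate = lo,
           prostate_cancer = hi, other_normal = lo, other_cancer = lo),
      passes_blood_filter = FALSE, selected_string1 = FALSE,
      selected_string2 = FALSE),
    globally_methylated = marker_archetype(
      "globally_methylated",
      list(peripheral_blood = hi, normal_prostate = hi, prostate_cancer = hi,
           other_normal = hi, other_cancer = hi),
      passes_blood_filter = FALSE, selected_string1 = FALSE,
      selected_string2 = FALSE),
    globally_unmethylated = marker_archetype(
      "globally_unmethylated",
      list(peripheral_blood = bg, normal_prostate = bg, prostate_cancer = bg,
           other_normal = bg, other_cancer = bg),
      passes_blood_filter = TRUE, selected_string1 = FALSE,
      selected_string2 = FALSE),
    near_miss = marker_archetype(
      "near_miss",
      list(peripheral_blood = bg, normal_prostate = mid, prostate_cancer = hi,
           other_normal = lo, other_cancer = lo),
      passes_blood_filter = TRUE, selected_string1 = FALSE,
      selected_string2 = FALSE))
}

#' @export
print.marker_archetype <- function(x, ...) {
  cat(sprintf("<marker_archetype> %s\n", x$name))
  for (g in names(x$shapes)) {
    cat(sprintf("  %-18s Beta(%g, %g)\n", g, x$shapes[[g]][1], x$shapes[[g]][2]))
  }
  cat(sprintf("  intent: blood filter %s, string 1 %s, string 2 %s\n",
              if (x$passes_blood_filter) "pass" else "fail",
              if (x$selected_string1) "selected" else "not selected",
              if (x$selected_string2) "selected" else "not selected"))
  invisible(x)
}
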