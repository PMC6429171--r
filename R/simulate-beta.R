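#' Configuration for beta-matrix simulation
#'
#' Defaults mirror the tissue-group composition of a large 450K compendium
#' discovery set (876 blood / 81 normal prostate / 187 prostate cancer /
#' 634 other normal / 2294 other cancer samples), scaled down by a factor of
#' four to keep simulated matrices desk-sized while preserving the filter
#' denominators' relative resolution.
#'
#' @param group_sizes Named integer vector of samples per tissue group; all
#'   five groups required, each at least 1.
#' @param cpgs_per_archetype Number of CpG sites to plant per archetype;
#'   either a single count or a vector named by archetype.
#' @param missing_rate Probability that any single beta value is missing
#'   (missing completely at random); in `[0, 1)`.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(group_sizes = c(peripheral_blood = 219L,
                                              normal_prostate = 20L,
                                              prostate_cancer = 47L,
                                              other_normal = 158L,
                                              other_cancer = 573L),
                              cpgs_per_archetype = 200L,
                              missing_rate = 0.01,
                              seed = 1L) {
  missing <- setdiff(TISSUE_GROUPS, names(group_sizes))
  if (length(missing)) {
    abort_config(sprintf("group_sizes must name all tissue groups; missing: %s",
                         oxford(missing)))
  }
  gs <- group_sizes[TISSUE_GROUPS]
  if (any(!vapply(gs, is_count, logical(1), min = 1L))) {
    abort_config("every group size must be a positive integer")
  }
  if (!all(vapply(cpgs_per_archetype, is_count, logical(1), min = 1L))) {
    abort_config("cpgs_per_archetype must be positive integer(s)")
  }
  if (!is_scalar_number(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort_config("missing_rate must be in [0, 1)")
  }
  if (!is_count(seed)) abort_config("seed must be a single integer")
  structure(list(group_sizes = vapply(gs, as.integer, integer(1)),
                 cpgs_per_archetype = cpgs_per_archetype,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a grouped beta-value matrix with planted marker archetypes
#'
#' Draws, for each planted CpG, group-conditional beta values from the
#' archetype's Beta distributions, inserts missing values completely at
#' random, and returns the matrix together with its sample annotation and a
#' truth table mapping every CpG to the archetype it was drawn from.
#'
#' @param cfg A [simulation_config()].
#' @param archetypes List of [marker_archetype] objects (default
#'   [default_archetypes()]).
#' @return List with components:
#'   \describe{
#'     \item{beta}{numeric matrix, CpG x sample, values in `[0, 1]` or `NA`;
#'       row names are `cg`-prefixed CpG ids, column names sample ids.}
#'     \item{annotation}{data frame with `sample_id`, `group`, `subtype`.}
#'     \item{truth}{data frame with `cpg_id`, `archetype`; covers every CpG
#'       exactly once.}
#'   }
#' @examples
#' sim <- generate_beta_matrix(simulation_config(
#'   group_sizes = c(peripheral_blood = 20, normal_prostate = 5,
#'                   prostate_cancer = 8, other_normal = 5, other_cancer = 10),
#'   cpgs_per_archetype = 3, seed = 7))
#' dim(sim$beta)
#' table(sim$truth$archetype)
#' @export
generate_beta_matrix <- function(cfg, archetypes = default_archetypes()) {
  if (!inherits(cfg, "simulation_config")) {
    abort_config("cfg must be a simulation_config")
  }
  if (!length(archetypes)) abort_config("archetype list must be non-empty")
  if (!all(vapply(archetypes, inherits, logical(1), "marker_archetype"))) {
    abort_config("archetypes must be marker_archetype objects")
  }
  arch_names <- vapply(archetypes, `[[`, character(1), "name")
  counts <- cfg$cpgs_per_archetype
  if (length(counts) == 1L && is.null(names(counts))) {
    counts <- setNames(rep(as.integer(counts), length(archetypes)), arch_names)
  } else {
    missing <- setdiff(arch_names, names(counts))
    if (length(missing)) {
      abort_config(sprintf("cpgs_per_archetype lacks counts for: %s",
                           oxford(missing)))
    }
    counts <- vapply(counts[arch_names], as.integer, integer(1))
  }

  n_cpg <- sum(counts)
  gs <- cfg$group_sizes
  sample_ids <- unlist(lapply(TISSUE_GROUPS, function(g) {
    sprintf("%s_%04d", g, seq_len(gs[[g]]))
  }), use.names = FALSE)
  group_of <- rep(TISSUE_GROUPS, times = gs[TISSUE_GROUPS])
  cpg_ids <- sprintf("cg%08d", seq_len(n_cpg))

  beta <- matrix(NA_real_, nrow = n_cpg, ncol = length(sample_ids),
                 dimnames = list(cpg_ids, sample_ids))
  with_seed(substream_seed(cfg$seed, "beta"), {
    row0 <- 0L
    for (i in seq_along(archetypes)) {
      arch <- archetypes[[i]]
      rows <- row0 + seq_len(counts[[arch_names[i]]])
      for (g in TISSUE_GROUPS) {
        cols <- which(group_of == g)
        ab <- arch$shapes[[g]]
        beta[rows, cols] <- rbeta(length(rows) * length(cols), ab[1], ab[2])
      }
      row0 <- row0 + length(rows)
    }
  })
  if (cfg$missing_rate > 0) {
    with_seed(substream_seed(cfg$seed, "missing"), {
      beta[runif(length(beta)) < cfg$missing_rate] <- NA_real_
    })
  }

  # deterministic subtype labels so annotations exercise the free-text field
  subtype_pool <- list(
    peripheral_blood = c("whole_blood", "buffycoat"),
    normal_prostate = "prostate",
    prostate_cancer = "prostate",
    other_normal = c("colorectal", "lung", "kidney", "liver"),
    other_cancer = c("colorectal", "lung", "kidney", "liver", "bladder",
                     "melanoma"))
  subtype <- unlist(lapply(TISSUE_GROUPS, function(g) {
    pool <- subtype_pool[[g]]
    pool[(seq_len(gs[[g]]) - 1L) %% length(pool) + 1L]
  }), use.names = FALSE)

  list(beta = beta,
       annotation = data.frame(sample_id = sample_ids, group = group_of,
                               subtype = subtype, stringsAsFactors = FALSE),
       truth = data.frame(cpg_id = cpg_ids,
                          archetype = rep(arch_names, times = counts),
                          stringsAsFactors = FALSE))
}
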