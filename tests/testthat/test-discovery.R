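# Discovery cascade: the fraction primitive, per-stage rules, strict
# boundary semantics, candidate summaries and the assembled report.

test_that("fraction_above counts strictly and ignores missing values", {
  expect_equal(fraction_above(c(0.1, 0.1, 0.1), 0.2), 0)
  expect_equal(fraction_above(c(0.25, 0.15, NA, 0.30), 0.2), 2 / 3)
  expect_equal(fraction_above(c(0.2, 0.2), 0.2), 0)
  expect_error(fraction_above(c(NA_real_, NA_real_), 0.2),
               class = "methmark_degenerate_error")
  # agreement with the loop oracle on random vectors with missingness
  set.seed(42)
  for (i in 1:25) {
    v <- runif(20)
    v[runif(20) < 0.2] <- NA
    if (all(is.na(v))) next
    cut <- runif(1)
    expect_equal(fraction_above(v, cut), oracle_frac_above(v, cut))
  }
})

test_that("blood filter retains at exactly the 1% bound (strict 'more than')", {
  # 100 blood samples: 1 above 0.2 is exactly 1% -> retained; 2 -> excluded
  gs <- list(peripheral_blood = 100, normal_prostate = 4,
             prostate_cancer = 4, other_normal = 4, other_cancer = 4)
  base <- list(normal_prostate = rep(0.05, 4), prostate_cancer = rep(0.9, 4),
               other_normal = rep(0.05, 4), other_cancer = rep(0.05, 4))
  at_bound <- c(base, list(peripheral_blood = c(0.5, rep(0.05, 99))))
  above <- c(base, list(peripheral_blood = c(0.5, 0.5, rep(0.05, 98))))
  at_cut <- c(base, list(peripheral_blood = c(rep(0.2, 50), rep(0.05, 50))))
  fx <- make_grouped_matrix(list(at_bound, above, at_cut), gs)
  kept <- blood_filter(fx$beta, fx$annotation)
  expect_identical(kept, c("cg00000001", "cg00000003"))
})

test_that("planted blood-methylated CpGs are excluded and the rest retained", {
  cfg <- simulation_config(
    group_sizes = c(peripheral_blood = 200, normal_prostate = 10,
                    prostate_cancer = 20, other_normal = 10,
                    other_cancer = 20),
    cpgs_per_archetype = c(blood_methylated = 7, globally_unmethylated = 13),
    missing_rate = 0, seed = 9)
  arch <- default_archetypes()[c("blood_methylated", "globally_unmethylated")]
  sim <- generate_beta_matrix(cfg, arch)
  kept <- blood_filter(sim$beta, sim$annotation)
  expect_length(kept, 13)
  expect_setequal(kept,
                  sim$truth$cpg_id[sim$truth$archetype == "globally_unmethylated"])
})

test_that("search strings apply their bounds strictly at the boundary", {
  gs <- list(peripheral_blood = 10, normal_prostate = 100,
             prostate_cancer = 100, other_normal = 10, other_cancer = 100)
  blood0 <- rep(0.01, 10)
  oth0 <- rep(0.01, 10)
  frac_vec <- function(n_above, n, hi = 0.9, lo = 0.01) {
    c(rep(hi, n_above), rep(lo, n - n_above))
  }
  rows <- list(
    # PCa hypermethylated fraction exactly 0.80: NOT selected by string 1
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(80, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # 81% PCa: selected by string 1 (and 2)
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(81, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # normal prostate exactly 19% above 0.2: retained by string 1
    list(peripheral_blood = blood0, normal_prostate = frac_vec(19, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # normal prostate 20%: excluded by string 1, retained by string 2
    list(peripheral_blood = blood0, normal_prostate = frac_vec(20, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # PCa exactly 60%: NOT selected by string 2
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(60, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # PCa 61%: selected by string 2 only
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(61, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # other cancer exactly 8% above 0.2: retained by string 2
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(8, 100)),
    # other cancer 10%: excluded by string 2 regardless of PCa methylation
    list(peripheral_blood = blood0, normal_prostate = frac_vec(0, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(10, 100)),
    # normal prostate exactly 30%: retained by string 2, excluded by string 1
    list(peripheral_blood = blood0, normal_prostate = frac_vec(30, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)),
    # normal prostate 31%: excluded by string 2 as well
    list(peripheral_blood = blood0, normal_prostate = frac_vec(31, 100),
         prostate_cancer = frac_vec(95, 100), other_normal = oth0,
         other_cancer = frac_vec(0, 100)))
  fx <- make_grouped_matrix(rows, gs)
  ids <- rownames(fx$beta)
  s1 <- select_pan_cancer(fx$beta, fx$annotation)
  s2 <- select_pca_specific(fx$beta, fx$annotation)
  expect_setequal(s1, ids[c(2, 3, 7, 8)])
  # row 1 (exactly 80% PCa) misses string 1 but clears string 2's 60% bound
  expect_setequal(s2, ids[c(1, 2, 3, 4, 6, 7, 9)])
})

test_that("beta values exactly at 0.5 do not count as hypermethylated", {
  gs <- list(peripheral_blood = 5, normal_prostate = 5,
             prostate_cancer = 10, other_normal = 5, other_cancer = 5)
  row <- list(peripheral_blood = rep(0.01, 5), normal_prostate = rep(0.01, 5),
              prostate_cancer = rep(0.5, 10), other_normal = rep(0.01, 5),
              other_cancer = rep(0.01, 5))
  fx <- make_grouped_matrix(list(row), gs)
  expect_length(select_pan_cancer(fx$beta, fx$annotation), 0)
  expect_length(select_pca_specific(fx$beta, fx$annotation), 0)
})

test_that("selection is invariant to sample and CpG order", {
  sim <- generate_beta_matrix(simulation_config(
    group_sizes = c(peripheral_blood = 50, normal_prostate = 10,
                    prostate_cancer = 20, other_normal = 10,
                    other_cancer = 40),
    cpgs_per_archetype = 8, seed = 13))
  set.seed(99)
  perm_s <- sample(ncol(sim$beta))
  perm_c <- sample(nrow(sim$beta))
  shuffled <- sim$beta[perm_c, perm_s]
  ann_shuffled <- sim$annotation[sample(nrow(sim$annotation)), ]
  a <- run_discovery(sim$beta, sim$annotation)
  b <- run_discovery(shuffled, ann_shuffled)
  expect_setequal(a$pan_cancer, b$pan_cancer)
  expect_setequal(a$pca_specific, b$pca_specific)
})

test_that("raising the hypermethylation cutoff never grows a candidate set", {
  sim <- generate_beta_matrix(simulation_config(
    group_sizes = c(peripheral_blood = 40, normal_prostate = 10,
                    prostate_cancer = 20, other_normal = 10,
                    other_cancer = 30),
    cpgs_per_archetype = 15, seed = 14))
  loose <- filter_thresholds(beta_hyper = 0.4)
  tight <- filter_thresholds(beta_hyper = 0.6)
  expect_true(all(select_pan_cancer(sim$beta, sim$annotation, tight) %in%
                    select_pan_cancer(sim$beta, sim$annotation, loose)))
  # and raising the other-cancer tolerance never shrinks string 2
  strict <- filter_thresholds(s2_othercancer_max_frac = 0.02)
  lax <- filter_thresholds(s2_othercancer_max_frac = 0.20)
  expect_true(all(select_pca_specific(sim$beta, sim$annotation, strict) %in%
                    select_pca_specific(sim$beta, sim$annotation, lax)))
})

test_that("candidate summaries report medians, effects and incomplete groups", {
  gs <- list(peripheral_blood = 6, normal_prostate = 8, prostate_cancer = 8,
             other_normal = 6, other_cancer = 6)
  clear <- list(peripheral_blood = rep(0.1, 6), normal_prostate = rep(0.1, 8),
                prostate_cancer = rep(0.9, 8), other_normal = rep(0.1, 6),
                other_cancer = rep(0.1, 6))
  flat <- list(peripheral_blood = rep(0.1, 6),
               normal_prostate = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
               prostate_cancer = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
               other_normal = rep(0.1, 6), other_cancer = rep(0.1, 6))
  missing_grp <- clear
  missing_grp$other_normal <- rep(NA_real_, 6)
  fx <- make_grouped_matrix(list(clear, flat, missing_grp), gs)
  s <- summarize_candidates(fx$beta, fx$annotation, rownames(fx$beta))
  expect_equal(s$median_difference[1], 0.8)
  expect_true(s$passes_effect_criterion[1])
  # identical PCa and normal-prostate distributions: no effect
  expect_gt(s$mw_p[2], 0.05)
  expect_false(s$passes_effect_criterion[2])
  # a group with no values flags the row incomplete but keeps it
  expect_true(s$incomplete[3])
  expect_false(s$passes_effect_criterion[3])
  expect_equal(nrow(s), 3)
})

test_that("run_discovery matches planted intent and conserves stage counts", {
  arch <- default_archetypes()[c("pca_specific", "pan_cancer",
                                 "blood_methylated", "globally_unmethylated",
                                 "near_miss")]
  cfg <- simulation_config(
    group_sizes = c(peripheral_blood = 219, normal_prostate = 20,
                    prostate_cancer = 47, other_normal = 30,
                    other_cancer = 150),
    cpgs_per_archetype = 5, missing_rate = 0, seed = 21)
  sim <- generate_beta_matrix(cfg, arch)
  rep <- run_discovery(sim$beta, sim$annotation)
  want_s1 <- sim$truth$cpg_id[sim$truth$archetype %in%
                                c("pca_specific", "pan_cancer")]
  want_s2 <- sim$truth$cpg_id[sim$truth$archetype == "pca_specific"]
  expect_setequal(rep$pan_cancer, want_s1)
  expect_setequal(rep$pca_specific, want_s2)
  expect_true(all(rep$stages$n_in - rep$stages$n_excluded ==
                    rep$stages$n_out))
  expect_setequal(rep$union, union(rep$pan_cancer, rep$pca_specific))
})

test_that("an empty candidate outcome still yields a valid report", {
  gs <- list(peripheral_blood = 10, normal_prostate = 5, prostate_cancer = 5,
             other_normal = 5, other_cancer = 5)
  row <- list(peripheral_blood = rep(0.05, 10), normal_prostate = rep(0.05, 5),
              prostate_cancer = rep(0.05, 5), other_normal = rep(0.05, 5),
              other_cancer = rep(0.05, 5))
  fx <- make_grouped_matrix(list(row, row), gs)
  rep <- run_discovery(fx$beta, fx$annotation)
  expect_length(rep$pan_cancer, 0)
  expect_length(rep$pca_specific, 0)
  expect_equal(nrow(rep$summaries), 0)
  path <- withr::local_tempfile(fileext = ".json")
  expect_no_error(write_filter_report(rep, path))
})

test_that("missing tissue groups raise configuration errors", {
  gs <- list(peripheral_blood = 5, normal_prostate = 5, prostate_cancer = 5,
             other_normal = 5, other_cancer = 5)
  row <- list(peripheral_blood = rep(0.1, 5), normal_prostate = rep(0.1, 5),
              prostate_cancer = rep(0.1, 5), other_normal = rep(0.1, 5),
              other_cancer = rep(0.1, 5))
  fx <- make_grouped_matrix(list(row), gs)
  ann_noblood <- fx$annotation[fx$annotation$group != "peripheral_blood", ]
  beta_noblood <- fx$beta[, ann_noblood$sample_id, drop = FALSE]
  expect_error(blood_filter(beta_noblood, ann_noblood),
               class = "methmark_config_error")
  expect_error(run_discovery(beta_noblood, ann_noblood),
               class = "methmark_config_error")
})
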