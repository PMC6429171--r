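# Prognostic stack: horizon status, ROC cutoffs, Kaplan-Meier, log-rank,
# Cox, concordance, backward selection, adjustment and subgroups.

test_that("horizon status distinguishes positives, negatives and excluded", {
  st <- bcr_status_at_horizon(time = c(20, 30, 48, 36, 36, 40),
                              event = c(1, 0, 0, 1, 0, 1), horizon = 36)
  expect_identical(st, c(1L, NA_integer_, 0L, 1L, 0L, 0L))
})

test_that("derive_cutoff maximizes Youden's J and breaks ties to specificity", {
  # perfect separation at 0.5: J = 1 and the cutoff sits between clusters
  lv <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  st <- c(0, 0, 0, 1, 1, 1)
  rule <- derive_cutoff(lv, st)
  expect_equal(rule$youden_j, 1)
  expect_gt(rule$cutoff, 0.3); expect_lt(rule$cutoff, 0.7)
  expect_true(all((lv > rule$cutoff) == (st == 1)))
  # all levels identical: no informative threshold
  expect_error(derive_cutoff(rep(1, 6), st),
               class = "methmark_degenerate_error")
  # one-class statuses
  expect_error(derive_cutoff(lv, rep(1, 6)),
               class = "methmark_degenerate_error")
  # counts reflect exclusions
  rule <- derive_cutoff(c(lv, 0.5), c(st, NA))
  expect_equal(rule$n_excluded, 1)
})

test_that("a hazard change-point cutoff is recovered near the truth", {
  # hazard doubles above marker 0.5; the ROC-derived cutoff should land
  # inside the central bulk of a Monte-Carlo distribution around 0.5
  set.seed(20)
  cuts <- replicate(50, {
    n <- 300
    marker <- runif(n)
    rate <- ifelse(marker > 0.5, 0.06, 0.02)
    time <- rexp(n, rate)
    event <- as.integer(time <= 120); time <- pmin(time, 120)
    derive_cutoff(marker, bcr_status_at_horizon(time, event, 36))$cutoff
  })
  expect_lt(abs(median(cuts) - 0.5), 0.1)
  expect_gt(mean(abs(cuts - 0.5) < 0.25), 0.8)
})

test_that("Kaplan-Meier matches hand and risk-set-product computations", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$steps$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  # classic toy with ties and censoring at 6
  time <- c(6, 6, 6, 6, 7, 10)
  event <- c(1, 1, 1, 0, 1, 1)
  km <- kaplan_meier(time, event)
  oracle <- oracle_km(time, event)
  expect_equal(km$steps$surv[km$steps$n_event > 0], oracle$surv,
               tolerance = 1e-12)
  expect_equal(km$steps$surv[1], 1 - 3 / 6)
  # all censored: flat curve, median not reached
  km <- kaplan_meier(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$steps$surv == 1))
  expect_true(is.na(km$median))
})

test_that("Kaplan-Meier equals the risk-set product oracle on random data", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    time <- sample(1:24, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    km <- kaplan_meier(time, event)
    oracle <- oracle_km(time, event)
    got <- km$steps[km$steps$n_event > 0, ]
    expect_equal(got$time, oracle$time)
    expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
    expect_equal(km$median, oracle_km_median(time, event))
  }
})

test_that("log-rank is null on identical groups and matches the Cox score test", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank(time, event, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  # tie-free random instances: chi-square within 5% of the Cox score test
  set.seed(22)
  for (i in 1:10) {
    coh <- simple_ph_cohort(200, beta = 0.5, cens_rate = 0.01)
    lr <- logrank(coh$time, coh$event, coh$x)
    sc <- survival::coxph(survival::Surv(coh$time, coh$event) ~ coh$x)$score
    expect_lt(abs(lr$statistic - sc), 0.05 * max(sc, 1))
  }
})

test_that("log-rank detects a planted hazard ratio of 3", {
  set.seed(23)
  hits <- replicate(40, {
    x <- rep(c(0, 1), each = 150)
    time <- rexp(300, 0.02 * exp(log(3) * x))
    cens <- runif(300, 0, 150)
    event <- as.integer(time <= cens)
    logrank(pmin(time, cens), event, x)$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Cox fits recover null and planted coefficients with sane intervals", {
  set.seed(24)
  coh <- simple_ph_cohort(1000, beta = 0, cens_rate = 0.01)
  fit <- cox_fit(data.frame(x = coh$x), coh$time, coh$event)
  expect_lt(abs(fit$coefficients$coef), 3 * fit$coefficients$se)
  coh <- simple_ph_cohort(1000, beta = 0.7, cens_rate = 0.01)
  fit <- cox_fit(data.frame(x = coh$x), coh$time, coh$event)
  expect_gt(fit$coefficients$coef, 0.4)
  expect_lt(fit$coefficients$coef, 1.0)
  expect_true(fit$coefficients$ci_lower < fit$coefficients$hr &
                fit$coefficients$hr < fit$coefficients$ci_upper)
})

test_that("Efron and Breslow agree on tie-free data", {
  set.seed(25)
  coh <- simple_ph_cohort(120, beta = 0.6, cens_rate = 0.01)
  fe <- cox_fit(data.frame(x = coh$x), coh$time, coh$event, ties = "efron")
  fb <- cox_fit(data.frame(x = coh$x), coh$time, coh$event, ties = "breslow")
  expect_equal(fe$coefficients$coef, fb$coefficients$coef, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("complete separation and degenerate inputs raise errors", {
  # covariate perfectly ordered with event times diverges
  time <- 1:20
  event <- rep(1, 20)
  x <- 20:1
  expect_error(cox_fit(data.frame(x = x), time, event),
               class = "methmark_degenerate_error")
  expect_error(cox_fit(data.frame(x = rnorm(5)), rep(10, 5), rep(0, 5)),
               class = "methmark_degenerate_error")
})

test_that("Harrell's C follows the classical pair convention exactly", {
  # risk = -time with no censoring orders every comparable pair correctly
  time <- c(3, 1, 4, 2, 6, 5)
  expect_equal(harrells_c(-time, time, rep(1, 6)), 1)
  # hand-built 6-point instance with one censored record
  time <- c(2, 4, 5, 7, 9, 9)
  event <- c(1, 1, 0, 1, 1, 0)
  risk <- c(3.0, 2.5, 2.5, 1.0, 0.5, 2.0)
  expect_equal(harrells_c(risk, time, event),
               oracle_c_index(risk, time, event))
  # random scores drift to 1/2
  set.seed(26)
  n <- 2000
  time <- rexp(n); risk <- rnorm(n)
  C <- harrells_c(risk, time, rep(1, n))
  expect_lt(abs(C - 0.5), 3 * 0.5 / sqrt(n))  # conservative null SE bound
  # no comparable pairs
  expect_error(harrells_c(c(1, 2), c(5, 5), c(1, 1)),
               class = "methmark_degenerate_error")
})

test_that("Harrell's C equals the O(n^2) enumeration on random instances", {
  set.seed(27)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    time <- sample(1:50, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    risk <- round(rnorm(n), 1)
    if (sum(outer(time, time, "<") & event == 1) == 0) next
    expect_equal(harrells_c(risk, time, event),
                 oracle_c_index(risk, time, event))
  }
  # cross-check against the survival package on tie-free data
  set.seed(28)
  time <- rexp(100); event <- rbinom(100, 1, 0.7); risk <- rnorm(100)
  ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(harrells_c(risk, time, event), unname(ref), tolerance = 1e-12)
})

test_that("backward selection drops noise first and conserves its trace", {
  set.seed(29)
  removed_first <- replicate(50, {
    n <- 300
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5); noise <- rnorm(n)
    time <- rexp(n, 0.05 * exp(1.0 * x1 - 1.0 * x2))
    cens <- runif(n, 0, quantile(time, 0.9))
    event <- as.integer(time <= cens)
    bs <- backward_select(data.frame(x1 = x1, x2 = x2, noise = noise),
                          pmin(time, cens), event)
    nrow(bs$trace) == 0 ||
      identical(bs$trace$removed[1], "noise")
  })
  expect_gte(mean(removed_first), 0.9)
  # strong coefficients at n = 1000: nothing removed
  n <- 1000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(1.2 * x1 - 1.2 * x2))
  event <- rep(1L, n)
  bs <- backward_select(data.frame(x1 = x1, x2 = x2), time, event)
  expect_equal(nrow(bs$trace), 0)
  expect_setequal(bs$retained, c("x1", "x2"))
  # trace length equals initial minus final covariates, always
  set.seed(30)
  x <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  time <- rexp(200); event <- rbinom(200, 1, 0.8)
  bs <- backward_select(x, time, event, marker_vars = "a")
  expect_equal(nrow(bs$trace), ncol(x) - length(bs$retained))
})

test_that("p-value adjustment matches brute-force step-up computations", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(adjust_pvalues(p), oracle_bh(p))
    expect_equal(adjust_pvalues(p, "hochberg"), oracle_hochberg(p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p)[perm], adjust_pvalues(p[perm]))
    # adjusted >= raw, capped at 1
    expect_true(all(adjust_pvalues(p) >= p - 1e-12))
    expect_true(all(adjust_pvalues(p) <= 1))
  }
  expect_error(adjust_pvalues(c(0.5, 0)), class = "methmark_config_error")
  expect_error(adjust_pvalues(1.2), class = "methmark_config_error")
})

test_that("subgroup analysis applies a full-cohort rule within strata", {
  set.seed(32)
  n <- 120
  # planted: within stratum A, high-marker patients all recur early
  marker <- runif(n)
  stratum <- rep(c("A", "B", "unknown"), times = c(60, 55, 5))
  time <- ifelse(stratum == "A" & marker > 0.5, rexp(n, 0.2),
                 rexp(n, 0.01))
  event <- as.integer(time <= 100); time <- pmin(time, 100)
  tab <- data.frame(patient_id = seq_len(n), marker = marker,
                    damico = stratum, time_months = time, event = event)
  rule <- derive_cutoff(tab$marker,
                        bcr_status_at_horizon(tab$time_months, tab$event, 36),
                        marker = "marker")
  sg <- subgroup_analysis(tab, "damico", rule)
  # unknown stratum is skipped; the strata partition the rest
  expect_setequal(names(sg), c("A", "B"))
  expect_equal(sum(vapply(sg, `[[`, numeric(1), "n")), 115)
  expect_true(sg$A$testable)
  expect_lt(sg$A$logrank_p, 0.01)
  # one-class stratum is untestable, not fatal
  tab2 <- tab
  tab2$marker[tab2$damico == "B"] <- 0  # all below any positive cutoff
  sg2 <- subgroup_analysis(tab2, "damico", rule)
  expect_false(sg2$B$testable)
})
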