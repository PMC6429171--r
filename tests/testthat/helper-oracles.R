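# Independent brute-force oracles. Each recomputes a quantity by the most
# direct route available (per-element loops, exhaustive enumeration,
# closed forms) and is deliberately kept separate from the package's
# vectorized implementations.

# --- discovery cascade ------------------------------------------------

# fraction of non-missing values strictly above a cutoff, by explicit loop
oracle_frac_above <- function(v, cutoff) {
  num <- 0L; den <- 0L
  for (x in v) {
    if (is.na(x)) next
    den <- den + 1L
    if (x > cutoff) num <- num + 1L
  }
  num / den
}

# direct per-CpG application of the selection predicates to one matrix row
oracle_cascade_row <- function(row, groups, t = filter_thresholds()) {
  blood <- row[groups == "peripheral_blood"]
  pca <- row[groups == "prostate_cancer"]
  np <- row[groups == "normal_prostate"]
  oc <- row[groups == "other_cancer"]
  blood_pass <- oracle_frac_above(blood, t$beta_detect) <= t$blood_max_frac
  s1 <- blood_pass &&
    oracle_frac_above(pca, t$beta_hyper) > t$s1_pca_min_frac &&
    oracle_frac_above(np, t$beta_detect) <= t$s1_normal_max_frac
  s2 <- blood_pass &&
    oracle_frac_above(pca, t$beta_hyper) > t$s2_pca_min_frac &&
    oracle_frac_above(oc, t$beta_detect) <= t$s2_othercancer_max_frac &&
    oracle_frac_above(np, t$beta_detect) <= t$s2_normal_max_frac
  c(blood = blood_pass, s1 = s1, s2 = s2)
}

oracle_cascade <- function(beta, annotation, t = filter_thresholds()) {
  groups <- annotation$group[match(colnames(beta), annotation$sample_id)]
  verdicts <- t(apply(beta, 1L, oracle_cascade_row, groups = groups, t = t))
  list(blood = rownames(beta)[verdicts[, "blood"]],
       s1 = rownames(beta)[verdicts[, "s1"]],
       s2 = rownames(beta)[verdicts[, "s2"]])
}

# --- rank statistics --------------------------------------------------

# U statistic of x over y by explicit pair counting
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  u
}

# exact two-sided Mann-Whitney p by enumerating all label arrangements,
# counting pairs directly (never through ranks)
oracle_mw_exact_p <- function(x, y) {
  combined <- c(x, y)
  n <- length(combined); nx <- length(x)
  mu <- nx * length(y) / 2
  obs <- abs(oracle_u(x, y) - mu)
  sets <- combn(n, nx)
  hits <- 0L
  for (j in seq_len(ncol(sets))) {
    xx <- combined[sets[, j]]; yy <- combined[-sets[, j]]
    if (abs(oracle_u(xx, yy) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# --- survival ---------------------------------------------------------

# Kaplan-Meier by explicit product over risk sets at each distinct event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

oracle_km_median <- function(time, event) {
  km <- oracle_km(time, event)
  hit <- km$time[km$surv <= 0.5 + 1e-12]
  if (length(hit)) min(hit) else NA_real_
}

# Harrell's C by double loop over ordered pairs
oracle_c_index <- function(risk, time, event) {
  conc <- 0; tied <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / comp
}

# --- multiplicity -----------------------------------------------------

# BH step-up from the definition: adj p_(i) = min over j >= i of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p); ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m); out[ord] <- adj
  out
}

# Hochberg step-up: adj p_(i) = min over j >= i of (m - j + 1) * p_(j)
oracle_hochberg <- function(p) {
  m <- length(p); ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m - (i:m) + 1) * ps[i:m]))
  }
  out <- numeric(m); out[ord] <- adj
  out
}

# --- shared fixture builders -----------------------------------------

# small annotation + matrix built from per-group value lists; each element
# of `rows` is a named list group -> numeric vector of betas
make_grouped_matrix <- function(rows, group_sizes) {
  ann <- data.frame(
    sample_id = unlist(lapply(names(group_sizes), function(g) {
      sprintf("%s_%03d", g, seq_len(group_sizes[[g]]))
    })),
    group = rep(names(group_sizes), unlist(group_sizes)),
    subtype = "", stringsAsFactors = FALSE)
  beta <- t(vapply(rows, function(r) {
    unlist(lapply(names(group_sizes), function(g) {
      v <- r[[g]]
      stopifnot(length(v) == group_sizes[[g]])
      v
    }))
  }, numeric(sum(unlist(group_sizes)))))
  rownames(beta) <- sprintf("cg%08d", seq_along(rows))
  colnames(beta) <- ann$sample_id
  list(beta = beta, annotation = ann)
}

# exponential proportional-hazards cohort for a single binary covariate,
# generated independently of the package's cohort module
simple_ph_cohort <- function(n, beta, prevalence = 0.5, base = 0.05,
                             cens_rate = 0) {
  x <- as.numeric(runif(n) < prevalence)
  t_event <- rexp(n, base * exp(beta * x))
  if (cens_rate > 0) {
    c_time <- rexp(n, cens_rate)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  } else {
    time <- t_event; event <- rep(1L, n)
  }
  list(x = x, time = time, event = event)
}
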