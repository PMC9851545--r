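# shared fixtures: tiny hand-checkable survival sets, cohort builders and
# structural invariant checks used across test files

# a 6-subject two-group toy with no tied event times
toy6 <- function() {
  data.frame(time = c(1, 3, 5, 2, 8, 9),
             status = c(1, 1, 0, 1, 1, 1),
             group = c(0, 0, 0, 1, 1, 1))
}

# cohort with one persistent adverse binary covariate (planted log-HR) and
# otherwise default study conditions
planted_cohort <- function(seed, n = 400, log_hr = log(3), transition = 0.05,
                           dropout = 0.1, max_visits = 6, init = 0.4) {
  simulate_cohort(sim_config(
    n_patients = n, visit_period = 90, max_visits = max_visits,
    covariates = list(cov_spec("adverse", "binary", effect = log_hr,
                               init = init, transition = transition)),
    treatments = c(treated = 0.4),
    dropout_prob = dropout, seed = seed))
}

# sliced table + dtsd + tree for one planted cohort
planted_tree <- function(seed, n = 400, time_slices = 3, p_value = 0.05,
                         minsample = 15, ...) {
  coh <- planted_cohort(seed, n = n, ...)
  sliced <- divide_time(coh, "id", "date", slice_config(90))
  dtsd <- build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                     "adverse", ifclassify = FALSE)
  tree <- build_survival_path(dtsd, path_config(
    time_slices = time_slices, p_value = p_value, minsample = minsample))
  list(cohort = coh, sliced = sliced, dtsd = dtsd, tree = tree)
}

# structural invariants that must hold for every built tree
check_tree_invariants <- function(tree) {
  dtsd <- tree$dtsd
  for (nd in tree$nodes) {
    expect_gte(nd$size, 1L)
    expect_identical(nd$size, length(nd$member_ids))
    if (length(nd$children)) {
      kids <- lapply(nd$children, function(c) tree$nodes[[c]]$member_ids)
      all_kids <- unlist(kids)
      expect_false(anyDuplicated(all_kids) > 0)  # disjoint
      present_next <- nd$member_ids[nd$member_ids %in% dtsd$tsid[[nd$slice + 1L]]]
      expect_setequal(all_kids, present_next)    # conservation
      if (length(nd$children) == 1L)             # carry-forward: condition kept
        expect_identical(tree$nodes[[nd$children]]$condition, nd$condition)
      if (length(nd$children) == 2L)
        expect_gte(nd$size, tree$config$params$minsample)
    }
  }
  # level-order contiguous ids
  ids <- vapply(tree$nodes, `[[`, integer(1L), "node_id")
  expect_identical(ids, seq_along(tree$nodes))
  slices <- vapply(tree$nodes, `[[`, integer(1L), "slice")
  expect_true(all(diff(slices) >= 0))
  # trajectory uniqueness: one node per (patient, slice)
  expect_false(anyDuplicated(tree$trajectory[c("patient_id", "slice")]) > 0)
  invisible(TRUE)
}

# independent log-rank oracle: direct O-E / hypergeometric-variance sums
logrank_oracle <- function(time, status, group) {
  ev <- sort(unique(time[status == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# independent Cox partial log-likelihood (no ties assumed)
cox_pll <- function(beta, x, time, status) {
  sum(vapply(which(status == 1), function(i) {
    risk <- time >= time[i]
    beta * x[i] - log(sum(exp(beta * x[risk])))
  }, numeric(1L)))
}

# brute-force Harrell's C over all pairs (assumes no tied survival times)
concordance_oracle <- function(time, status, risk) {
  stopifnot(!anyDuplicated(time))
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shorter <- if (time[i] < time[j]) i else j
    longer <- if (time[i] < time[j]) j else i
    if (status[shorter] != 1) next  # unusable under right censoring
    den <- den + 1
    if (risk[shorter] > risk[longer]) num <- num + 1
    else if (risk[shorter] == risk[longer]) num <- num + 0.5
  }
  num / den
}
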