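# one simulated node's worth of data with named binary effects (log-HRs)
sim_node <- function(n, effects, seed, censor = c(100, 2000)) {
  set.seed(seed)
  x <- as.data.frame(lapply(effects, function(e) rbinom(n, 1, 0.5)))
  lp <- as.numeric(as.matrix(x) %*% unlist(effects))
  t <- rexp(n, (log(2) / 365) * exp(lp))
  cens <- runif(n, censor[1], censor[2])
  list(x = x, time = pmin(t, cens), status = as.integer(t <= cens))
}

test_that("pearson_r evaluates the correlation formula on fixed points", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("univariate screen admits real effects and drops untestable columns", {
  nd <- sim_node(400, list(hit = log(3), noise = 0), seed = 7)
  nd$x$flat <- 1                       # constant: excluded, not tested
  keep <- univariate_screen(nd$x, nd$time, nd$status, 0.05)
  expect_true("hit" %in% keep)
  expect_false("flat" %in% keep)
})

test_that("collinearity pruning keeps the smaller-AIC member of each pair", {
  nd <- sim_node(1000, list(x1 = log(2.5)), seed = 19)
  # x2: x1 with 5% of labels flipped -> strongly collinear, weaker signal
  set.seed(20)
  flip <- rbinom(1000, 1, 0.05)
  nd$x$x2 <- ifelse(flip == 1, 1 - nd$x$x1, nd$x$x1)
  expect_gt(abs(pearson_r(nd$x$x1, nd$x$x2)), 0.7)
  pr <- collinearity_prune(c("x1", "x2"), nd$x, nd$time, nd$status, 0.7)
  expect_identical(pr$kept, "x1")
  expect_identical(pr$removed$dropped, "x2")
  expect_lte(pr$removed$aic_kept, pr$removed$aic_dropped)
  expect_gt(abs(pr$removed$r), 0.7)

  # duplicated column: exactly one survives, tie keeps the earlier variable
  nd$x$x3 <- nd$x$x1
  pr2 <- collinearity_prune(c("x1", "x3"), nd$x, nd$time, nd$status, 0.7)
  expect_identical(pr2$kept, "x1")

  # uncorrelated variables pass through untouched
  nd2 <- sim_node(300, list(a = 0.5, b = 0.5), seed = 21)
  pr3 <- collinearity_prune(c("a", "b"), nd2$x, nd2$time, nd2$status, 0.7)
  expect_identical(pr3$kept, c("a", "b"))
  expect_identical(nrow(pr3$removed), 0L)
})

test_that("backward elimination keeps a lone significant variable unchanged", {
  nd <- sim_node(400, list(hit = log(3)), seed = 31)
  fit <- backward_eliminate("hit", nd$x, nd$time, nd$status, 0.05)
  expect_identical(fit$variables, "hit")
  expect_lt(fit$p_values[["hit"]], 0.05)
})

test_that("elimination can legally empty the model under pure noise", {
  empties <- 0L
  for (seed in 1:20) {
    nd <- sim_node(150, list(n1 = 0, n2 = 0, n3 = 0), seed = 100 + seed)
    fit <- suppressWarnings(
      backward_eliminate(names(nd$x), nd$x, nd$time, nd$status, 0.05))
    if (!length(fit$variables)) empties <- empties + 1L
    for (v in fit$variables) expect_lt(fit$p_values[[v]], 0.05)
  }
  expect_gte(empties, 10L)   # roughly (1 - p_value)^3 of runs
})

test_that("select_split handles all degenerate paths with reason codes", {
  nd <- sim_node(10, list(x = log(3)), seed = 41)
  res <- select_split(nd$x, nd$time, nd$status, selection_params(minsample = 15))
  expect_true(is.na(res$split_variable))
  expect_identical(res$reason, "minsample")

  nd2 <- sim_node(200, list(noise = 0), seed = 42)
  res2 <- select_split(nd2$x, nd2$time, nd2$status,
                       selection_params(p_value = 0.001))
  expect_true(res2$reason %in% c("screen", "elimination"))
  expect_true(is.na(res2$split_variable))

  # a single surviving variable is the split variable (argmax over singleton)
  nd3 <- sim_node(400, list(hit = log(3)), seed = 43)
  res3 <- select_split(nd3$x, nd3$time, nd3$status, selection_params())
  expect_identical(res3$split_variable, "hit")
  expect_named(res3$importances, res3$final_model$variables)
})

test_that("the cascade is invariant to covariate column order", {
  nd <- sim_node(600, list(a = log(2.5), b = log(1.6), c = 0), seed = 53)
  r1 <- select_split(nd$x, nd$time, nd$status, selection_params())
  r2 <- select_split(nd$x[rev(names(nd$x))], nd$time, nd$status,
                     selection_params())
  expect_identical(r1$split_variable, r2$split_variable)
  expect_setequal(r1$final_model$variables, r2$final_model$variables)
  expect_equal(sort(r1$importances), sort(r2$importances), tolerance = 1e-8)
})

test_that("the stronger of two planted effects wins the importance contest", {
  wins <- 0L
  for (seed in 1:20) {
    nd <- sim_node(1200, list(strong = 1.0, weak = 0.3), seed = 200 + seed)
    res <- select_split(nd$x, nd$time, nd$status, selection_params())
    if (identical(res$split_variable, "strong")) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("importances reproduce from full and reduced fits", {
  nd <- sim_node(500, list(a = 0.8, b = 0.5), seed = 61)
  res <- select_split(nd$x, nd$time, nd$status, selection_params())
  for (v in res$final_model$variables) {
    red <- cox_fit(nd$x[setdiff(res$final_model$variables, v)],
                   nd$time, nd$status)
    expect_equal(res$importances[[v]], lr_importance(res$final_model, red),
                 tolerance = 1e-8)
    expect_gte(res$importances[[v]], 0)
  }
})
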