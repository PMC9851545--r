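#' Feature-selection parameters
#'
#' @param p_value significance threshold used both by the univariate screen
#'   and by backward elimination (default 0.05).
#' @param minsample minimum node size at which a split is attempted
#'   (default 15).
#' @param degree_of_correlation absolute Pearson correlation above which a
#'   pair of covariates is treated as collinear (default 0.7).
#' @return an object of class \code{selection_params}.
#' @export
selection_params <- function(p_value = 0.05, minsample = 15,
                             degree_of_correlation = 0.7) {
  stopifnot(p_value > 0, p_value < 1)
  stopifnot(minsample >= 2)
  stopifnot(degree_of_correlation > 0, degree_of_correlation <= 1)
  structure(list(p_value = p_value, minsample = minsample,
                 degree_of_correlation = degree_of_correlation),
            class = "selection_params")
}

#' Univariate Kaplan-Meier screen
#'
#' Tests each binary covariate with a two-sample log-rank test and returns
#' those with p below \code{p_value}. Constant covariates, and covariates
#' whose grouping leaves a group empty, are excluded rather than tested.
#'
#' @param covariates data frame of binary covariates.
#' @param times,statuses survival outcome vectors.
#' @param p_value significance threshold.
#' @return character vector of screened-in variable names (possibly empty).
#' @export
univariate_screen <- function(covariates, times, statuses, p_value = 0.05) {
  stopifnot(is.data.frame(covariates))
  keep <- character(0)
  for (v in names(covariates)) {
    g <- covariates[[v]]
    if (anyNA(g)) next
    if (length(unique(g)) != 2L) next
    p <- tryCatch(logrank_test(times, statuses, g)$p, error = function(e) NA_real_)
    if (!is.na(p) && p < p_value) keep <- c(keep, v)
  }
  keep
}

#' Sample Pearson correlation coefficient
#'
#' r = sum((xa - mean(xa)) (xb - mean(xb))) /
#'     sqrt(sum((xa - mean(xa))^2) sum((xb - mean(xb))^2)).
#'
#' @param xa,xb equal-length numeric vectors, both non-constant.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(xa, xb) {
  stopifnot(length(xa) == length(xb), length(xa) >= 2)
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop("constant input: correlation undefined")
  stats::cor(xa, xb)
}

#' Resolve collinear covariate pairs by single-predictor AIC
#'
#' All pairs among \code{variables} with |r| above
#' \code{degree_of_correlation} are processed in decreasing |r| (pairs with
#' an already-removed member are skipped). For each pair, two
#' single-covariate Cox models are fitted; the variable with the smaller AIC
#' survives and the other is removed. Equal AICs keep the variable that
#' comes first in the input order.
#'
#' @param variables character vector of candidate covariate names.
#' @param covariates data frame holding those covariates.
#' @param times,statuses survival outcome vectors.
#' @param degree_of_correlation |r| threshold.
#' @return list with \code{kept} (character vector, input order preserved)
#'   and \code{removed} (data frame: kept, dropped, r, aic_kept,
#'   aic_dropped).
#' @export
collinearity_prune <- function(variables, covariates, times, statuses,
                               degree_of_correlation = 0.7) {
  removed_log <- data.frame(kept = character(0), dropped = character(0),
                            r = numeric(0), aic_kept = numeric(0),
                            aic_dropped = numeric(0), stringsAsFactors = FALSE)
  if (length(variables) < 2L)
    return(list(kept = variables, removed = removed_log))

  pairs <- utils::combn(variables, 2L)
  rvals <- apply(pairs, 2L, function(pr) {
    tryCatch(pearson_r(covariates[[pr[1L]]], covariates[[pr[2L]]]),
             error = function(e) 0)  # constant pair: treated as non-collinear
  })
  flag <- abs(rvals) > degree_of_correlation
  ord <- order(-abs(rvals))
  ord <- ord[flag[ord]]

  uni_aic <- function(v)
    cox_fit(covariates[v], times, statuses)$aic

  removed <- character(0)
  for (j in ord) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (a %in% removed || b %in% removed) next
    aic_a <- uni_aic(a); aic_b <- uni_aic(b)
    # keep the smaller AIC; tie -> keep the earlier variable in input order
    if (aic_b < aic_a) { keep <- b; drop <- a }
    else { keep <- a; drop <- b }
    removed <- c(removed, drop)
    removed_log <- rbind(removed_log, data.frame(
      kept = keep, dropped = drop, r = rvals[j],
      aic_kept = min(aic_a, aic_b), aic_dropped = max(aic_a, aic_b),
      stringsAsFactors = FALSE))
  }
  list(kept = setdiff(variables, removed), removed = removed_log)
}

#' Backward elimination on the Cox partial likelihood
#'
#' Iteratively refits the multivariable Cox model; at each round the
#' variable with the largest likelihood-ratio p-value is removed if that
#' p-value is >= \code{p_value}, until every remaining variable is
#' significant or none remain. A covariate whose inclusion makes the fit
#' non-convergent (monotone likelihood) is dropped with a warning.
#'
#' @param variables character vector of candidate covariates.
#' @param covariates data frame holding them.
#' @param times,statuses survival outcome vectors.
#' @param p_value retention threshold.
#' @return the final \code{\link{cox_fit}} (possibly the null model).
#' @export
backward_eliminate <- function(variables, covariates, times, statuses,
                               p_value = 0.05) {
  current <- variables
  repeat {
    fit <- cox_fit(covariates[current], times, statuses)
    if (!fit$converged && length(current)) {
      # drop the worst offender (largest |coef|, the monotone-likelihood mark)
      bad <- current[which.max(abs(fit$coef))]
      warning("dropping non-convergent covariate '", bad, "'")
      current <- setdiff(current, bad)
      next
    }
    if (!length(current)) return(fit)
    worst <- which.max(fit$p_values)
    if (fit$p_values[worst] >= p_value) {
      current <- setdiff(current, fit$variables[worst])
    } else return(fit)
  }
}

#' Select the split variable for one node
#'
#' Runs the full per-node cascade: univariate log-rank screen, collinearity
#' pruning by AIC, backward elimination on the Cox partial likelihood, then
#' picks as split variable the final-model covariate whose removal changes
#' -2 logL the most (\code{\link{lr_importance}}). All degenerate paths
#' (node smaller than \code{minsample}, empty screen, elimination emptying
#' the model) return \code{split_variable = NA} with a reason code instead
#' of failing.
#'
#' @param covariates data frame of binary covariates at the node's slice.
#' @param times,statuses survival outcome vectors for the node members.
#' @param params a \code{\link{selection_params}}.
#' @return an object of class \code{selection_result}: list with
#'   \code{screened}, \code{removed_collinear}, \code{final_model},
#'   \code{importances}, \code{split_variable} (NA when no split) and
#'   \code{reason} (one of "ok", "minsample", "screen", "elimination").
#' @export
select_split <- function(covariates, times, statuses,
                         params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  res <- function(screened = character(0), removed = NULL, model = NULL,
                  importances = numeric(0), split = NA_character_, reason) {
    structure(list(screened = screened, removed_collinear = removed,
                   final_model = model, importances = importances,
                   split_variable = split, reason = reason),
              class = "selection_result")
  }
  if (length(times) < params$minsample) return(res(reason = "minsample"))

  screened <- univariate_screen(covariates, times, statuses, params$p_value)
  if (!length(screened)) return(res(reason = "screen"))

  pruned <- collinearity_prune(screened, covariates, times, statuses,
                               params$degree_of_correlation)
  fit <- suppressWarnings(
    backward_eliminate(pruned$kept, covariates, times, statuses,
                       params$p_value))
  if (!length(fit$variables))
    return(res(screened, pruned$removed, fit, reason = "elimination"))

  imp <- vapply(fit$variables, function(v) {
    red <- cox_fit(covariates[setdiff(fit$variables, v)], times, statuses)
    lr_importance(fit, red)
  }, numeric(1L))
  split <- fit$variables[which.max(imp)]
  res(screened, pruned$removed, fit, imp, split, "ok")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("node split selection:", x$reason, "\n")
  if (!is.na(x$split_variable))
    cat("  split variable:", x$split_variable, "\n")
  if (length(x$importances))
    cat("  importances:", paste(sprintf("%s=%.3f", names(x$importances),
                                        x$importances), collapse = ", "), "\n")
  invisible(x)
}
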