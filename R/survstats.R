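#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around \code{survival::survfit} returning the event-time
#' grid, survival probabilities, numbers at risk and the median residual
#' survival (smallest t with S(t) <= 0.5, or \code{NA} when the curve never
#' drops to 0.5). Ties between events and censorings at the same time are
#' handled events-first, the product-limit convention.
#'
#' @param times survival times (days), non-negative.
#' @param statuses event indicators (0/1).
#' @return an object of class \code{km_curve}: list with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{median} and \code{n}.
#' @export
km_curve <- function(times, statuses) {
  stopifnot(length(times) == length(statuses), length(times) >= 1)
  stopifnot(all(statuses %in% c(0, 1)))
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, statuses) ~ 1)
  s <- fit$surv
  med <- if (any(s <= 0.5)) fit$time[which(s <= 0.5)[1L]] else NA_real_
  structure(list(time = fit$time, surv = s, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation: S(t) is the estimate at the
#' largest event/censoring time <= t (1 before the first time, last value
#' beyond the final time).
#'
#' @param km a \code{\link{km_curve}}.
#' @param t evaluation time (scalar or vector).
#' @return survival probability/ies at \code{t}.
#' @export
km_surv_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1L)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, " events =", sum(x$n_event), "\n")
  cat("  median:", if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' Two-or-more-sample log-rank test
#'
#' Standard log-rank chi-square via \code{survival::survdiff} with k - 1
#' degrees of freedom for k groups.
#'
#' @param times survival times.
#' @param statuses event indicators (0/1).
#' @param group group membership (any vector coercible to factor).
#' @return list with \code{chi2}, \code{df} and \code{p}.
#' @export
logrank_test <- function(times, statuses, group) {
  stopifnot(length(times) == length(statuses), length(times) == length(group))
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs at least two non-empty groups")
  if (sum(statuses) == 0) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, statuses) ~ g)
  df <- length(sd$n) - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie approximation
#' (convergence tolerance 1e-9 on the coefficients, at most 100 iterations).
#' Per-variable p-values are likelihood-ratio chi-square (1 df) tests,
#' obtained by refitting the model without each variable in turn. An empty
#' variable set is legal and returns the null model (logL of the empty
#' model, AIC = -2 logL).
#'
#' @param covariates data frame of covariates (no constant columns).
#' @param times survival times.
#' @param statuses event indicators (0/1).
#' @return an object of class \code{cox_fit}: list with \code{variables},
#'   \code{coef}, \code{loglik} (fitted model), \code{loglik_null},
#'   \code{aic}, \code{p_values} (per-variable LR tests), \code{converged}
#'   and \code{n}.
#' @export
cox_fit <- function(covariates, times, statuses) {
  stopifnot(is.data.frame(covariates))
  n <- length(times)
  stopifnot(length(statuses) == n, nrow(covariates) == n || ncol(covariates) == 0)
  vars <- names(covariates)

  null_ll <- null_cox_loglik(times, statuses)
  if (!length(vars)) {
    return(structure(list(variables = character(0), coef = numeric(0),
                          loglik = null_ll, loglik_null = null_ll,
                          aic = -2 * null_ll, p_values = numeric(0),
                          converged = TRUE, n = n),
                     class = "cox_fit"))
  }
  const <- vars[vapply(covariates, function(v) length(unique(v)) < 2L, logical(1L))]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "))
  if (n < length(vars)) stop("fewer observations than covariates")

  core <- fit_cox_raw(covariates, times, statuses)
  pvals <- vapply(vars, function(v) {
    red <- if (length(vars) > 1L)
      fit_cox_raw(covariates[setdiff(vars, v)], times, statuses)$loglik
    else null_ll
    stats::pchisq(2 * (core$loglik - red), df = 1, lower.tail = FALSE)
  }, numeric(1L))

  structure(list(variables = vars, coef = core$coef, loglik = core$loglik,
                 loglik_null = null_ll,
                 aic = -2 * core$loglik + 2 * length(vars),
                 p_values = pvals, converged = core$converged, n = n),
            class = "cox_fit")
}

# single coxph call; flags non-convergence and monotone-likelihood
# (infinite coefficient) warnings
fit_cox_raw <- function(covariates, times, statuses) {
  dat <- cbind(data.frame(.time = times, .status = statuses), covariates)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .status) ~ ., data = dat,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|did not converge|out of iterations|beta may be",
                msg, ignore.case = TRUE))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(coef = stats::setNames(unname(stats::coef(fit)), names(covariates)),
       loglik = fit$loglik[2L],
       converged = !flagged)
}

null_cox_loglik <- function(times, statuses) {
  dat <- data.frame(.time = times, .status = statuses)
  fit <- survival::coxph(survival::Surv(.time, .status) ~ 1, data = dat,
                         ties = "efron")
  fit$loglik[1L]
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit: n =", x$n, " k =", length(x$variables), "\n")
  if (length(x$variables)) {
    print(data.frame(coef = x$coef, lr_p = x$p_values, row.names = x$variables))
  } else cat("  (null model)\n")
  cat("  logL =", format(x$loglik, digits = 7), " AIC =",
      format(x$aic, digits = 7), "\n")
  invisible(x)
}

#' Likelihood-ratio variable importance
#'
#' The importance of the variable removed between \code{full} and
#' \code{reduced}: -2 (logL_reduced - logL_full), i.e. -2 log of the
#' likelihood ratio of the reduced to the full model, always >= 0 up to
#' numerical noise. \code{reduced} must be \code{full} minus exactly one
#' variable (or the identical variable set, giving 0), fitted on the same
#' data.
#'
#' @param full,reduced \code{\link{cox_fit}} objects.
#' @return the importance (non-negative scalar).
#' @export
lr_importance <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (full$n != reduced$n)
    stop("models were not fitted on the same data (different n)")
  dropped <- setdiff(full$variables, reduced$variables)
  extra <- setdiff(reduced$variables, full$variables)
  if (length(extra) || length(dropped) > 1L)
    stop("reduced model must be the full model minus at most one variable")
  if (!length(dropped)) return(0)
  max(0, -2 * (reduced$loglik - full$loglik))
}

#' Harrell's concordance index
#'
#' Proportion of usable pairs (comparable under right censoring) whose risk
#' ordering agrees with their survival ordering; risk ties count 0.5. Higher
#' risk scores are expected to go with shorter survival.
#'
#' @param times survival times.
#' @param statuses event indicators (0/1).
#' @param risk_scores numeric risk scores.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(times, statuses, risk_scores) {
  n <- length(times)
  stopifnot(length(statuses) == n, length(risk_scores) == n)
  cc <- survival::concordance(survival::Surv(times, statuses) ~ risk_scores,
                              reverse = TRUE)
  usable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable pairs for concordance")
  unname(cc$concordance)
}
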