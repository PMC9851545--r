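#' Dichotomization configuration
#'
#' @param predict_time horizon in days at which the time-dependent ROC is
#'   evaluated (default 365, i.e. 1-year survival).
#' @return an object of class \code{dichotomize_config}.
#' @export
dichotomize_config <- function(predict_time = 365) {
  stopifnot(is.numeric(predict_time), length(predict_time) == 1L, predict_time > 0)
  structure(list(predict_time = predict_time), class = "dichotomize_config")
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC at \code{predict_time}, estimated in
#' the Kaplan-Meier form of Heagerty, Lumley and Pepe (2000): for each
#' threshold \code{c}, sensitivity and specificity are derived from the
#' marginal KM estimate of S(t) and the conditional KM estimate of S(t) among
#' subjects with marker above the threshold, via Bayes' theorem. Cases are
#' subjects with an event by \code{predict_time}; controls are subjects still
#' event-free at \code{predict_time}. The classification rule is
#' \code{marker > threshold}.
#'
#' @param times residual survival times (days).
#' @param statuses event indicators (0/1).
#' @param marker continuous marker values.
#' @param predict_time evaluation horizon in days.
#' @return an object of class \code{td_roc}: list with \code{thresholds}
#'   (sorted unique marker values), \code{tpr}, \code{fpr}, \code{auc} and
#'   \code{degenerate} (TRUE when the marker is constant).
#' @export
td_roc <- function(times, statuses, marker, predict_time) {
  n <- length(times)
  stopifnot(length(statuses) == n, length(marker) == n, n >= 2)
  stopifnot(all(statuses %in% c(0, 1)))
  ok <- stats::complete.cases(times, statuses, marker)
  times <- times[ok]; statuses <- statuses[ok]; marker <- marker[ok]
  n <- length(times)
  if (!any(statuses == 1 & times <= predict_time))
    stop("no cases at horizon: no event occurs at or before predict_time")

  s_marg <- km_surv_at(km_curve(times, statuses), predict_time)
  if (s_marg <= 0) stop("no controls at horizon: estimated S(predict_time) is 0")
  if (s_marg >= 1) stop("no cases at horizon: estimated S(predict_time) is 1")
  thresholds <- sort(unique(marker))
  degenerate <- length(thresholds) < 2L

  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    sel <- marker > thresholds[i]
    px <- mean(sel)
    if (!any(sel)) { tpr[i] <- 0; fpr[i] <- 0; next }
    s_cond <- km_surv_at(km_curve(times[sel], statuses[sel]), predict_time)
    tpr[i] <- (1 - s_cond) * px / (1 - s_marg)
    fpr[i] <- s_cond * px / s_marg
  }
  tpr <- pmin(pmax(tpr, 0), 1)
  fpr <- pmin(pmax(fpr, 0), 1)

  # sweep from threshold = +Inf (0,0) down to -Inf (1,1); trapezoidal AUC
  xs <- c(0, rev(fpr), 1)
  ys <- c(0, rev(tpr), 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)

  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc, predict_time = predict_time,
                 degenerate = degenerate),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat("time-dependent ROC at t =", x$predict_time, "\n")
  cat("  thresholds:", length(x$thresholds), " AUC:", round(x$auc, 4), "\n")
  if (x$degenerate) cat("  [degenerate: constant marker]\n")
  invisible(x)
}

#' Optimal dichotomization cutoff from a time-dependent ROC
#'
#' Returns the threshold maximizing Youden's J = sensitivity - (1 -
#' specificity). Ties are resolved in favour of the smallest threshold.
#'
#' @param roc a \code{\link{td_roc}} object.
#' @return the optimal threshold (numeric scalar).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  if (roc$degenerate)
    stop("degenerate ROC: marker is constant, no cutoff can be chosen")
  j <- roc$tpr - roc$fpr
  best <- max(j)
  roc$thresholds[which(j >= best - 1e-12)[1L]]
}

#' Dichotomize the continuous covariates of a DTSD object
#'
#' Continuous covariates (more than two distinct values across the whole
#' object) are dichotomized at the Youden-optimal cutoff of a time-dependent
#' ROC estimated on slice-1 data only; the same cutoff is then applied
#' uniformly to every slice as the indicator \code{value > cutoff} (a value
#' exactly equal to the cutoff codes to 0). Binary covariates are left
#' untouched and do not appear in \code{cutoffs}.
#'
#' @param dtsd a \code{\link{build_dtsd}} object.
#' @param config a \code{\link{dichotomize_config}}.
#' @return the \code{dtsd} object with binary covariates and cutoffs recorded
#'   in \code{dtsd$cutoffs}.
#' @export
apply_cutoffs <- function(dtsd, config = dichotomize_config()) {
  stopifnot(inherits(dtsd, "dtsd"), inherits(config, "dichotomize_config"))
  pooled_distinct <- function(v) {
    vals <- unlist(lapply(dtsd$tsdata, function(d) d[[v]]))
    unique(vals[!is.na(vals)])
  }
  continuous <- dtsd$variables[vapply(dtsd$variables,
                                      function(v) length(pooled_distinct(v)) > 2L,
                                      logical(1L))]
  if (!length(continuous)) return(dtsd)

  cutoffs <- dtsd$cutoffs
  for (v in continuous) {
    marker <- dtsd$tsdata[[1L]][[v]]
    cut <- tryCatch({
      roc <- td_roc(dtsd$time[[1L]], dtsd$status[[1L]], marker,
                    config$predict_time)
      optimal_cutoff(roc)
    }, error = function(e)
      stop("cutoff estimation failed for variable '", v, "' on slice 1: ",
           conditionMessage(e), call. = FALSE))
    for (i in seq_len(dtsd$length)) {
      vals <- dtsd$tsdata[[i]][[v]]
      dtsd$tsdata[[i]][[v]] <- ifelse(is.na(vals), NA_integer_,
                                      as.integer(vals > cut))
    }
    cutoffs[[v]] <- cut
  }
  dtsd$cutoffs <- cutoffs
  dtsd
}
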