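#' Covariate specification for the synthetic cohort generator
#'
#' @param name column name.
#' @param type "binary" or "continuous".
#' @param effect log hazard ratio per unit of the covariate (0 = no
#'   prognostic effect).
#' @param init for binary covariates the baseline prevalence; for
#'   continuous covariates a length-2 vector c(mean, sd) of the baseline
#'   normal distribution.
#' @param transition for binary covariates the per-visit probability of
#'   switching 0 -> 1 (disease progression); for continuous covariates the
#'   sd of the per-visit random-walk increment. 0 freezes the covariate.
#' @param reversal for binary covariates the per-visit probability of
#'   switching 1 -> 0 (default 0).
#' @return an object of class \code{cov_spec}.
#' @export
cov_spec <- function(name, type = c("binary", "continuous"), effect = 0,
                     init = if (match.arg(type) == "binary") 0.3 else c(5, 2),
                     transition = 0, reversal = 0) {
  type <- match.arg(type)
  stopifnot(transition >= 0, reversal >= 0, reversal <= 1)
  if (type == "binary") stopifnot(init >= 0, init <= 1, transition <= 1)
  else stopifnot(length(init) == 2L, init[2L] >= 0)
  structure(list(name = name, type = type, effect = effect, init = init,
                 transition = transition, reversal = reversal),
            class = "cov_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults describe a moderately sized oncology-like follow-up study:
#' quarterly visits over two years, a baseline exponential hazard with
#' one-year median survival, and mild per-visit dropout.
#'
#' @param n_patients cohort size (default 300).
#' @param visit_period nominal days between visits (default 90).
#' @param visit_jitter_sd sd in days of the visit-date jitter, first visit
#'   is exact (default 7).
#' @param max_visits maximum scheduled visits per patient (default 8).
#' @param covariates list of \code{\link{cov_spec}} objects.
#' @param treatments named numeric vector: per-visit probability of each
#'   (outcome-independent) binary treatment flag; may be empty.
#' @param baseline_hazard exponential event rate per day (default
#'   log(2)/365, i.e. one-year median survival).
#' @param dropout_prob per-visit probability that the patient is lost to
#'   follow-up before the next visit (default 0.1).
#' @param admin_censor_days administrative censoring horizon from each
#'   patient's baseline (default 1825).
#' @param seed mandatory RNG seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 300, visit_period = 90,
                       visit_jitter_sd = 7, max_visits = 8,
                       covariates = list(
                         cov_spec("risk_factor", "binary", effect = log(2),
                                  init = 0.35, transition = 0.1),
                         cov_spec("marker", "continuous", effect = 0.1,
                                  init = c(5, 2), transition = 0.5)),
                       treatments = c(treated = 0.4),
                       baseline_hazard = log(2) / 365, dropout_prob = 0.1,
                       admin_censor_days = 1825, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_patients >= 1, visit_period > 0, visit_jitter_sd >= 0,
            max_visits >= 1, baseline_hazard > 0,
            dropout_prob >= 0, dropout_prob <= 1, admin_censor_days > 0)
  stopifnot(all(vapply(covariates, inherits, logical(1L), "cov_spec")))
  structure(list(n_patients = n_patients, visit_period = visit_period,
                 visit_jitter_sd = visit_jitter_sd, max_visits = max_visits,
                 covariates = covariates, treatments = treatments,
                 baseline_hazard = baseline_hazard,
                 dropout_prob = dropout_prob,
                 admin_censor_days = admin_censor_days,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a longitudinal cohort with planted prognostic structure
#'
#' Per patient: visit times follow the nominal schedule with Gaussian
#' jitter (first visit exact); covariates evolve by the per-spec Markov
#' transition (binary) or random walk (continuous); the death time is drawn
#' from a piecewise-constant proportional-hazards model whose hazard is
#' refreshed at every visit, \code{baseline_hazard * exp(sum(effect *
#' covariate))}; follow-up ends at death, dropout or administrative
#' censoring. One output row per completed visit, with the residual
#' survival time (days from that visit to death/censoring) and a per-patient
#' constant event indicator. Fully reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data frame with columns \code{id}, \code{date} (ISO dates from a
#'   fixed 2015-01-01 epoch), one column per covariate and treatment,
#'   \code{surv_time} and \code{status}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  epoch <- as.Date("2015-01-01")
  specs <- config$covariates
  cov_names <- vapply(specs, `[[`, character(1L), "name")
  trt_names <- names(config$treatments)

  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    k <- config$max_visits
    tvis <- (seq_len(k) - 1) * config$visit_period
    if (k > 1L && config$visit_jitter_sd > 0)
      tvis[-1L] <- tvis[-1L] + stats::rnorm(k - 1L, 0, config$visit_jitter_sd)
    tvis <- sort(tvis)
    tvis[1L] <- 0

    # covariate paths across scheduled visits
    x <- matrix(0, nrow = k, ncol = length(specs),
                dimnames = list(NULL, cov_names))
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      if (sp$type == "binary") {
        v <- stats::rbinom(1L, 1L, sp$init)
        for (m in seq_len(k)) {
          if (m > 1L) {
            if (v == 0 && stats::runif(1) < sp$transition) v <- 1L
            else if (v == 1 && stats::runif(1) < sp$reversal) v <- 0L
          }
          x[m, j] <- v
        }
      } else {
        v <- stats::rnorm(1L, sp$init[1L], sp$init[2L])
        for (m in seq_len(k)) {
          if (m > 1L && sp$transition > 0)
            v <- v + stats::rnorm(1L, 0, sp$transition)
          x[m, j] <- v
        }
      }
    }

    # death time: piecewise-constant hazard, refreshed at each visit
    effects <- vapply(specs, `[[`, numeric(1L), "effect")
    haz <- config$baseline_hazard * exp(as.numeric(x %*% effects))
    target <- stats::rexp(1L)  # cumulative hazard at death
    bounds <- c(tvis, Inf)
    death <- Inf
    acc <- 0
    for (m in seq_len(k)) {
      width <- bounds[m + 1L] - bounds[m]
      seg <- haz[m] * width
      if (acc + seg >= target) {
        death <- bounds[m] + (target - acc) / haz[m]
        break
      }
      acc <- acc + seg
    }

    # dropout: first visit (>= 2) that does not happen
    drop_at <- Inf
    if (config$dropout_prob > 0 && k > 1L) {
      u <- stats::runif(k - 1L) < config$dropout_prob
      if (any(u)) drop_at <- tvis[which(u)[1L] + 1L]
    }
    censor <- min(config$admin_censor_days, drop_at)
    terminal <- min(death, censor)
    status <- as.integer(death <= censor)

    visible <- which(tvis < terminal)
    if (!length(visible)) visible <- 1L  # baseline visit always observed
    nv <- length(visible)

    trt <- if (length(trt_names))
      matrix(stats::rbinom(nv * length(trt_names), 1L,
                           rep(config$treatments, each = nv)),
             nrow = nv, dimnames = list(NULL, trt_names))
    else NULL

    d <- data.frame(id = sprintf("P%05d", i),
                    date = epoch + round(tvis[visible]),
                    stringsAsFactors = FALSE)
    d <- cbind(d, as.data.frame(x[visible, , drop = FALSE]))
    if (!is.null(trt)) d <- cbind(d, as.data.frame(trt))
    d$surv_time <- terminal - tvis[visible]
    d$status <- status
    rows[[i]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
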