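#' Time-slice configuration
#'
#' Parameters controlling how a patient's per-visit timeline is binned into
#' fixed-width slices. Slice \code{k} (1-based) is centred at
#' \code{(k - 1) * period} days after the patient's own zero point (earliest
#' visit), and a record at offset \code{d} is admitted to slice \code{k} when
#' \code{center - left_interval * period <= d < center + right_interval * period}.
#' With \code{left_interval + right_interval <= 1} the windows never overlap,
#' so a record can belong to at most one slice.
#'
#' @param period days per time slice (default 30).
#' @param left_interval fraction of \code{period} admitted to the left of a
#'   slice centre, in \code{[0, 1)} (default 0.5).
#' @param right_interval fraction of \code{period} admitted to the right of a
#'   slice centre, in \code{(0, 1]} (default 0.5).
#' @return an object of class \code{slice_config}.
#' @export
slice_config <- function(period = 30, left_interval = 0.5, right_interval = 0.5) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  stopifnot(is.numeric(left_interval), length(left_interval) == 1L,
            left_interval >= 0, left_interval < 1)
  stopifnot(is.numeric(right_interval), length(right_interval) == 1L,
            right_interval > 0, right_interval <= 1)
  if (left_interval + right_interval > 1)
    stop("left_interval + right_interval must be <= 1 (windows must not overlap)")
  structure(list(period = period, left_interval = left_interval,
                 right_interval = right_interval),
            class = "slice_config")
}

#' Bin per-visit records into fixed-width time slices
#'
#' Each patient's earliest visit defines that patient's zero point. Every
#' record is assigned to the slice whose admission window contains its offset
#' (see \code{\link{slice_config}}); records falling in no window are dropped.
#' When several records of one patient land in the same window, the record
#' nearest the slice centre is kept, with ties resolved in favour of the
#' earlier date.
#'
#' @param raw data frame of per-visit records, one row per patient-visit.
#' @param id_col name of the patient identifier column.
#' @param date_col name of the visit date column (\code{Date} or ISO-8601
#'   strings).
#' @param config a \code{\link{slice_config}}.
#' @return \code{raw} with an added integer column \code{time_slice}
#'   (1-based), restricted to admitted records and sorted by patient then
#'   slice.
#' @export
divide_time <- function(raw, id_col, date_col, config = slice_config()) {
  stopifnot(is.data.frame(raw), nrow(raw) > 0)
  for (col in c(id_col, date_col))
    if (!col %in% names(raw)) stop("column not found: ", col)
  dates <- raw[[date_col]]
  if (!inherits(dates, "Date")) {
    parsed <- as.Date(as.character(dates), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(dates))
    if (length(bad))
      stop("unparseable date(s) in rows: ", paste(utils::head(bad, 5L), collapse = ", "))
    dates <- parsed
  }
  if (anyNA(dates)) stop("missing date(s) in rows: ",
                         paste(utils::head(which(is.na(dates)), 5L), collapse = ", "))
  ids <- as.character(raw[[id_col]])
  dup <- duplicated(paste(ids, dates, sep = "\r"))
  if (any(dup))
    stop("duplicate (patient, date) record(s), e.g. patient ", ids[which(dup)[1L]],
         " on ", dates[which(dup)[1L]])

  p <- config$period
  zero <- stats::ave(as.numeric(dates), ids, FUN = min)
  offset <- as.numeric(dates) - zero
  # windows are disjoint, so the candidate slice is unique if it exists:
  # k - 1 must lie in (offset/p - right, offset/p + left]
  cand <- floor(offset / p + config$left_interval) + 1
  center <- (cand - 1) * p
  ok <- cand >= 1 &
    offset >= center - config$left_interval * p &
    offset <  center + config$right_interval * p
  keep <- which(ok)
  if (!length(keep)) stop("no record falls inside any slice window")

  out <- raw[keep, , drop = FALSE]
  out$time_slice <- as.integer(cand[keep])
  dist <- abs(offset[keep] - center[keep])
  # nearest-to-center within each (patient, slice); tie -> earlier date
  ord <- order(ids[keep], out$time_slice, dist, dates[keep])
  out <- out[ord, , drop = FALSE]
  first <- !duplicated(paste(ids[keep][ord], out$time_slice, sep = "\r"))
  out <- out[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a dynamic time-series data (DTSD) object
#'
#' Packs a time-sliced table into per-slice parallel lists of residual
#' survival time, event status, covariate values and patient IDs -- the
#' container consumed by \code{\link{build_survival_path}}. Optionally fills
#' missing covariate values with the within-slice average (continuous
#' covariates get the slice mean; binary covariates get the slice majority
#' value so the 0/1 coding survives) and dichotomizes continuous covariates
#' at the cutoff recommended by a time-dependent ROC curve
#' (\code{\link{apply_cutoffs}}).
#'
#' @param sliced data frame carrying the \code{time_slice} column produced by
#'   \code{\link{divide_time}}.
#' @param slice_col,id_col,time_col,status_col column names for slice index,
#'   patient ID, residual survival time (days) and event status (0/1).
#' @param variables character vector of covariate columns to model.
#' @param ifclassify dichotomize continuous covariates? (default TRUE)
#' @param predict_time horizon in days for the time-dependent ROC (default 365).
#' @param isfill fill missing covariate values with the within-slice average?
#'   (default TRUE)
#' @return an object of class \code{dtsd}: list with elements \code{length},
#'   \code{ts_size}, \code{slices} (original slice indices; indices with no
#'   rows are omitted), \code{time}, \code{status}, \code{tsdata},
#'   \code{tsid}, \code{variables} and \code{cutoffs}.
#' @export
build_dtsd <- function(sliced, slice_col = "time_slice", id_col, time_col,
                       status_col, variables, ifclassify = TRUE,
                       predict_time = 365, isfill = TRUE) {
  stopifnot(is.data.frame(sliced), nrow(sliced) > 0)
  for (col in c(slice_col, id_col, time_col, status_col, variables))
    if (!col %in% names(sliced)) stop("column not found: ", col)
  status <- sliced[[status_col]]
  if (!all(status %in% c(0, 1)))
    stop("status values outside {0, 1} in column ", status_col)
  stime <- sliced[[time_col]]
  if (any(is.na(stime)) || any(stime < 0))
    stop("survival times must be non-negative and non-missing")

  slice_idx <- as.integer(sliced[[slice_col]])
  slices <- sort(unique(slice_idx))
  ids <- as.character(sliced[[id_col]])

  # binary vs continuous decided on the pooled data, before any fill
  is_binary <- vapply(variables, function(v) {
    length(unique(sliced[[v]][!is.na(sliced[[v]])])) <= 2L
  }, logical(1L))

  time_l <- status_l <- tsdata_l <- tsid_l <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    rows <- which(slice_idx == slices[i])
    sid <- ids[rows]
    if (anyDuplicated(sid))
      stop("patient appears more than once in slice ", slices[i])
    dat <- sliced[rows, variables, drop = FALSE]
    for (v in variables) {
      vals <- dat[[v]]
      if (all(is.na(vals)))
        stop("variable '", v, "' is missing in all rows of slice ", slices[i])
      if (isfill && anyNA(vals)) {
        if (is_binary[[v]]) {
          lev <- sort(unique(vals[!is.na(vals)]))
          fill <- lev[which.max(tabulate(match(vals, lev)))]
        } else {
          fill <- mean(vals, na.rm = TRUE)
        }
        vals[is.na(vals)] <- fill
        dat[[v]] <- vals
      }
    }
    rownames(dat) <- NULL
    time_l[[i]] <- as.numeric(stime[rows])
    status_l[[i]] <- as.integer(status[rows])
    tsdata_l[[i]] <- dat
    tsid_l[[i]] <- sid
  }

  obj <- structure(list(
    length = length(slices),
    ts_size = vapply(tsid_l, length, integer(1L)),
    slices = slices,
    time = time_l,
    status = status_l,
    tsdata = tsdata_l,
    tsid = tsid_l,
    variables = variables,
    cutoffs = stats::setNames(numeric(0), character(0))
  ), class = "dtsd")

  if (ifclassify)
    obj <- apply_cutoffs(obj, dichotomize_config(predict_time))
  obj
}

#' @export
print.dtsd <- function(x, ...) {
  cat("DTSD object:", x$length, "time slice(s)\n")
  cat("  per-slice sizes:", paste(x$ts_size, collapse = ", "), "\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  if (length(x$cutoffs))
    cat("  cutoffs:", paste(sprintf("%s=%.4g", names(x$cutoffs), x$cutoffs),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Re-zero a cohort on the onset of a matched disease state
#'
#' For each patient, the earliest slice in which every \code{varnames[i]}
#' equals \code{varvalues[i]} becomes that patient's new slice 1; later
#' slices keep their relative offsets (new slice = old slice - match slice
#' + 1). Patients never matching the condition are excluded.
#'
#' @param dtsd a \code{\link{build_dtsd}} object.
#' @param varnames character vector of matching variables (must be in
#'   \code{dtsd$variables}).
#' @param varvalues vector of values, parallel to \code{varnames}.
#' @return a re-zeroed \code{dtsd} object.
#' @export
match_subgroup <- function(dtsd, varnames, varvalues) {
  stopifnot(inherits(dtsd, "dtsd"))
  varnames <- unlist(varnames)
  varvalues <- unlist(varvalues)
  if (length(varnames) != length(varvalues))
    stop("varnames and varvalues must have equal length")
  if (!all(varnames %in% dtsd$variables))
    stop("unknown variable(s): ",
         paste(setdiff(varnames, dtsd$variables), collapse = ", "))

  # long view: one row per (patient, slice entry)
  recs <- list()
  for (i in seq_len(dtsd$length)) {
    dat <- dtsd$tsdata[[i]]
    match_here <- rep(TRUE, nrow(dat))
    for (j in seq_along(varnames))
      match_here <- match_here & !is.na(dat[[varnames[j]]]) &
        dat[[varnames[j]]] == varvalues[j]
    recs[[i]] <- data.frame(entry = i, row = seq_len(nrow(dat)),
                            id = dtsd$tsid[[i]], slice = dtsd$slices[i],
                            match = match_here, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, recs)

  new_rows <- list()  # per new-slice index: list of (entry, row)
  for (id in unique(long$id)) {
    sub <- long[long$id == id, , drop = FALSE]
    sub <- sub[order(sub$slice), , drop = FALSE]
    hit <- which(sub$match)
    if (!length(hit)) next
    first <- hit[1L]
    keep <- sub[first:nrow(sub), , drop = FALSE]
    new_slice <- keep$slice - keep$slice[1L] + 1L
    for (k in seq_len(nrow(keep))) {
      key <- as.character(new_slice[k])
      new_rows[[key]] <- rbind(new_rows[[key]],
                               data.frame(entry = keep$entry[k], row = keep$row[k]))
    }
  }
  if (!length(new_rows))
    stop("empty cohort: no patient matches the given condition")

  new_slices <- sort(as.integer(names(new_rows)))
  time_l <- status_l <- tsdata_l <- tsid_l <- vector("list", length(new_slices))
  for (i in seq_along(new_slices)) {
    sel <- new_rows[[as.character(new_slices[i])]]
    time_l[[i]] <- unlist(Map(function(e, r) dtsd$time[[e]][r], sel$entry, sel$row))
    status_l[[i]] <- unlist(Map(function(e, r) dtsd$status[[e]][r], sel$entry, sel$row))
    tsdata_l[[i]] <- do.call(rbind, Map(function(e, r)
      dtsd$tsdata[[e]][r, , drop = FALSE], sel$entry, sel$row))
    rownames(tsdata_l[[i]]) <- NULL
    tsid_l[[i]] <- unlist(Map(function(e, r) dtsd$tsid[[e]][r], sel$entry, sel$row))
  }

  structure(list(
    length = length(new_slices),
    ts_size = vapply(tsid_l, length, integer(1L)),
    slices = new_slices,
    time = time_l,
    status = status_l,
    tsdata = tsdata_l,
    tsid = tsid_l,
    variables = dtsd$variables,
    cutoffs = dtsd$cutoffs
  ), class = "dtsd")
}
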