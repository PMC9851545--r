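#' Run the full survival-path pipeline
#'
#' Reads (or accepts) a per-visit table, bins it into time slices,
#' assembles and dichotomizes the DTSD object, builds the path tree,
#' evaluates per-slice concordance and writes all artifacts to
#' \code{out_dir}: \code{node_table.csv}, \code{trajectory.csv},
#' \code{annotated_slices.csv}, \code{tree.nwk}, \code{cutoffs.json},
#' \code{cindex.csv} and a \code{manifest.json} echoing the configuration.
#'
#' @param input a data frame of per-visit records, or a path to a CSV file
#'   with the same schema.
#' @param out_dir output directory (created if absent).
#' @param id_col,date_col,time_col,status_col column names of the patient
#'   ID, visit date, residual survival time and event status.
#' @param variables covariate columns to model; default: every column not
#'   named above and not in \code{treatments}.
#' @param treatments optional treatment column names (excluded from the
#'   candidate split set).
#' @param period,left_interval,right_interval time-slicing parameters, see
#'   \code{\link{slice_config}}.
#' @param time_slices number of slices to model; default: all slices with
#'   at least \code{minsample} records.
#' @param predict_time dichotomization horizon in days (default 365).
#' @param p_value,minsample,degree_of_correlation,rates path-model
#'   parameters, see \code{\link{path_config}}.
#' @param min_node_size node-size floor for the concordance evaluation
#'   (default \code{minsample}).
#' @param quiet suppress progress messages (default FALSE).
#' @return (invisibly) a list with the \code{dtsd}, \code{tree},
#'   \code{cindex} vector and output paths.
#' @export
run_pipeline <- function(input, out_dir,
                         id_col = "id", date_col = "date",
                         time_col = "surv_time", status_col = "status",
                         variables = NULL, treatments = NULL,
                         period = 90, left_interval = 0.5, right_interval = 0.5,
                         time_slices = NULL, predict_time = 365,
                         p_value = 0.05, minsample = 15,
                         degree_of_correlation = 0.7, rates = 365,
                         min_node_size = minsample, quiet = FALSE) {
  raw <- if (is.character(input)) {
    if (!file.exists(input)) stop("input file not found: ", input)
    utils::read.csv(input, stringsAsFactors = FALSE)
  } else as.data.frame(input)
  for (col in c(id_col, date_col, time_col, status_col))
    if (!col %in% names(raw)) stop("required column missing: ", col)
  if (is.null(variables))
    variables <- setdiff(names(raw),
                         c(id_col, date_col, time_col, status_col, treatments))
  if (!length(variables)) stop("no covariates to model")
  say <- function(...) if (!quiet) message(...)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sliced <- divide_time(raw, id_col, date_col,
                        slice_config(period, left_interval, right_interval))
  say("time division: ", nrow(sliced), " records in ",
      length(unique(sliced$time_slice)), " slice(s)")

  dtsd <- build_dtsd(sliced, "time_slice", id_col, time_col, status_col,
                     variables, ifclassify = TRUE,
                     predict_time = predict_time, isfill = TRUE)
  if (is.null(time_slices)) {
    time_slices <- max(which(dtsd$ts_size >= minsample))
    say("modeling ", time_slices, " slice(s) with >= ", minsample, " records")
  }

  tree <- build_survival_path(dtsd, path_config(
    time_slices = time_slices, p_value = p_value, minsample = minsample,
    degree_of_correlation = degree_of_correlation, rates = rates,
    treatments = treatments))
  say("tree: ", length(tree$nodes), " node(s)")

  cindex <- evaluate_cindex(tree, min_node_size)

  paths <- list(
    node_table = file.path(out_dir, "node_table.csv"),
    trajectory = file.path(out_dir, "trajectory.csv"),
    annotated = file.path(out_dir, "annotated_slices.csv"),
    newick = file.path(out_dir, "tree.nwk"),
    cutoffs = file.path(out_dir, "cutoffs.json"),
    cindex = file.path(out_dir, "cindex.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(node_table(tree), paths$node_table, row.names = FALSE)
  utils::write.csv(tree$trajectory, paths$trajectory, row.names = FALSE)
  utils::write.csv(tree$df, paths$annotated, row.names = FALSE)
  writeLines(to_newick(tree), paths$newick)
  jsonlite::write_json(as.list(dtsd$cutoffs), paths$cutoffs,
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(slice = seq_along(cindex), cindex = cindex),
                   paths$cindex, row.names = FALSE)
  jsonlite::write_json(list(
    package = "survpath",
    version = as.character(utils::packageVersion("survpath")),
    r_version = R.version.string,
    config = list(id_col = id_col, date_col = date_col, time_col = time_col,
                  status_col = status_col, variables = variables,
                  treatments = treatments, period = period,
                  left_interval = left_interval,
                  right_interval = right_interval,
                  time_slices = time_slices, predict_time = predict_time,
                  p_value = p_value, minsample = minsample,
                  degree_of_correlation = degree_of_correlation,
                  rates = rates, min_node_size = min_node_size)),
    paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(dtsd = dtsd, tree = tree, cindex = cindex, paths = paths))
}
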