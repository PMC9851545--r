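#' Survival-path model configuration
#'
#' @param time_slices number of time slices to model (>= 1).
#' @param p_value significance threshold for the per-node selection cascade
#'   (default 0.05).
#' @param minsample minimum node size to attempt a split (default 15).
#' @param degree_of_correlation collinearity |r| threshold (default 0.7).
#' @param rates horizon in days at which each node's survival rate is
#'   annotated (default 365).
#' @param num_categories number of branches per split; only binary splits
#'   (2) are supported.
#' @param treatments optional character vector of treatment/exposure
#'   columns; these are analysis variables and are excluded from the
#'   candidate split set.
#' @return an object of class \code{path_config}.
#' @export
path_config <- function(time_slices, p_value = 0.05, minsample = 15,
                        degree_of_correlation = 0.7, rates = 365,
                        num_categories = 2, treatments = NULL) {
  stopifnot(is.numeric(time_slices), length(time_slices) == 1L, time_slices >= 1)
  if (!identical(as.integer(num_categories), 2L))
    stop("only binary splits are supported (num_categories = 2)")
  stopifnot(rates > 0)
  params <- selection_params(p_value, minsample, degree_of_correlation)
  structure(list(time_slices = as.integer(time_slices), params = params,
                 rates = rates, num_categories = 2L,
                 treatments = treatments),
            class = "path_config")
}

#' Build the survival-path tree
#'
#' Recursive construction across time slices. The root is the full slice-1
#' cohort. For each node at slice t < \code{time_slices}, the selection
#' cascade (\code{\link{select_split}}) runs on the node's own slice-t data;
#' if a split variable is chosen the node's members are partitioned by that
#' variable's value at slice t, otherwise the whole subgroup is carried
#' forward unchanged. Children at slice t+1 are the partition members that
#' still have a record in slice t+1 (patients lost to follow-up or already
#' past their endpoint simply disappear from the tree). Every node is
#' annotated with its size, Kaplan-Meier median residual survival and
#' survival rate at \code{rates} days. Node ids are assigned in level order
#' (breadth first), root = 1, and the child with split-variable value 0
#' always precedes the value-1 child.
#'
#' @param dtsd a \code{\link{build_dtsd}} object with binary covariates.
#' @param config a \code{\link{path_config}}.
#' @return an object of class \code{path_tree}: list with \code{nodes}
#'   (list of node records), \code{trajectory} (data frame patient_id /
#'   slice / node_id), \code{df} (annotated slice table), \code{config} and
#'   \code{dtsd}.
#' @export
build_survival_path <- function(dtsd, config) {
  stopifnot(inherits(dtsd, "dtsd"), inherits(config, "path_config"))
  ts <- config$time_slices
  if (ts > dtsd$length)
    stop("time_slices (", ts, ") exceeds the number of slices in the data (",
         dtsd$length, ")")
  if (dtsd$ts_size[1L] < 1L) stop("empty slice-1 cohort")
  model_vars <- setdiff(dtsd$variables, config$treatments)
  for (i in seq_len(ts)) {
    nonbin <- model_vars[vapply(model_vars, function(v)
      length(unique(dtsd$tsdata[[i]][[v]])) > 2L, logical(1L))]
    if (length(nonbin))
      stop("non-binary covariate(s) at slice ", i, ": ",
           paste(nonbin, collapse = ", "),
           " (dichotomize first, see apply_cutoffs)")
  }

  id_index <- lapply(seq_len(ts), function(i)
    stats::setNames(seq_along(dtsd$tsid[[i]]), dtsd$tsid[[i]]))

  nodes <- list()
  new_node <- function(slice, parent, condition, members) {
    rows <- unname(id_index[[slice]][members])
    tm <- dtsd$time[[slice]][rows]
    st <- dtsd$status[[slice]][rows]
    km <- km_curve(tm, st)
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(node_id = id, slice = slice, parent_id = parent,
                         condition = condition, member_ids = members,
                         size = length(members), median_survival = km$median,
                         survival_rate = unname(km_surv_at(km, config$rates)),
                         split_variable = NA_character_,
                         split_reason = NA_character_, children = integer(0))
    id
  }

  root <- new_node(1L, NA_integer_, list(), dtsd$tsid[[1L]])
  queue <- root
  while (length(queue)) {
    nid <- queue[1L]; queue <- queue[-1L]
    node <- nodes[[nid]]
    t <- node$slice
    if (t >= ts) { nodes[[nid]]$split_reason <- "last_slice"; next }

    rows <- unname(id_index[[t]][node$member_ids])
    sel <- select_split(dtsd$tsdata[[t]][rows, model_vars, drop = FALSE],
                        dtsd$time[[t]][rows], dtsd$status[[t]][rows],
                        config$params)
    nodes[[nid]]$split_variable <- sel$split_variable
    nodes[[nid]]$split_reason <- sel$reason

    present_next <- node$member_ids[node$member_ids %in% dtsd$tsid[[t + 1L]]]
    if (!length(present_next)) next

    if (!is.na(sel$split_variable)) {
      vals <- dtsd$tsdata[[t]][rows, sel$split_variable]
      lev <- sort(unique(vals))
      for (v in lev) {
        kids <- node$member_ids[!is.na(vals) & vals == v]
        kids <- kids[kids %in% present_next]
        if (!length(kids)) next
        cond <- c(node$condition, list(list(variable = sel$split_variable,
                                            value = v)))
        cid <- new_node(t + 1L, nid, cond, kids)
        nodes[[nid]]$children <- c(nodes[[nid]]$children, cid)
        queue <- c(queue, cid)
      }
    } else {
      cid <- new_node(t + 1L, nid, node$condition, present_next)
      nodes[[nid]]$children <- c(nodes[[nid]]$children, cid)
      queue <- c(queue, cid)
    }
  }

  traj <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(patient_id = nd$member_ids, slice = nd$slice,
               node_id = nd$node_id, stringsAsFactors = FALSE)))
  traj <- traj[order(traj$patient_id, traj$slice), , drop = FALSE]
  rownames(traj) <- NULL

  df <- do.call(rbind, lapply(seq_len(ts), function(i) {
    d <- data.frame(patient_id = dtsd$tsid[[i]], time_slice = i,
                    surv_time = dtsd$time[[i]], status = dtsd$status[[i]],
                    stringsAsFactors = FALSE)
    d <- cbind(d, dtsd$tsdata[[i]])
    key <- paste(d$patient_id, i)
    m <- match(key, paste(traj$patient_id, traj$slice))
    d$node_id <- traj$node_id[m]
    d
  }))
  rownames(df) <- NULL

  structure(list(nodes = nodes, trajectory = traj, df = df,
                 config = config, dtsd = dtsd),
            class = "path_tree")
}

#' @export
print.path_tree <- function(x, ...) {
  cat("survival path tree:", length(x$nodes), "nodes over",
      x$config$time_slices, "time slice(s)\n")
  splits <- sum(vapply(x$nodes, function(nd) length(nd$children) == 2L, logical(1L)))
  cat("  bifurcations:", splits, "\n")
  invisible(x)
}

# human-readable "var=0 & var=1" lineage label; "" for the root
condition_label <- function(condition) {
  if (!length(condition)) return("")
  paste(vapply(condition, function(cv)
    paste0(cv$variable, "=", cv$value), character(1L)), collapse = " & ")
}

#' Tabular node summary
#'
#' One row per node, in level order: id, slice, condition lineage, size,
#' median residual survival, survival rate at the configured horizon, split
#' variable.
#'
#' @param tree a \code{\link{build_survival_path}} object.
#' @return data frame.
#' @export
node_table <- function(tree) {
  stopifnot(inherits(tree, "path_tree"))
  do.call(rbind, lapply(tree$nodes, function(nd) data.frame(
    node_id = nd$node_id, slice = nd$slice,
    condition = condition_label(nd$condition),
    size = nd$size, median_survival = nd$median_survival,
    survival_rate = nd$survival_rate,
    split_variable = nd$split_variable,
    stringsAsFactors = FALSE)))
}

#' Export the path tree as a Newick string
#'
#' Node labels are \code{id|size|median|rate} (median "NA" when not
#' reached); every parent-child edge has branch length 1 (one slice step).
#'
#' @param tree a \code{\link{build_survival_path}} object.
#' @return a single Newick string, terminated by ";".
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "path_tree"))
  lab <- function(nd)
    paste(nd$node_id, nd$size,
          if (is.na(nd$median_survival)) "NA" else signif(nd$median_survival, 6),
          signif(nd$survival_rate, 4), sep = "|")
  rec <- function(id) {
    nd <- tree$nodes[[id]]
    if (!length(nd$children)) return(lab(nd))
    inner <- paste(vapply(nd$children, function(c)
      paste0(rec(c), ":1"), character(1L)), collapse = ",")
    paste0("(", inner, ")", lab(nd))
  }
  paste0(rec(1L), ";")
}
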