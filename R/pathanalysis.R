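#' Compare survival between nodes of a path tree
#'
#' Kaplan-Meier curves per node on the members' residual survival at each
#' node's own slice, plus an overall log-rank test across the nodes.
#'
#' @param tree a \code{\link{build_survival_path}} object.
#' @param node_ids two or more distinct node ids.
#' @return list with \code{km} (named list of \code{km_curve}), \code{n}
#'   (per-node sizes), \code{chi2}, \code{df} and \code{p}.
#' @export
compare_nodes <- function(tree, node_ids) {
  stopifnot(inherits(tree, "path_tree"))
  node_ids <- as.integer(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicated node id(s)")
  if (length(node_ids) < 2L) stop("need at least two nodes to compare")
  bad <- setdiff(node_ids, vapply(tree$nodes, `[[`, integer(1L), "node_id"))
  if (length(bad)) stop("unknown node id(s): ", paste(bad, collapse = ", "))

  parts <- lapply(node_ids, function(id) node_outcomes(tree, id))
  times <- unlist(lapply(parts, `[[`, "time"))
  status <- unlist(lapply(parts, `[[`, "status"))
  group <- rep(node_ids, vapply(parts, function(p) length(p$time), integer(1L)))

  lr <- logrank_test(times, status, group)
  km <- stats::setNames(lapply(parts, function(p) km_curve(p$time, p$status)),
                        paste0("node_", node_ids))
  list(km = km, n = vapply(parts, function(p) length(p$time), integer(1L)),
       chi2 = lr$chi2, df = lr$df, p = lr$p)
}

# residual survival outcomes of a node's members at the node's slice
node_outcomes <- function(tree, node_id) {
  nd <- tree$nodes[[node_id]]
  idx <- match(nd$member_ids, tree$dtsd$tsid[[nd$slice]])
  list(time = tree$dtsd$time[[nd$slice]][idx],
       status = tree$dtsd$status[[nd$slice]][idx],
       ids = nd$member_ids, slice = nd$slice)
}

#' Compare treatment arms within one node
#'
#' Stratifies the node's members by the value of a binary treatment column
#' at the node's slice (taken from the time-sliced source table) and runs a
#' Kaplan-Meier / log-rank comparison of residual survival between arms.
#'
#' @param tree a \code{\link{build_survival_path}} object.
#' @param node_id a node id.
#' @param sliced the time-sliced records (output of
#'   \code{\link{divide_time}}) the tree was built from.
#' @param treatment_col name of the binary treatment column in
#'   \code{sliced}.
#' @param id_col,slice_col column names in \code{sliced}.
#' @return list with \code{km} (per arm), \code{n} (per-arm counts),
#'   \code{chi2}, \code{df} and \code{p}.
#' @export
compare_treatments <- function(tree, node_id, sliced, treatment_col,
                               id_col = "id", slice_col = "time_slice") {
  stopifnot(inherits(tree, "path_tree"))
  out <- node_outcomes(tree, node_id)
  trt <- treatment_at_slice(sliced, out$ids, out$slice, treatment_col,
                            id_col, slice_col)
  arms <- table(trt)
  if (length(arms) < 2L)
    stop("empty treatment arm at node ", node_id, ": counts ",
         paste(sprintf("%s=%d", names(arms), arms), collapse = ", "))
  lr <- logrank_test(out$time, out$status, trt)
  km <- lapply(split(seq_along(trt), trt), function(ix)
    km_curve(out$time[ix], out$status[ix]))
  names(km) <- paste0(treatment_col, "_", names(km))
  list(km = km, n = as.integer(arms), chi2 = lr$chi2, df = lr$df, p = lr$p)
}

treatment_at_slice <- function(sliced, ids, slice, treatment_col, id_col,
                               slice_col) {
  for (col in c(treatment_col, id_col, slice_col))
    if (!col %in% names(sliced)) stop("column not found: ", col)
  sub <- sliced[sliced[[slice_col]] == slice, , drop = FALSE]
  m <- match(ids, as.character(sub[[id_col]]))
  if (anyNA(m))
    stop("member(s) of the node have no record at slice ", slice,
         " in the supplied table")
  trt <- sub[[treatment_col]][m]
  if (anyNA(trt)) stop("missing treatment values at slice ", slice)
  trt
}

#' Treatment-to-node-transition table
#'
#' Cross-tabulates, for one node, the treatment received at the node's
#' slice against the node occupied at the next slice ("Missing follow-up"
#' for members with no next-slice record). Proportions are row-normalized
#' within each treatment level; raw counts are retained.
#'
#' @inheritParams compare_treatments
#' @return an object of class \code{transition_table}: list with
#'   \code{counts} and \code{proportions} matrices (rows = treatment
#'   levels, columns = destination node ids plus "Missing follow-up"),
#'   \code{node_id} and \code{treatment}.
#' @export
evolution_after_treatment <- function(tree, node_id, sliced, treatment_col,
                                      id_col = "id", slice_col = "time_slice") {
  stopifnot(inherits(tree, "path_tree"))
  nd <- tree$nodes[[as.integer(node_id)]]
  if (is.null(nd)) stop("unknown node id: ", node_id)
  if (nd$slice >= tree$config$time_slices)
    stop("no next slice: node ", node_id, " is at the last modeled slice")

  trt <- treatment_at_slice(sliced, nd$member_ids, nd$slice, treatment_col,
                            id_col, slice_col)
  nxt <- tree$trajectory[tree$trajectory$slice == nd$slice + 1L, , drop = FALSE]
  dest <- nxt$node_id[match(nd$member_ids, nxt$patient_id)]
  dest_lab <- ifelse(is.na(dest), "Missing follow-up", as.character(dest))

  dest_nodes <- sort(unique(dest[!is.na(dest)]))
  levels_dest <- c(as.character(dest_nodes), "Missing follow-up")
  counts <- table(factor(trt), factor(dest_lab, levels = levels_dest))
  counts <- unclass(counts)
  props <- counts / rowSums(counts)

  structure(list(counts = counts, proportions = props,
                 node_id = nd$node_id, treatment = treatment_col),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("transitions out of node", x$node_id, "by", x$treatment, "\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Per-slice discrimination of the survival path (Harrell's C)
#'
#' For each modeled slice, patients in nodes of size >=
#' \code{min_node_size} are pooled and scored by a node-level risk ranking:
#' nodes are ordered by Kaplan-Meier median residual survival (an undefined
#' median ranks as the best prognosis), ties broken by the survival rate at
#' the configured horizon, and each patient inherits the (negated) rank of
#' their node as risk score. Harrell's C is then computed on the pooled
#' patients. Slices with fewer than two usable nodes yield \code{NA}.
#'
#' @param tree a \code{\link{build_survival_path}} object.
#' @param min_node_size minimum node size for a node to enter the
#'   evaluation (default 15).
#' @return numeric vector of per-slice C-indices (NA where undefined).
#' @export
evaluate_cindex <- function(tree, min_node_size = 15) {
  stopifnot(inherits(tree, "path_tree"), min_node_size >= 1)
  ts <- tree$config$time_slices
  out <- rep(NA_real_, ts)
  for (s in seq_len(ts)) {
    nds <- Filter(function(nd) nd$slice == s && nd$size >= min_node_size,
                  tree$nodes)
    if (length(nds) < 2L) next
    med <- vapply(nds, function(nd)
      ifelse(is.na(nd$median_survival), Inf, nd$median_survival), numeric(1L))
    rate <- vapply(nds, `[[`, numeric(1L), "survival_rate")
    # shorter median (then lower survival rate) = higher risk
    ord <- order(med, rate)
    risk <- numeric(length(nds)); risk[ord] <- -seq_along(nds)
    times <- unlist(lapply(nds, function(nd) node_outcomes(tree, nd$node_id)$time))
    status <- unlist(lapply(nds, function(nd) node_outcomes(tree, nd$node_id)$status))
    scores <- rep(risk, vapply(nds, `[[`, integer(1L), "size"))
    out[s] <- tryCatch(concordance_index(times, status, scores),
                       error = function(e) NA_real_)
  }
  out
}
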