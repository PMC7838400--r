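#' Default proportional threshold set
#'
#' The five retained-edge proportions over which graph metrics are
#' averaged: 10%, 20%, 25%, 30% and 40%.
#'
#' @return Numeric vector of proportions.
#' @export
default_thresholds <- function() c(0.10, 0.20, 0.25, 0.30, 0.40)

#' Proportional thresholding and binarization
#'
#' Retains the `round(p * n_pairs)` node pairs with the largest signed
#' Fisher-z values (most-positive kept; `n_pairs = n(n-1)/2` over retained
#' nodes) and binarizes. Rounding is half-away-from-zero for cross-platform
#' determinism. Ties at the cut are broken by z descending, then by the
#' lexicographically smaller `(i, j)` pair. For lesioned connectomes the
#' proportion is taken over retained-node pairs only, so smaller matrices
#' get proportionally fewer edges.
#'
#' @param conn A [connectome()].
#' @param p Retained edge proportion in `(0, 1]`.
#' @return A [binary_graph()].
#' @export
proportional_threshold <- function(conn, p) {
  stopifnot(inherits(conn, "connectome"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop_invalid("threshold proportion must be in (0, 1], got %s", format(p))
  }
  n <- nrow(conn$z)
  if (n < 2) stop_invalid("connectome needs at least 2 retained nodes")
  ut <- which(upper.tri(conn$z), arr.ind = TRUE)
  vals <- conn$z[ut]
  m <- round_half_away(p * nrow(ut))
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0, n, n)
  A[ut[keep, , drop = FALSE]] <- 1
  A <- A + t(A)
  binary_graph(A, threshold_p = p, retained_nodes = conn$retained_nodes,
               provenance = list(subject_id = conn$subject_id,
                                 group = conn$group, mask_id = conn$mask_id))
}

#' Restrict a connectome or binary graph to one hemisphere
#'
#' Hemispheric metrics use only within-hemisphere connections. For
#' hemispheric modularity the intended order is restrict-then-threshold:
#' restrict the *connectome* and apply [proportional_threshold()] to the
#' restriction (see [q_modularity_multi()] with `hemisphere`). Restricting
#' an already thresholded graph instead is also supported and exposed as
#' the alternative convention.
#'
#' @param obj A [connectome()] or [binary_graph()].
#' @param node_table A `node_table` covering the object's nodes.
#' @param hemisphere `"L"` or `"R"`.
#' @return Object of the same class restricted to that hemisphere.
#' @export
hemisphere_subgraph <- function(obj, node_table, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  hemi <- node_hemispheres(node_table)
  ids <- if (inherits(obj, "connectome")) obj$retained_nodes else obj$retained_nodes
  keep <- which(hemi[as.character(ids)] == hemisphere)
  if (length(keep) == 0) {
    pl_stop("pl_empty_result", "no %s-hemisphere nodes present", hemisphere)
  }
  if (inherits(obj, "connectome")) {
    connectome(obj$z[keep, keep, drop = FALSE], retained_nodes = ids[keep],
               subject_id = obj$subject_id, group = obj$group,
               mask_id = obj$mask_id)
  } else if (inherits(obj, "binary_graph")) {
    binary_graph(obj$adjacency[keep, keep, drop = FALSE],
                 threshold_p = obj$threshold_p, retained_nodes = ids[keep],
                 provenance = obj$provenance)
  } else {
    stop_invalid("unsupported object class: %s", paste(class(obj), collapse = "/"))
  }
}

#' Graph metric averaged across a threshold set
#'
#' Computes modularity Q, per-node participation coefficients or per-node
#' within-module degree z-scores on the binarized graph at each threshold
#' and returns the arithmetic mean across thresholds (nodewise for
#' per-node metrics).
#'
#' @param conn A [connectome()].
#' @param partition Named module vector (names = node ids) covering the
#'   connectome's nodes; typically from [reference_partition()] or the node
#'   table's module labels.
#' @param metric One of `"q"`, `"pc"`, `"wd"`.
#' @param thresholds Numeric proportions (default [default_thresholds()]).
#' @return A scalar (Q) or named per-node numeric vector (PC/WD).
#' @export
multi_threshold_metric <- function(conn, partition,
                                   metric = c("q", "pc", "wd"),
                                   thresholds = default_thresholds()) {
  metric <- match.arg(metric)
  fun <- switch(metric,
                q = function(g) modularity_q(g, partition),
                pc = function(g) participation_coefficients(g, partition),
                wd = function(g) within_module_degree_z(g, partition))
  vals <- lapply(thresholds, function(p) fun(proportional_threshold(conn, p)))
  if (metric == "q") {
    mean(unlist(vals))
  } else {
    Reduce(`+`, vals) / length(vals)
  }
}

#' Modularity of a connectome, averaged over thresholds, optionally
#' hemispheric
#'
#' Convenience wrapper: restricts to a hemisphere first if requested
#' (threshold applied after restriction, at the same proportions), then
#' averages fixed-partition Q across the threshold set.
#'
#' @inheritParams multi_threshold_metric
#' @param node_table Needed when `hemisphere` is given.
#' @param hemisphere `NULL` (whole brain), `"L"` or `"R"`.
#' @return Scalar Q.
#' @export
q_modularity_multi <- function(conn, partition,
                               thresholds = default_thresholds(),
                               node_table = NULL, hemisphere = NULL) {
  if (!is.null(hemisphere)) {
    if (is.null(node_table)) stop_invalid("node_table required for hemispheric Q")
    conn <- hemisphere_subgraph(conn, node_table, hemisphere)
  }
  multi_threshold_metric(conn, partition, "q", thresholds)
}
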