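#' Reference modular partition by Ward clustering
#'
#' Derives a reference modular organization from a group-average Fisher-z
#' matrix by agglomerative hierarchical clustering with Ward's criterion
#' (`stats::hclust(method = "ward.D2")`, equivalent to SciPy's Ward
#' linkage) on Euclidean distances between matrix rows, cut at `k`
#' clusters. The uninformative diagonal is replaced by each row's maximum
#' off-diagonal value before computing distances. Labels are assigned
#' 1..k in order of first node appearance.
#'
#' @param avg_matrix Symmetric group-average z matrix; row/column names
#'   are taken as node ids (defaults to 0-based positions).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of module labels keyed by node id, of
#'   class `partition`.
#' @export
reference_partition <- function(avg_matrix, k) {
  avg_matrix <- as.matrix(avg_matrix)
  n <- nrow(avg_matrix)
  if (!is_count(k, 1L) || k > n) {
    stop_invalid("k must be an integer in 1..%d, got %s", n, format(k))
  }
  ids <- rownames(avg_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n) - 1L)
  prof <- avg_matrix
  tmp <- avg_matrix
  diag(tmp) <- -Inf
  diag(prof) <- apply(tmp, 1, max)
  labs <- if (k == n) {
    seq_len(n)
  } else if (k == 1L) {
    rep(1L, n)
  } else {
    stats::cutree(stats::hclust(stats::dist(prof), method = "ward.D2"), k)
  }
  # relabel 1..k in order of first appearance
  labs <- match(labs, unique(labs))
  structure(stats::setNames(as.integer(labs), ids), class = "partition")
}

# membership of a graph's nodes under a partition (positional integer vector)
graph_membership <- function(graph, partition) {
  memb <- unclass(partition)[rownames(graph$adjacency)]
  if (anyNA(memb)) {
    pl_stop("pl_invalid_node", "graph contains nodes absent from the partition")
  }
  as.integer(memb)
}

#' Newman modularity against a fixed partition
#'
#' `Q = sum_s [ l_s / L - (d_s / (2L))^2 ]` over modules `s`, where `L` is
#' the total edge count, `l_s` the number of edges within module `s`, and
#' `d_s` the summed degree of module-`s` nodes. The partition is fixed and
#' given (no community detection is performed).
#'
#' @param graph A [binary_graph()].
#' @param partition Named module vector covering the graph's nodes.
#' @return Scalar Q in `[-1, 1)`.
#' @export
modularity_q <- function(graph, partition) {
  A <- graph$adjacency
  memb <- graph_membership(graph, partition)
  L <- sum(A) / 2
  if (L == 0) pl_stop("pl_undefined_metric", "modularity is undefined for an edgeless graph")
  deg <- rowSums(A)
  q <- 0
  for (s in unique(memb)) {
    in_s <- memb == s
    l_s <- sum(A[in_s, in_s]) / 2
    d_s <- sum(deg[in_s])
    q <- q + l_s / L - (d_s / (2 * L))^2
  }
  q
}

# per-node edge counts into each module: n x M matrix
module_degree_matrix <- function(A, memb) {
  t(rowsum(A, group = memb, reorder = TRUE))
}

#' Participation coefficients
#'
#' `PC_i = 1 - sum_s (kappa_is / k_i)^2`, with `kappa_is` the number of
#' edges from node `i` into module `s` and `k_i` its degree. Isolated
#' nodes get `PC = 0` by convention.
#'
#' @inheritParams modularity_q
#' @return Named per-node numeric vector in `[0, 1)`.
#' @export
participation_coefficients <- function(graph, partition) {
  A <- graph$adjacency
  memb <- graph_membership(graph, partition)
  k <- rowSums(A)
  kappa <- module_degree_matrix(A, memb)
  pc <- 1 - rowSums((kappa / ifelse(k == 0, 1, k))^2)
  pc[k == 0] <- 0
  stats::setNames(pc, rownames(A))
}

#' Within-module degree z-scores
#'
#' For node `i` in module `m`: `WD_i = (kappa_i - mu_m) / sigma_m`, where
#' `kappa_i` is `i`'s within-module degree and `mu_m`, `sigma_m` the mean
#' and population SD of within-module degrees over module `m`'s nodes.
#' Nodes in modules with `sigma_m = 0` get `WD = 0` by convention.
#'
#' @inheritParams modularity_q
#' @param sd_type `"population"` (divide-by-n, default) or `"sample"`.
#' @return Named per-node numeric vector.
#' @export
within_module_degree_z <- function(graph, partition,
                                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  A <- graph$adjacency
  memb <- graph_membership(graph, partition)
  kappa <- vapply(seq_len(nrow(A)), function(i) {
    sum(A[i, memb == memb[i]])
  }, numeric(1))
  wd <- numeric(length(kappa))
  for (s in unique(memb)) {
    in_s <- memb == s
    mu <- mean(kappa[in_s])
    sg <- if (sd_type == "population") pop_sd(kappa[in_s]) else stats::sd(kappa[in_s])
    wd[in_s] <- if (is.na(sg) || sg == 0) 0 else (kappa[in_s] - mu) / sg
  }
  stats::setNames(wd, rownames(A))
}

#' Identify hubs by the mean-plus-one-SD rule
#'
#' Hubs are the nodes whose score is *strictly* greater than the mean plus
#' one standard deviation of all scores (population SD by default).
#'
#' @param values Named per-node numeric vector (names = node ids).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Integer vector of hub node ids.
#' @export
identify_hubs <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    pl_stop("pl_invalid_input", "need at least 2 finite values to identify hubs")
  }
  s <- if (sd_type == "population") pop_sd(v) else stats::sd(v)
  cut <- mean(v) + s
  as.integer(names(v)[v > cut])
}

#' Build a group hub template from per-subject nodal values
#'
#' Averages per-node PC and WD values across a cohort, nodewise over the
#' subjects in which each node was retained (lesioned cohorts cover
#' different node subsets), and derives global/local hub sets with
#' [identify_hubs()]. Nodes retained in no subject are excluded from the
#' template and from hub candidacy.
#'
#' @param pc_list,wd_list Lists (one element per subject) of named
#'   per-node numeric vectors, as returned by
#'   [participation_coefficients()] / [within_module_degree_z()] or
#'   [multi_threshold_metric()].
#' @param sd_type SD flavour for hub identification.
#' @return A list of class `hub_template` with `node_id`, `pc_mean`,
#'   `wd_mean`, `n_contributing`, `global_hubs`, `local_hubs`.
#' @export
build_hub_template <- function(pc_list, wd_list,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(pc_list) < 1 || length(pc_list) != length(wd_list)) {
    stop_invalid("need matching non-empty PC and WD value lists")
  }
  ids <- sort(unique(as.integer(unlist(lapply(pc_list, names)))))
  key <- as.character(ids)
  nodewise_mean <- function(lst) {
    acc <- stats::setNames(numeric(length(key)), key)
    cnt <- stats::setNames(integer(length(key)), key)
    for (v in lst) {
      acc[names(v)] <- acc[names(v)] + v
      cnt[names(v)] <- cnt[names(v)] + 1L
    }
    list(mean = acc / pmax(cnt, 1L), n = cnt)
  }
  pc <- nodewise_mean(pc_list)
  wd <- nodewise_mean(wd_list)
  structure(list(node_id = ids,
                 pc_mean = pc$mean, wd_mean = wd$mean,
                 n_contributing = pc$n,
                 global_hubs = identify_hubs(pc$mean, sd_type),
                 local_hubs = identify_hubs(wd$mean, sd_type)),
            class = "hub_template")
}

#' @export
print.hub_template <- function(x, ...) {
  cat(sprintf("<hub_template> %d nodes, %d global hubs, %d local hubs\n",
              length(x$node_id), length(x$global_hubs), length(x$local_hubs)))
  invisible(x)
}

#' Per-subject nodal metrics across a cohort, averaged over thresholds
#'
#' Convenience wrapper producing the inputs of [build_hub_template()] for
#' a list of connectomes.
#'
#' @param connectomes List of [connectome()] objects.
#' @param partition Named module vector covering all nodes.
#' @param thresholds Threshold set; use a single value (e.g. `0.25`) for
#'   single-threshold hub topography.
#' @return List with elements `pc` and `wd`, each a list of named
#'   per-node vectors.
#' @export
cohort_nodal_metrics <- function(connectomes, partition,
                                 thresholds = default_thresholds()) {
  pc <- lapply(connectomes, multi_threshold_metric, partition = partition,
               metric = "pc", thresholds = thresholds)
  wd <- lapply(connectomes, multi_threshold_metric, partition = partition,
               metric = "wd", thresholds = thresholds)
  list(pc = pc, wd = wd)
}
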