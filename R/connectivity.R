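#' Background connectivity from a run of node time series
#'
#' Implements the background-connectivity approach to task fMRI: each
#' node's time series is replaced by its least-squares residual against
#' the task and nuisance regressors (an intercept is always included),
#' pairwise Pearson correlations are computed on the residuals, and the
#' correlations are Fisher z-transformed with clipping at
#' `atanh(1 - 1e-7)`.
#'
#' @param ts Numeric T x N matrix, time points by nodes. Column names, if
#'   present and numeric, are taken as node ids; otherwise
#'   `node_ids` or `0:(N-1)` is used.
#' @param task Optional T x K matrix of task regressors (already
#'   convolved).
#' @param nuisance Optional T x J matrix of nuisance regressors.
#' @param node_ids Optional integer node ids for the columns of `ts`.
#' @param subject_id,run_id Identifiers carried into the output.
#' @return A [connectome()] with group `"HC"` and an attribute `run_id`.
#' @export
background_connectivity <- function(ts, task = NULL, nuisance = NULL,
                                    node_ids = NULL,
                                    subject_id = NA_character_,
                                    run_id = NA_character_) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop_invalid("need at least 3 time points, got %d", nrow(ts))
  if (anyNA(ts) || !all(is.finite(ts))) stop_invalid("time series contain non-finite values")
  if (is.null(node_ids)) {
    node_ids <- if (!is.null(colnames(ts)) &&
                      !anyNA(suppressWarnings(as.integer(colnames(ts))))) {
      as.integer(colnames(ts))
    } else {
      seq_len(ncol(ts)) - 1L
    }
  }
  X <- cbind(intercept = rep(1, nrow(ts)), task, nuisance)
  if (nrow(X) != nrow(ts)) {
    pl_stop("pl_incompatible_input",
            "design has %d rows but run has %d time points", nrow(X), nrow(ts))
  }
  if (anyNA(X) || !all(is.finite(X))) stop_invalid("design matrix contains non-finite values")
  res <- residualize(ts, X)
  v <- colSums(res^2)
  if (any(v < 1e-12)) {
    bad <- node_ids[which(v < 1e-12)]
    pl_stop("pl_degenerate_series",
            "zero residual variance for node(s): %s",
            paste(bad, collapse = ", "))
  }
  r <- stats::cor(res)
  z <- fisher_z(r)
  diag(z) <- 0
  out <- connectome(z, retained_nodes = node_ids, subject_id = subject_id,
                    group = "HC")
  attr(out, "run_id") <- run_id
  out
}

# least-squares residuals of each column of y against the columns of X
residualize <- function(y, X) {
  qr.resid(qr(X), y)
}

#' Average run-level connectomes in Fisher-z space
#'
#' Entrywise arithmetic mean of the z matrices of several runs from the
#' same subject over the same retained node set.
#'
#' @param connectomes List of [connectome()] objects sharing `subject_id`
#'   and `retained_nodes`.
#' @return A single averaged [connectome()].
#' @export
average_runs <- function(connectomes) {
  if (length(connectomes) == 0) stop_invalid("no connectomes to average")
  first <- connectomes[[1]]
  for (cn in connectomes[-1]) {
    if (!identical(cn$retained_nodes, first$retained_nodes)) {
      pl_stop("pl_incompatible_input",
              "runs have different retained node sets")
    }
    if (!identical(cn$subject_id, first$subject_id)) {
      pl_stop("pl_incompatible_input", "runs belong to different subjects")
    }
  }
  z <- Reduce(`+`, lapply(connectomes, `[[`, "z")) / length(connectomes)
  connectome(z, retained_nodes = first$retained_nodes,
             subject_id = first$subject_id, group = first$group)
}
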