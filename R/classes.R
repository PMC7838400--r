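#' Construct a connectome
#'
#' A connectome is a symmetric matrix of Fisher-z transformed Pearson
#' correlations over a set of retained nodes. The diagonal carries no
#' information and is stored as zero; all downstream computations exclude it.
#'
#' @param z Symmetric numeric matrix of Fisher-z correlations.
#' @param retained_nodes Integer vector of 0-based node ids, one per
#'   row/column of `z`.
#' @param subject_id Subject identifier.
#' @param group One of `"HC"`, `"REAL"`, `"PSEUDO"`, `"TARGETED"`.
#' @param mask_id Optional lesion-mask identifier for lesioned connectomes.
#' @return An object of class `connectome`.
#' @export
connectome <- function(z, retained_nodes = seq_len(nrow(z)) - 1L,
                       subject_id = NA_character_,
                       group = c("HC", "REAL", "PSEUDO", "TARGETED"),
                       mask_id = NA_character_) {
  group <- match.arg(group)
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop_invalid("connectome matrix must be square")
  retained_nodes <- as.integer(retained_nodes)
  if (length(retained_nodes) != nrow(z)) {
    stop_invalid("retained_nodes length (%d) does not match matrix dimension (%d)",
                 length(retained_nodes), nrow(z))
  }
  if (anyDuplicated(retained_nodes)) stop_invalid("retained_nodes must be unique")
  if (max(abs(z - t(z))) > 1e-12) stop_invalid("connectome matrix must be symmetric")
  diag(z) <- 0
  dimnames(z) <- list(as.character(retained_nodes), as.character(retained_nodes))
  structure(list(z = z, retained_nodes = retained_nodes,
                 subject_id = subject_id, group = group, mask_id = mask_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject=%s group=%s nodes=%d\n",
              x$subject_id, x$group, length(x$retained_nodes)))
  invisible(x)
}

#' Construct a binary graph
#'
#' Undirected, unweighted adjacency over retained nodes, as produced by
#' [proportional_threshold()].
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param threshold_p Retained edge proportion that produced the graph.
#' @param retained_nodes Integer node ids (0-based).
#' @param provenance Free-form list recording source subject/group.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, threshold_p = NA_real_,
                         retained_nodes = seq_len(nrow(adjacency)) - 1L,
                         provenance = list()) {
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency %in% c(0, 1))) stop_invalid("adjacency must be binary")
  if (any(adjacency != t(adjacency))) stop_invalid("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop_invalid("adjacency must have zero diagonal")
  retained_nodes <- as.integer(retained_nodes)
  dimnames(adjacency) <- list(as.character(retained_nodes),
                              as.character(retained_nodes))
  structure(list(adjacency = adjacency, threshold_p = threshold_p,
                 retained_nodes = retained_nodes, provenance = provenance),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> nodes=%d edges=%d p=%s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$threshold_p)))
  invisible(x)
}

#' Construct a lesion mask
#'
#' A lesion mask is either a resolved set of lesioned node ids (`nodes`
#' form, the synthetic path) or a binary 3D voxel grid with an affine
#' (`voxel` form, the neuroimaging path; see
#' [lesioned_nodes_from_voxel_mask()]).
#'
#' @param mask_id Mask identifier.
#' @param nodes Integer vector of lesioned node ids (nodes form).
#' @param data 3D binary array (voxel form).
#' @param affine 4x4 voxel-to-mm affine (voxel form).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask_id, nodes = NULL, data = NULL, affine = NULL) {
  if (!is.null(nodes)) {
    structure(list(mask_id = mask_id, form = "nodes",
                   nodes = sort(unique(as.integer(nodes)))),
              class = "lesion_mask")
  } else {
    if (is.null(data) || is.null(affine)) {
      stop_invalid("voxel-form mask needs both data and affine")
    }
    if (!all(data %in% c(0, 1))) stop_invalid("voxel mask must be binary")
    if (!all(dim(as.matrix(affine)) == c(4, 4))) {
      stop_invalid("affine must be a 4x4 matrix")
    }
    structure(list(mask_id = mask_id, form = "voxel",
                   data = data, affine = as.matrix(affine)),
              class = "lesion_mask")
  }
}

#' @export
print.lesion_mask <- function(x, ...) {
  if (x$form == "nodes") {
    cat(sprintf("<lesion_mask:%s> %d nodes\n", x$mask_id, length(x$nodes)))
  } else {
    cat(sprintf("<lesion_mask:%s> voxel grid %s, %d voxels set\n", x$mask_id,
                paste(dim(x$data), collapse = "x"), sum(x$data)))
  }
  invisible(x)
}
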