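#' Generate a bilateral node space
#'
#' Builds a synthetic node table emulating the structure of a
#' cortical-sphere node set in MNI millimetre space: mirrored left/right
#' coordinate pairs and bilateral modules (every module has nodes in both
#' hemispheres). Module labels are spatially coherent: each module is drawn
#' around a left-hemisphere centroid and mirrored to the right, so that
#' spatially contiguous lesion masks intersect modules the way focal
#' lesions do.
#'
#' The midline convention is `hemisphere == "L"` iff `x < 0`; no nodes are
#' generated with `x == 0` (left coordinates are strictly negative and
#' mirrored to strictly positive).
#'
#' @param n_nodes Total node count; must be even and at least
#'   `2 * n_modules`.
#' @param n_modules Number of bilateral modules.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param module_spread SD (mm) of node scatter around module centroids.
#' @return A `data.frame` of class `node_table` with columns
#'   `node_id` (0-based, contiguous), `x`, `y`, `z`, `module` (1..M),
#'   `hemisphere` (`"L"`/`"R"`).
#' @export
generate_node_space <- function(n_nodes, n_modules, seed, module_spread = 28) {
  if (!is_count(n_nodes, 2L) || n_nodes %% 2L != 0L) {
    stop_invalid("n_nodes must be a positive even integer, got %s",
                 format(n_nodes))
  }
  if (!is_count(n_modules, 1L)) stop_invalid("n_modules must be a positive integer")
  if (n_nodes < 2L * n_modules) {
    stop_invalid("n_nodes (%d) must be at least 2 * n_modules (%d)",
                 n_nodes, 2L * n_modules)
  }
  n_half <- n_nodes %/% 2L
  # per-module node counts on one hemisphere, as even as possible
  sizes <- rep(n_half %/% n_modules, n_modules)
  extra <- n_half %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  box <- list(x = c(-60, -15), y = c(-90, 60), z = c(-40, 70))
  withr::with_seed(as.integer(seed), {
    cx <- stats::runif(n_modules, box$x[1], box$x[2])
    cy <- stats::runif(n_modules, box$y[1], box$y[2])
    cz <- stats::runif(n_modules, box$z[1], box$z[2])
    module <- rep(seq_len(n_modules), sizes)
    x <- stats::rnorm(n_half, cx[module], module_spread)
    y <- stats::rnorm(n_half, cy[module], module_spread)
    z <- stats::rnorm(n_half, cz[module], module_spread)
  })
  # keep left coordinates strictly negative (midline convention)
  x <- pmin(x, -1)
  left <- data.frame(node_id = seq_len(n_half) - 1L, x = x, y = y, z = z,
                     module = module, hemisphere = "L",
                     stringsAsFactors = FALSE)
  right <- left
  right$node_id <- left$node_id + n_half
  right$x <- -left$x
  right$hemisphere <- "R"
  out <- rbind(left, right)
  rownames(out) <- NULL
  class(out) <- c("node_table", "data.frame")
  out
}

# Module labels of a node table as a named integer vector keyed by node id.
node_modules <- function(node_table) {
  stats::setNames(as.integer(node_table$module),
                  as.character(node_table$node_id))
}

# Hemisphere of a node table as a named character vector keyed by node id.
node_hemispheres <- function(node_table) {
  stats::setNames(node_table$hemisphere, as.character(node_table$node_id))
}
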