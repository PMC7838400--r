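#' Resolve a voxel lesion mask to lesioned node ids
#'
#' For each node, the sphere of `sphere_radius_mm` at the node's
#' coordinate is rasterized onto the mask grid (a voxel belongs to the
#' sphere iff its center lies within the radius, in mm via the affine).
#' The node is lesioned iff the fraction of damaged voxels within its
#' sphere is *strictly* greater than `frac_threshold`. The default
#' threshold 0.25 corresponds to the more-than-25%-voxels-damaged rule;
#' sensitivity values such as 0.10/0.20/0.30 are supported by argument.
#'
#' @param mask A voxel-form [lesion_mask()].
#' @param node_table A `node_table`.
#' @param sphere_radius_mm Node sphere radius (default 5 mm).
#' @param frac_threshold Damage fraction threshold in `[0, 1)`.
#' @return Integer vector of lesioned node ids (possibly empty).
#' @export
lesioned_nodes_from_voxel_mask <- function(mask, node_table,
                                           sphere_radius_mm = 5,
                                           frac_threshold = 0.25) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (mask$form != "voxel") stop_invalid("mask is not in voxel form")
  if (frac_threshold < 0 || frac_threshold >= 1) {
    stop_invalid("frac_threshold must be in [0, 1)")
  }
  centers <- voxel_centers(dim(mask$data), mask$affine)
  vals <- as.vector(mask$data)
  lesioned <- integer(0)
  for (r in seq_len(nrow(node_table))) {
    p <- c(node_table$x[r], node_table$y[r], node_table$z[r])
    idx <- which(colSums((centers - p)^2) <= sphere_radius_mm^2)
    if (length(idx) == 0) {
      pl_stop("pl_coverage_error",
              "mask grid does not cover the sphere of node %d",
              node_table$node_id[r])
    }
    if (mean(vals[idx]) > frac_threshold) {
      lesioned <- c(lesioned, node_table$node_id[r])
    }
  }
  lesioned
}

#' Remove lesioned nodes and their connections from a connectome
#'
#' Deletes the rows and columns of the lesioned nodes (node subtraction);
#' connectivity among the remaining nodes is unchanged.
#'
#' @param conn A [connectome()].
#' @param node_set Integer node ids to remove (set semantics; must all be
#'   retained in `conn`).
#' @param group Group label for the lesioned connectome.
#' @param mask_id Optional mask identifier to record.
#' @return A [connectome()] over the remaining nodes.
#' @export
apply_lesion <- function(conn, node_set, group = "PSEUDO",
                         mask_id = conn$mask_id) {
  node_set <- unique(as.integer(node_set))
  unknown <- setdiff(node_set, conn$retained_nodes)
  if (length(unknown) > 0) {
    pl_stop("pl_invalid_node", "node(s) not retained in connectome: %s",
            paste(unknown, collapse = ", "))
  }
  keep <- !(conn$retained_nodes %in% node_set)
  connectome(conn$z[keep, keep, drop = FALSE],
             retained_nodes = conn$retained_nodes[keep],
             subject_id = conn$subject_id, group = group, mask_id = mask_id)
}

#' Build a pseudo-lesion cohort
#'
#' Applies every lesion mask to every healthy-control connectome, yielding
#' one pseudo-lesioned connectome per (mask, control) pair; the cohort
#' size is `n_masks * n_controls`.
#'
#' @param hc_connectomes List of healthy-control [connectome()] objects.
#' @param masks List of node-form [lesion_mask()] objects.
#' @return Flat list of [connectome()] objects with group `"PSEUDO"`,
#'   each tagged with its `mask_id` and source `subject_id`.
#' @export
make_pseudo_cohort <- function(hc_connectomes, masks) {
  out <- list()
  for (mk in masks) {
    if (mk$form != "nodes") stop_invalid("masks must be resolved to node sets")
    for (cn in hc_connectomes) {
      out[[length(out) + 1L]] <- apply_lesion(cn, mk$nodes, group = "PSEUDO",
                                              mask_id = mk$mask_id)
    }
  }
  out
}

#' Targeted hub lesion
#'
#' Removes a chosen hub set (e.g. all reference global hubs) and their
#' connections from a connectome — the classic targeted-attack
#' simulation.
#'
#' @param conn A [connectome()].
#' @param hub_set Integer node ids to remove.
#' @return A [connectome()] with group `"TARGETED"`.
#' @export
targeted_lesion <- function(conn, hub_set) {
  apply_lesion(conn, hub_set, group = "TARGETED")
}

#' PC/WD damage scores of a lesion
#'
#' The PC (WD) damage score of a lesion is the mean of the template's
#' per-node PC (WD) values over the lesioned nodes: the extent to which
#' the lesion hits global (local) hubs.
#'
#' @param template A [build_hub_template()] result.
#' @param node_set Non-empty integer vector of lesioned node ids, all
#'   present in the template.
#' @param mask_id Mask identifier to record.
#' @return A list of class `damage_score` with `mask_id`, `pc_damage`,
#'   `wd_damage`, `n_lesioned`.
#' @export
damage_scores <- function(template, node_set, mask_id = NA_character_) {
  node_set <- unique(as.integer(node_set))
  if (length(node_set) == 0) {
    pl_stop("pl_invalid_input", "cannot score an empty lesion")
  }
  missing <- setdiff(node_set, template$node_id)
  if (length(missing) > 0) {
    pl_stop("pl_invalid_node", "node(s) absent from template: %s",
            paste(missing, collapse = ", "))
  }
  key <- as.character(node_set)
  structure(list(mask_id = mask_id,
                 pc_damage = mean(template$pc_mean[key]),
                 wd_damage = mean(template$wd_mean[key]),
                 n_lesioned = length(node_set)),
            class = "damage_score")
}

#' Damage-score table for a set of masks
#'
#' @param template A [build_hub_template()] result.
#' @param masks List of node-form [lesion_mask()] objects.
#' @return `data.frame` with columns `mask_id`, `pc_damage`, `wd_damage`,
#'   `n_lesioned`, one row per mask in input order.
#' @export
damage_score_table <- function(template, masks) {
  rows <- lapply(masks, function(mk) {
    ds <- damage_scores(template, mk$nodes, mask_id = mk$mask_id)
    data.frame(mask_id = ds$mask_id, pc_damage = ds$pc_damage,
               wd_damage = ds$wd_damage, n_lesioned = ds$n_lesioned,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
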