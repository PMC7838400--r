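#' Parameters for a synthetic connectome cohort
#'
#' Defaults describe the study conditions the generator emulates at desk
#' scale: a healthy-control cohort of 10 subjects over a 60-node,
#' 6-bilateral-module space with planted global (connector) and local
#' (provincial) hubs. Correlation targets are given in r units and realised
#' as block means in Fisher-z space; see the methods vignette for the
#' rationale behind each default.
#'
#' @param n_nodes,n_modules Node-space dimensions (see
#'   [generate_node_space()]).
#' @param r_within,r_between Target mean within-/between-module Pearson
#'   correlations; require `0 <= r_between < r_within < 1`.
#' @param n_global_hubs,n_local_hubs Counts of planted connector/provincial
#'   hubs (placed as mirrored bilateral spatial clumps, with at most half
#'   of any module's nodes planted).
#' @param hub_boost Additive Fisher-z increment applied to a planted
#'   global hub's between-module entries.
#' @param local_hub_boost Additive z increment for a planted local hub's
#'   within-module entries. Larger than `hub_boost` by default: a
#'   provincial boost acts on ~module-size entries against a higher
#'   within-module baseline, whereas a connector boost acts on all
#'   between-module entries, so equal increments would make local hubs
#'   much harder to express than global ones.
#' @param strength_sd SD of the per-node within-module strength factors
#'   (z units). Each node carries a fixed factor `u_i ~ N(0, strength_sd)`
#'   added to all its within-module entries (`z_ij` gains `u_i + u_j`),
#'   emulating the continuous within-module degree heterogeneity of real
#'   functional connectomes; planted local hubs sit on top of this
#'   continuum.
#' @param noise_sd SD of the per-subject Gaussian perturbation in z space.
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_nodes = 60, n_modules = 6,
                          r_within = 0.35, r_between = 0.03,
                          n_global_hubs = 4, n_local_hubs = 10,
                          hub_boost = 0.12, local_hub_boost = 0.20,
                          strength_sd = 0.12, noise_sd = 0.10,
                          n_subjects = 10, seed = 1) {
  if (!(r_between >= 0 && r_between < r_within && r_within < 1)) {
    stop_invalid("need 0 <= r_between < r_within < 1 (got %g, %g)",
                 r_between, r_within)
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is_count(n_subjects, 1L)) stop_invalid("n_subjects must be >= 1")
  if (!is_count(n_global_hubs) || !is_count(n_local_hubs)) {
    stop_invalid("hub counts must be non-negative integers")
  }
  if (n_global_hubs + n_local_hubs > n_nodes) {
    stop_invalid("hub counts exceed n_nodes")
  }
  structure(list(n_nodes = n_nodes, n_modules = n_modules,
                 r_within = r_within, r_between = r_between,
                 n_global_hubs = n_global_hubs, n_local_hubs = n_local_hubs,
                 hub_boost = hub_boost, local_hub_boost = local_hub_boost,
                 strength_sd = strength_sd, noise_sd = noise_sd,
                 n_subjects = n_subjects, seed = as.integer(seed)),
            class = "cohort_params")
}

# Pick a bilateral, spatially clumped hub set: left nodes nearest a random
# left anchor, plus their mirrored right partners. With `spread_cap` at
# most half of any module's nodes may become hubs (a fully-hub module
# would have no within-module degree contrast left to measure), so the
# clump skips over saturated modules to the next-nearest free node;
# without it the clump concentrates in one module (connector hubs).
pick_hub_clump <- function(node_table, n_hubs, exclude, spread_cap = TRUE) {
  if (n_hubs == 0L) return(integer(0))
  n_half <- nrow(node_table) %/% 2L
  module_size <- table(node_table$module)
  cap <- if (spread_cap) floor(unclass(module_size) / 2) else unclass(module_size)
  used <- table(factor(node_table$module[node_table$node_id %in% exclude],
                       levels = names(module_size)))
  used <- stats::setNames(as.integer(used), names(module_size))
  left <- node_table[node_table$hemisphere == "L" &
                       !(node_table$node_id %in% exclude) &
                       !((node_table$node_id + n_half) %in% exclude), ]
  n_left <- ceiling(n_hubs / 2)
  if (nrow(left) < n_left) stop_invalid("not enough free nodes to plant hubs")
  anchor <- left[sample.int(nrow(left), 1L), ]
  d <- sqrt((left$x - anchor$x)^2 + (left$y - anchor$y)^2 +
              (left$z - anchor$z)^2)
  ranked <- left[order(d, left$node_id), ]
  picked_left <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    if (length(picked_left) == n_left) break
    key <- as.character(ranked$module[i])
    if (used[key] + 2L > cap[key]) next  # node + its mirror would oversaturate
    picked_left <- c(picked_left, ranked$node_id[i])
    used[key] <- used[key] + 2L
  }
  if (length(picked_left) < n_left) {
    stop_invalid("not enough module capacity to plant %d hubs", n_hubs)
  }
  hubs <- c(picked_left, picked_left + n_half)
  sort(hubs[seq_len(n_hubs)])
}

# Smooth bilateral within-strength field: a few Gaussian bumps of random
# sign placed in |x|-space (so mirror pairs share their strength), scaled
# to the requested SD over nodes. Draws from the current RNG state.
strength_field <- function(node_table, strength_sd, n_bumps = 4,
                           bandwidth = 30) {
  if (strength_sd == 0) return(numeric(nrow(node_table)))
  p <- cbind(abs(node_table$x), node_table$y, node_table$z)
  ctr <- cbind(stats::runif(n_bumps, min(p[, 1]), max(p[, 1])),
               stats::runif(n_bumps, min(p[, 2]), max(p[, 2])),
               stats::runif(n_bumps, min(p[, 3]), max(p[, 3])))
  w <- stats::rnorm(n_bumps)
  f <- rowSums(vapply(seq_len(n_bumps), function(k) {
    w[k] * exp(-colSums((t(p) - ctr[k, ])^2) / (2 * bandwidth^2))
  }, numeric(nrow(p))))
  f <- f - mean(f)
  s <- pop_sd(f)
  if (s < 1e-12) return(numeric(nrow(node_table)))
  f <- f * strength_sd / s
  # clip heavy tails: extreme rows become clustering outliers
  pmin(pmax(f, -1.6 * strength_sd), 1.6 * strength_sd)
}

# Global (connector) hubs live in one module: mirrored pairs of the left
# members nearest that module's left centroid.
pick_global_hubs <- function(node_table, n_hubs) {
  if (n_hubs == 0L) return(integer(0))
  n_half <- nrow(node_table) %/% 2L
  mod <- sample(unique(node_table$module), 1L)
  left <- node_table[node_table$module == mod & node_table$hemisphere == "L", ]
  n_left <- ceiling(n_hubs / 2)
  if (nrow(left) < n_left) stop_invalid("module too small for %d global hubs", n_hubs)
  d <- sqrt((left$x - mean(left$x))^2 + (left$y - mean(left$y))^2 +
              (left$z - mean(left$z))^2)
  picked_left <- left$node_id[order(d, left$node_id)][seq_len(n_left)]
  hubs <- c(picked_left, picked_left + n_half)
  sort(hubs[seq_len(n_hubs)])
}

# Local (provincial) hubs sit at the top of the within-strength continuum
# *relative to their module* (the within-module degree z-score is a
# module-relative measure, so hub status is module-relative too): the
# nodes with the largest module-centered strength in each hemisphere,
# excluding planted global hubs. They then receive an extra within-module
# boost so they stand clear of the un-planted continuum.
pick_local_hubs <- function(node_table, n_hubs, u, exclude) {
  if (n_hubs == 0L) return(integer(0))
  u_rel <- u - stats::ave(u, node_table$module)
  mods <- sort(unique(node_table$module))
  # round-robin over modules (the within-module degree z-score ranks nodes
  # per module, so hubs concentrated in few modules would be under-called)
  take_side <- function(hemi, n_take) {
    ranked <- lapply(mods, function(mo) {
      side <- node_table[node_table$hemisphere == hemi &
                           node_table$module == mo &
                           !(node_table$node_id %in% exclude), ]
      us <- u_rel[match(side$node_id, node_table$node_id)]
      side$node_id[order(-us, side$node_id)]
    })
    picked <- integer(0)
    round <- 1L
    while (length(picked) < n_take) {
      avail <- vapply(ranked, length, integer(1)) >= round
      if (!any(avail)) stop_invalid("not enough nodes for %d local hubs", n_hubs)
      for (k in which(avail)) {
        if (length(picked) == n_take) break
        picked <- c(picked, ranked[[k]][round])
      }
      round <- round + 1L
    }
    picked
  }
  sort(c(take_side("L", ceiling(n_hubs / 2)),
         take_side("R", floor(n_hubs / 2))))
}

#' Generate a synthetic connectome cohort with planted structure
#'
#' Builds per-subject Fisher-z correlation matrices directly in z space:
#' a block mean matrix (within-module `atanh(r_within)`, between-module
#' `atanh(r_between)`), plus additive hub boosts, plus independent
#' symmetric Gaussian noise per subject. No positive-definiteness is
#' enforced; downstream analyses use only ranks and thresholds, which are
#' invariant to PD projection.
#'
#' Planted global hubs gain `hub_boost` on their between-module entries,
#' planted local hubs `local_hub_boost` on their within-module entries;
#' boosts are additive and accumulate where two hubs meet. Hub sets are
#' bilateral spatial clumps (mirrored pairs), so contiguous lesion masks
#' vary in hub overlap.
#'
#' @param node_table A `node_table` from [generate_node_space()].
#' @param params A [cohort_params()] object.
#' @param group Group label for the generated connectomes.
#' @param id_prefix Prefix for subject ids.
#' @return A list of class `cohort` with elements `connectomes` (list of
#'   [connectome()]), `node_table`, `params`, `planted_global`,
#'   `planted_local` (integer node-id vectors).
#' @export
generate_connectome_cohort <- function(node_table, params = cohort_params(),
                                       group = "HC", id_prefix = group) {
  stopifnot(inherits(params, "cohort_params"))
  if (nrow(node_table) != params$n_nodes) {
    stop_invalid("node_table has %d nodes but params expect %d",
                 nrow(node_table), params$n_nodes)
  }
  n <- nrow(node_table)
  m <- node_table$module
  zw <- atanh(params$r_within)
  zb <- atanh(params$r_between)
  same <- outer(m, m, "==")
  base <- matrix(zb, n, n)
  base[same] <- zw

  withr::with_seed(params$seed, {
    # continuous within-module strength heterogeneity (see cohort_params):
    # a smooth, hemispherically mirrored spatial field, so that strength
    # varies coherently across neighbouring nodes as in real connectomes
    u <- strength_field(node_table, params$strength_sd)
    upair <- outer(u, u, "+")
    base[same] <- base[same] + upair[same]
    global <- pick_global_hubs(node_table, params$n_global_hubs)
    local <- pick_local_hubs(node_table, params$n_local_hubs, u, global)
    for (g in global + 1L) {
      idx <- which(m != m[g])
      base[g, idx] <- base[g, idx] + params$hub_boost
      base[idx, g] <- base[idx, g] + params$hub_boost
    }
    for (l in local + 1L) {
      idx <- setdiff(which(m == m[l]), l)
      base[l, idx] <- base[l, idx] + params$local_hub_boost
      base[idx, l] <- base[idx, l] + params$local_hub_boost
    }
    diag(base) <- 0
    connectomes <- lapply(seq_len(params$n_subjects), function(s) {
      noise <- matrix(0, n, n)
      ut <- upper.tri(noise)
      noise[ut] <- stats::rnorm(sum(ut), 0, params$noise_sd)
      noise <- noise + t(noise)
      connectome(base + noise, retained_nodes = node_table$node_id,
                 subject_id = sprintf("%s%02d", id_prefix, s), group = group)
    })
  })
  structure(list(connectomes = connectomes, node_table = node_table,
                 params = params, planted_global = global,
                 planted_local = local),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d nodes, %d modules\n",
              length(x$connectomes), nrow(x$node_table),
              x$params$n_modules))
  invisible(x)
}

#' Generate contiguous left-hemisphere lesion masks
#'
#' Emulates focal middle-cerebral-artery-like lesions as spatially
#' contiguous sets of left-hemisphere nodes. Contiguity is defined on a
#' 6-nearest-neighbour adjacency in Euclidean coordinate space
#' (symmetrized); each mask grows breadth-first from a random left seed
#' node, expanding neighbours in ascending node-id order, to a size drawn
#' uniformly from `size_min:size_max`.
#'
#' @param node_table A `node_table`.
#' @param n_masks Number of masks.
#' @param size_min,size_max Inclusive node-count bounds per mask.
#' @param seed Integer seed.
#' @param k_neighbours Neighbourhood size of the contiguity graph.
#' @return List of node-form [lesion_mask()] objects.
#' @export
generate_lesion_masks <- function(node_table, n_masks = 25,
                                  size_min = 4, size_max = 8, seed = 1,
                                  k_neighbours = 6) {
  left <- node_table[node_table$hemisphere == "L", ]
  n_left <- nrow(left)
  if (!is_count(n_masks, 1L)) stop_invalid("n_masks must be >= 1")
  if (!is_count(size_min, 1L) || !is_count(size_max, 1L) ||
        size_min > size_max || size_max > n_left) {
    stop_invalid("need 1 <= size_min <= size_max <= %d left-hemisphere nodes",
                 n_left)
  }
  coords <- as.matrix(left[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  k <- min(k_neighbours, n_left - 1L)
  adj <- matrix(FALSE, n_left, n_left)
  for (i in seq_len(n_left)) {
    nb <- order(d[i, ])[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)

  withr::with_seed(as.integer(seed), {
    # stratified seeding: cycle through a shuffled tour of all left nodes,
    # so the mask set reliably spans hub-rich and hub-poor territory
    starts <- rep_len(sample.int(n_left), n_masks)
    masks <- lapply(seq_len(n_masks), function(j) {
      size <- sample(seq(size_min, size_max), 1L)
      start <- starts[j]
      visited <- logical(n_left)
      queue <- start
      visited[start] <- TRUE
      order_taken <- integer(0)
      while (length(queue) > 0 && length(order_taken) < size) {
        cur <- queue[1L]
        queue <- queue[-1L]
        order_taken <- c(order_taken, cur)
        nb <- which(adj[cur, ] & !visited)
        nb <- nb[order(left$node_id[nb])]  # tie rule: ascending node id
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
      if (length(order_taken) < size) {
        stop_invalid("contiguity graph component smaller than requested mask size %d",
                     size)
      }
      lesion_mask(sprintf("mask%02d", j), nodes = left$node_id[order_taken])
    })
  })
  masks
}

#' Rasterize a node set into a binary voxel lesion mask
#'
#' Builds a 3D binary grid (with a diagonal affine) covering the node
#' space, in which approximately `covered_fraction` of the voxels inside
#' each listed node's sphere are set, while all other nodes' spheres are
#' left untouched. Used as a fixture for voxel-mask-to-node resolution.
#'
#' @param node_table A `node_table`.
#' @param node_set Integer node ids to damage.
#' @param voxel_size_mm Isotropic voxel edge length.
#' @param covered_fraction Fraction of each sphere's voxels to set, in
#'   `[0, 1]`.
#' @param seed Integer seed (which voxels are set is randomized).
#' @param sphere_radius_mm Node sphere radius (default 5 mm).
#' @return A voxel-form [lesion_mask()].
#' @export
generate_voxel_mask <- function(node_table, node_set, voxel_size_mm = 2,
                                covered_fraction = 1, seed = 1,
                                sphere_radius_mm = 5) {
  if (covered_fraction < 0 || covered_fraction > 1) {
    stop_invalid("covered_fraction must be in [0, 1]")
  }
  if (!all(node_set %in% node_table$node_id)) {
    pl_stop("pl_invalid_node", "node_set contains ids absent from node table")
  }
  pad <- sphere_radius_mm + 2 * voxel_size_mm
  lo <- c(min(node_table$x), min(node_table$y), min(node_table$z)) - pad
  hi <- c(max(node_table$x), max(node_table$y), max(node_table$z)) + pad
  dims <- ceiling((hi - lo) / voxel_size_mm) + 1L
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- lo
  grid <- array(0L, dim = dims)

  centers <- voxel_centers(dims, affine)
  sphere_vox <- lapply(node_table$node_id, function(id) {
    p <- unlist(node_table[node_table$node_id == id, c("x", "y", "z")])
    which(colSums((centers - p)^2) <= sphere_radius_mm^2)
  })
  names(sphere_vox) <- as.character(node_table$node_id)
  if (any(lengths(sphere_vox[as.character(node_set)]) == 0)) {
    pl_stop("pl_coverage_error", "grid does not cover all requested spheres")
  }
  other <- unique(unlist(sphere_vox[!(node_table$node_id %in% node_set)]))
  withr::with_seed(as.integer(seed), {
    for (id in as.character(node_set)) {
      vox <- sphere_vox[[id]]
      n_set <- round_half_away(covered_fraction * length(vox))
      if (n_set == 0) next
      # prefer voxels exclusive to this sphere so other nodes stay clean
      pool <- setdiff(vox, other)
      if (length(pool) < n_set) pool <- vox
      grid[sample(pool, n_set)] <- 1L
    }
  })
  lesion_mask(sprintf("voxmask_%s", paste(node_set, collapse = "_")),
              data = grid, affine = affine)
}

# mm coordinates of every voxel center, as a 3 x n_voxels matrix
voxel_centers <- function(dims, affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  t(ijk %*% t(affine[1:3, 1:3])) + affine[1:3, 4]
}

#' Parameters for the post-lesion re-organization transform
#'
#' The transform is an explicit hypothesis instrument for long-term
#' network re-organization: it modifies connectivity among the remaining
#' nodes of an already-lesioned connectome as a function of how much hub
#' damage the lesion caused, and promotes a set of remaining nodes to
#' hub-level connectivity.
#'
#' `pc_coupling` is the signed coupling between a mask's global-hub (PC)
#' damage and the modularity of the re-organized network: negative values
#' add inter-module connectivity in proportion to PC damage (compensatory
#' integration), driving modularity *down* as global-hub damage grows.
#' `wd_coupling` is the analogue for local-hub (WD) damage and
#' within-module connectivity. With all parameters zero the transform is
#' the identity.
#'
#' @param pc_coupling,wd_coupling Signed coupling scalars (see above).
#' @param new_hub_count Number of remaining nodes promoted to hub-level
#'   connectivity (alternating local/global promotion, starting local).
#' @param rh_bias Probability that a promoted node is right-hemisphere.
#' @param promotion_boost Additive z increment for promoted rows.
#' @param seed Integer seed used when promotions are drawn.
#' @return A list of class `reorg_params`.
#' @export
reorg_params <- function(pc_coupling = 0, wd_coupling = 0,
                         new_hub_count = 0, rh_bias = 0.5,
                         promotion_boost = 0.25, seed = 1) {
  if (rh_bias < 0 || rh_bias > 1) stop_invalid("rh_bias must be in [0, 1]")
  if (!is_count(new_hub_count)) stop_invalid("new_hub_count must be >= 0")
  structure(list(pc_coupling = pc_coupling, wd_coupling = wd_coupling,
                 new_hub_count = new_hub_count, rh_bias = rh_bias,
                 promotion_boost = promotion_boost, seed = as.integer(seed)),
            class = "reorg_params")
}

#' Select nodes to promote to hub status during re-organization
#'
#' Draws `new_hub_count` promotion targets, alternating promotion type
#' (local, global, local, ...). Each target's hemisphere is right with
#' probability `rh_bias`; the node is sampled uniformly from that
#' hemisphere's non-excluded nodes (falling back to the other hemisphere
#' if exhausted).
#'
#' @param node_table A `node_table`.
#' @param params A [reorg_params()].
#' @param exclude Node ids never promoted (e.g. reference hubs).
#' @return `data.frame` with columns `node_id`, `type`
#'   (`"local"`/`"global"`).
#' @export
select_promotions <- function(node_table, params, exclude = integer(0)) {
  if (params$new_hub_count == 0L) {
    return(data.frame(node_id = integer(0), type = character(0)))
  }
  withr::with_seed(params$seed, {
    chosen <- integer(0)
    types <- character(0)
    for (j in seq_len(params$new_hub_count)) {
      type <- if (j %% 2L == 1L) "local" else "global"
      hemi <- if (stats::runif(1) < params$rh_bias) "R" else "L"
      pool <- node_table$node_id[node_table$hemisphere == hemi &
                                   !(node_table$node_id %in% c(exclude, chosen))]
      if (length(pool) == 0) {
        pool <- node_table$node_id[!(node_table$node_id %in% c(exclude, chosen))]
      }
      if (length(pool) == 0) stop_invalid("no nodes left to promote")
      chosen <- c(chosen, pool[sample.int(length(pool), 1L)])
      types <- c(types, type)
    }
    data.frame(node_id = chosen, type = types, stringsAsFactors = FALSE)
  })
}

#' Apply the re-organization transform to a lesioned connectome
#'
#' Adds damage-coupled global connectivity shifts and hub promotions to
#' the remaining nodes of an already-lesioned connectome (see
#' [reorg_params()] for the model). Module membership comes from the node
#' table's reference module labels.
#'
#' @param lesioned Connectome after node subtraction ([apply_lesion()]).
#' @param damage A [damage_scores()] result for the same mask.
#' @param params A [reorg_params()].
#' @param node_table A `node_table` covering the connectome's nodes.
#' @param promotions Optional pre-drawn promotion table from
#'   [select_promotions()]; supply one shared table when transforming a
#'   whole cohort so promoted hubs are consistent across subjects. If
#'   `NULL`, promotions are drawn from `params$seed`.
#' @return A transformed [connectome()] (group preserved).
#' @export
apply_reorganization <- function(lesioned, damage, params, node_table,
                                 promotions = NULL) {
  stopifnot(inherits(lesioned, "connectome"), inherits(params, "reorg_params"))
  z <- lesioned$z
  ids <- lesioned$retained_nodes
  mods <- node_modules(node_table)[as.character(ids)]
  if (anyNA(mods)) pl_stop("pl_invalid_node", "connectome nodes missing from node table")
  same <- outer(mods, mods, "==")
  off <- !diag(nrow(z))
  z[!same & off] <- z[!same & off] + (-params$pc_coupling) * damage$pc_damage
  z[same & off] <- z[same & off] + (-params$wd_coupling) * damage$wd_damage
  if (is.null(promotions)) {
    promotions <- select_promotions(node_table, params)
  }
  boost <- params$promotion_boost
  for (r in seq_len(nrow(promotions))) {
    id <- promotions$node_id[r]
    i <- match(id, ids)
    if (is.na(i)) next  # promoted node was lesioned out of this subject
    idx <- if (promotions$type[r] == "global") {
      which(mods != mods[i])
    } else {
      setdiff(which(mods == mods[i]), i)
    }
    z[i, idx] <- z[i, idx] + boost
    z[idx, i] <- z[idx, i] + boost
  }
  connectome(z, retained_nodes = ids, subject_id = lesioned$subject_id,
             group = lesioned$group, mask_id = lesioned$mask_id)
}
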