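test_that("node spaces are bilateral, mirrored, and validated", {
  nt <- generate_node_space(20, 2, seed = 1)
  expect_equal(sum(nt$hemisphere == "L"), 10)
  expect_equal(sum(nt$hemisphere == "R"), 10)
  expect_true(all(table(nt$module, nt$hemisphere) > 0))
  expect_equal(nt$node_id, 0:19)
  # mirrored coordinates, no x == 0
  expect_equal(nt$x[11:20], -nt$x[1:10])
  expect_true(all(nt$x != 0))
  expect_true(all((nt$x < 0) == (nt$hemisphere == "L")))
  # 4-node, 2-module case: each module on both hemispheres
  nt4 <- generate_node_space(4, 2, seed = 7)
  expect_equal(sort(unique(nt4$module)), 1:2)
  expect_true(all(table(nt4$module, nt4$hemisphere) == 1))
  expect_error(generate_node_space(5, 2, seed = 1),
               class = "pl_invalid_parameter")
  expect_error(generate_node_space(2, 2, seed = 1),
               class = "pl_invalid_parameter")
  # deterministic for a fixed seed
  expect_identical(nt, generate_node_space(20, 2, seed = 1))
})

test_that("cohort generation hits its block targets and respects noise", {
  nt <- generate_node_space(60, 6, seed = 3)
  # zero noise: all subjects identical
  p0 <- cohort_params(noise_sd = 0, strength_sd = 0, seed = 3)
  co0 <- generate_connectome_cohort(nt, p0)
  expect_identical(co0$connectomes[[1]]$z, co0$connectomes[[5]]$z)
  # symmetry is exact
  z <- co0$connectomes[[1]]$z
  expect_identical(z, t(z))
  # cohort-mean within-block average near atanh(r_within) (no hubs/continuum)
  pm <- cohort_params(r_within = 0.6, r_between = 0.1, noise_sd = 0.1,
                      strength_sd = 0, n_global_hubs = 0, n_local_hubs = 0,
                      n_subjects = 20, seed = 3)
  com <- generate_connectome_cohort(nt, pm)
  zbar <- Reduce(`+`, lapply(com$connectomes, `[[`, "z")) / 20
  same <- outer(nt$module, nt$module, "==") & upper.tri(zbar)
  expect_lt(abs(mean(zbar[same]) - atanh(0.6)), 0.05)
  btw <- !outer(nt$module, nt$module, "==") & upper.tri(zbar)
  expect_lt(abs(mean(zbar[btw]) - atanh(0.1)), 0.05)
  # determinism
  expect_identical(generate_connectome_cohort(nt, pm)$connectomes[[3]]$z,
                   com$connectomes[[3]]$z)
})

test_that("zero hub boost makes planted rows indistinguishable", {
  # with hub_boost = 0 the planted-global rows have the same mean z as
  # non-hub rows: two-sample t-test over 50 seeds is non-significant
  diffs <- vapply(1:50, function(s) {
    nt <- generate_node_space(40, 4, seed = s)
    p <- cohort_params(n_nodes = 40, n_modules = 4, hub_boost = 0,
                       strength_sd = 0, n_global_hubs = 5, n_local_hubs = 0,
                       n_subjects = 2, seed = s)
    co <- generate_connectome_cohort(nt, p)
    z <- co$connectomes[[1]]$z
    hub <- nt$node_id %in% co$planted_global
    mean(z[hub, ]) - mean(z[!hub, ])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("lesion masks are contiguous left-hemisphere node sets", {
  nt <- generate_node_space(60, 6, seed = 5)
  masks <- generate_lesion_masks(nt, n_masks = 25, size_min = 3,
                                 size_max = 8, seed = 9)
  expect_length(masks, 25)
  left_ids <- nt$node_id[nt$hemisphere == "L"]
  coords <- as.matrix(nt[nt$hemisphere == "L", c("x", "y", "z")])
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  adj <- matrix(FALSE, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) adj[i, order(d[i, ])[1:6]] <- TRUE
  adj <- adj | t(adj)
  for (mk in masks) {
    expect_true(all(mk$nodes %in% left_ids))
    expect_true(length(mk$nodes) >= 3 && length(mk$nodes) <= 8)
    # connected under the 6-NN adjacency
    idx <- match(mk$nodes, left_ids)
    reach <- idx[1]
    repeat {
      nxt <- unique(c(reach, idx[apply(adj[reach, idx, drop = FALSE], 2, any)]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_setequal(reach, idx)
  }
  # singleton masks and determinism
  m1 <- generate_lesion_masks(nt, n_masks = 3, size_min = 1, size_max = 1,
                              seed = 2)
  expect_true(all(lengths(lapply(m1, `[[`, "nodes")) == 1))
  expect_identical(generate_lesion_masks(nt, 25, 3, 8, seed = 9), masks)
  expect_error(generate_lesion_masks(nt, 5, 3, 99, seed = 1),
               class = "pl_invalid_parameter")
})

test_that("mask damage scores vary across masks", {
  st <- small_study()
  expect_gt(var(st$damage_table$pc_damage), 0)
  expect_gt(var(st$damage_table$wd_damage), 0)
})

test_that("reorganization is the identity at zero parameters", {
  st <- small_study()
  cn <- apply_lesion(st$hc_cohort$connectomes[[1]], st$masks[[1]]$nodes)
  ds <- damage_scores(st$template, st$masks[[1]]$nodes)
  out <- apply_reorganization(cn, ds, reorg_params(), st$node_table)
  expect_identical(out$z, cn$z)
})

test_that("reorganization shifts inter-module z and promotes hubs", {
  st <- small_study()
  nt <- st$node_table
  cn <- apply_lesion(st$hc_cohort$connectomes[[1]], st$masks[[1]]$nodes)
  ds <- damage_scores(st$template, st$masks[[1]]$nodes)
  pr <- reorg_params(pc_coupling = -0.5)
  out <- apply_reorganization(cn, ds, pr, nt)
  mods <- nt$module[match(cn$retained_nodes, nt$node_id)]
  btw <- outer(mods, mods, "!=")
  expect_equal(mean(out$z[btw] - cn$z[btw]), 0.5 * ds$pc_damage,
               tolerance = 1e-12)
  same <- outer(mods, mods, "==") & !diag(nrow(cn$z))
  expect_equal(out$z[same], cn$z[same])
  expect_identical(out$z, t(out$z))
  # rh_bias = 1 forces all promotions onto the right hemisphere
  prom <- select_promotions(nt, reorg_params(new_hub_count = 6, rh_bias = 1,
                                             seed = 4))
  expect_equal(nrow(prom), 6)
  expect_true(all(nt$hemisphere[match(prom$node_id, nt$node_id)] == "R"))
  expect_setequal(unique(prom$type), c("local", "global"))
})

test_that("parameter validation rejects inconsistent cohort settings", {
  expect_error(cohort_params(r_within = 0.1, r_between = 0.2),
               class = "pl_invalid_parameter")
  expect_error(cohort_params(noise_sd = -1), class = "pl_invalid_parameter")
  expect_error(cohort_params(n_global_hubs = 40, n_local_hubs = 40),
               class = "pl_invalid_parameter")
  expect_error(reorg_params(rh_bias = 2), class = "pl_invalid_parameter")
})
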