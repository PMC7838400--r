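#' Simulate a complete lesion study
#'
#' Generates every ingredient of the three analyses at desk scale: a
#' bilateral node space, a healthy-control cohort and an independent
#' patient cohort with planted modular/hub structure, contiguous
#' left-hemisphere lesion masks, the reference partition (Ward clustering
#' of the HC average matrix), the HC hub template, per-mask damage
#' scores, the pseudo-lesion cohort (every mask applied to every
#' control), and the real-lesion analogue (each patient lesioned with one
#' mask, then transformed by the re-organization model).
#'
#' All randomness derives from `seed`; sub-seeds for each stage are
#' recorded in the returned manifest.
#'
#' @param seed Master integer seed.
#' @param params A [cohort_params()]; `n_subjects` is used for the HC
#'   cohort.
#' @param n_patients Number of real-lesion subjects (one mask each).
#' @param n_masks Number of lesion masks (defaults to `n_patients`).
#' @param size_min,size_max Mask size bounds (nodes).
#' @param reorg A [reorg_params()] applied to the real group;
#'   `reorg_params()` (all zero) makes the real group pure subtraction.
#' @param thresholds Threshold set used for the HC template metrics.
#' @return A list of class `lesion_study`.
#' @export
simulate_study <- function(seed = 1, params = cohort_params(),
                           n_patients = 25, n_masks = n_patients,
                           size_min = 4, size_max = 8,
                           reorg = reorg_params(pc_coupling = -0.75,
                                                wd_coupling = 0,
                                                new_hub_count = 10,
                                                rh_bias = 0.9,
                                                promotion_boost = 0.35),
                           thresholds = default_thresholds()) {
  seeds <- list(node_space = child_seed(seed, 1), hc = child_seed(seed, 2),
                patients = child_seed(seed, 3), masks = child_seed(seed, 4),
                reorg = child_seed(seed, 5))
  node_table <- generate_node_space(params$n_nodes, params$n_modules,
                                    seed = seeds$node_space)
  hc_params <- params
  hc_params$seed <- seeds$hc
  hc_cohort <- generate_connectome_cohort(node_table, hc_params,
                                          group = "HC", id_prefix = "HC")
  pt_params <- params
  pt_params$n_subjects <- n_patients
  pt_params$seed <- seeds$patients
  patient_cohort <- generate_connectome_cohort(node_table, pt_params,
                                               group = "HC",
                                               id_prefix = "PT")
  masks <- generate_lesion_masks(node_table, n_masks = n_masks,
                                 size_min = size_min, size_max = size_max,
                                 seed = seeds$masks)
  avg <- Reduce(`+`, lapply(hc_cohort$connectomes, `[[`, "z")) /
    length(hc_cohort$connectomes)
  dimnames(avg) <- list(as.character(node_table$node_id),
                        as.character(node_table$node_id))
  partition <- reference_partition(avg, k = params$n_modules)
  nm <- cohort_nodal_metrics(hc_cohort$connectomes, partition, thresholds)
  template <- build_hub_template(nm$pc, nm$wd)
  damage_table <- damage_score_table(template, masks)

  reorg$seed <- seeds$reorg
  promotions <- select_promotions(node_table, reorg,
                                  exclude = c(template$global_hubs,
                                              template$local_hubs))
  # couplings act on cohort-centered damage: re-organization differs across
  # lesions without shifting the group-mean connectivity level
  real_cohort <- lapply(seq_len(n_patients), function(i) {
    mk <- masks[[(i - 1L) %% length(masks) + 1L]]
    les <- apply_lesion(patient_cohort$connectomes[[i]], mk$nodes,
                        group = "REAL", mask_id = mk$mask_id)
    ds <- damage_scores(template, mk$nodes, mask_id = mk$mask_id)
    ds$pc_damage <- ds$pc_damage - mean(damage_table$pc_damage)
    ds$wd_damage <- ds$wd_damage - mean(damage_table$wd_damage)
    apply_reorganization(les, ds, reorg, node_table,
                         promotions = promotions)
  })
  pseudo_cohort <- make_pseudo_cohort(hc_cohort$connectomes, masks)

  structure(list(node_table = node_table, hc_cohort = hc_cohort,
                 patient_cohort = patient_cohort, masks = masks,
                 partition = partition, template = template,
                 damage_table = damage_table, promotions = promotions,
                 real_cohort = real_cohort, pseudo_cohort = pseudo_cohort,
                 thresholds = thresholds, reorg = reorg,
                 manifest = list(seed = as.integer(seed), seeds = seeds,
                                 params = unclass(params),
                                 n_patients = n_patients,
                                 n_masks = n_masks,
                                 size_min = size_min, size_max = size_max,
                                 reorg = unclass(reorg))),
            class = "lesion_study")
}

#' @export
print.lesion_study <- function(x, ...) {
  cat(sprintf(
    "<lesion_study> %d nodes | HC n=%d | real n=%d | pseudo n=%d | %d masks\n",
    nrow(x$node_table), length(x$hc_cohort$connectomes),
    length(x$real_cohort), length(x$pseudo_cohort), length(x$masks)))
  invisible(x)
}

#' Analysis 1: simulated targeted hub lesions
#'
#' Removes the template's global hubs (and, separately, local hubs) from
#' every healthy-control connectome, computes threshold-averaged
#' fixed-partition modularity for intact and attacked connectomes, and
#' compares each attack against intact with paired t-tests
#' (Bonferroni-corrected over the two comparisons). Expected pattern:
#' global-hub removal increases Q, local-hub removal decreases it.
#'
#' @param study A [simulate_study()] result (or compatible list).
#' @param thresholds Threshold set for Q.
#' @return A list with `q_table` (per subject: `q_intact`, `q_global_attack`,
#'   `q_local_attack`), `delta` (mean Q changes), `tests` (t-table), and
#'   `skipped` (character vector of attacks skipped for empty hub sets).
#' @export
run_analysis1 <- function(study, thresholds = study$thresholds) {
  conns <- study$hc_cohort$connectomes
  part <- study$partition
  tmpl <- study$template
  q_of <- function(cn) multi_threshold_metric(cn, part, "q", thresholds)
  q_intact <- vapply(conns, q_of, numeric(1))
  skipped <- character(0)
  attack_q <- function(hubs, label) {
    if (length(hubs) == 0) {
      warning(sprintf("no %s hubs in template; targeted attack skipped", label))
      skipped <<- c(skipped, label)
      return(rep(NA_real_, length(conns)))
    }
    vapply(conns, function(cn) q_of(targeted_lesion(cn, hubs)), numeric(1))
  }
  q_global <- attack_q(tmpl$global_hubs, "global")
  q_local <- attack_q(tmpl$local_hubs, "local")
  q_table <- data.frame(subject_id = vapply(conns, `[[`, "", "subject_id"),
                        q_intact = q_intact, q_global_attack = q_global,
                        q_local_attack = q_local, stringsAsFactors = FALSE)
  comparisons <- list()
  if (!("global" %in% skipped)) {
    comparisons$global_attack_vs_intact <- list(a = q_global, b = q_intact)
  }
  if (!("local" %in% skipped)) {
    comparisons$local_attack_vs_intact <- list(a = q_local, b = q_intact)
  }
  tests <- if (length(comparisons) > 0) {
    group_ttests(comparisons, design = "paired", n_comparisons = 2)
  } else {
    NULL
  }
  list(q_table = q_table,
       delta = c(global = mean(q_global - q_intact),
                 local = mean(q_local - q_intact)),
       tests = tests, skipped = skipped)
}

# modularity of each connectome in a list at the given scope
cohort_q <- function(conns, partition, thresholds, node_table = NULL,
                     hemisphere = NULL) {
  vapply(conns, q_modularity_multi, numeric(1), partition = partition,
         thresholds = thresholds, node_table = node_table,
         hemisphere = hemisphere)
}

#' Analysis 2: pseudo- vs real-lesion modularity and hub-damage coupling
#'
#' Computes whole-brain and hemispheric modularity for the HC, pseudo-
#' and real-lesion groups; correlates the per-mask PC/WD damage scores
#' with modularity (per control for the pseudo group, with a group
#' permutation test; a single correlation with a permutation test for the
#' real group); compares real against pseudo correlations by bootstrap;
#' and t-tests group modularity differences (Bonferroni over 3).
#'
#' Right-hemisphere results for the pseudo group are marked not
#' applicable: left-only lesions remove nothing from the right
#' hemisphere, so pseudo RH connectomes are identical to HC.
#'
#' @param study A [simulate_study()] result.
#' @param thresholds Threshold set for Q.
#' @param n_perm Permutations for the correlation tests.
#' @param n_boot Bootstrap replicates for the group comparison.
#' @param side Side rule for permutation tests.
#' @param seed Integer seed for the resampling.
#' @return A list with `correlations` (tidy data.frame: scope, measure,
#'   group, mean_r, p_perm, n), `bootstrap` (scope x measure table),
#'   `ttests`, `q_hc`, `q_real`, `q_pseudo` (mask x control matrices per
#'   scope), and `rh_pseudo = "not_applicable"`.
#' @export
run_analysis2 <- function(study, thresholds = study$thresholds,
                          n_perm = 10000, n_boot = 10000,
                          side = c("one_sided", "two_sided"), seed = 1) {
  side <- match.arg(side)
  part <- study$partition
  nt <- study$node_table
  masks <- study$masks
  n_masks <- length(masks)
  hc <- study$hc_cohort$connectomes
  n_hc <- length(hc)
  dmg <- study$damage_table

  q_hc <- data.frame(
    subject_id = vapply(hc, `[[`, "", "subject_id"),
    whole = cohort_q(hc, part, thresholds),
    LH = cohort_q(hc, part, thresholds, nt, "L"),
    RH = cohort_q(hc, part, thresholds, nt, "R"),
    stringsAsFactors = FALSE)

  q_real <- data.frame(
    subject_id = vapply(study$real_cohort, `[[`, "", "subject_id"),
    mask_id = vapply(study$real_cohort, `[[`, "", "mask_id"),
    whole = cohort_q(study$real_cohort, part, thresholds),
    LH = cohort_q(study$real_cohort, part, thresholds, nt, "L"),
    RH = cohort_q(study$real_cohort, part, thresholds, nt, "R"),
    stringsAsFactors = FALSE)

  # pseudo cohort is ordered mask-major (mask 1 x all controls, ...)
  q_pseudo <- list()
  for (scope in c("whole", "LH")) {
    hemi <- if (scope == "whole") NULL else "L"
    qv <- cohort_q(study$pseudo_cohort, part, thresholds, nt, hemi)
    q_pseudo[[scope]] <- matrix(qv, nrow = n_masks, ncol = n_hc, byrow = TRUE,
                                dimnames = list(vapply(masks, `[[`, "", "mask_id"),
                                                q_hc$subject_id))
  }

  align <- match(q_real$mask_id, dmg$mask_id)
  corr_rows <- list()
  boot_rows <- list()
  k <- 0
  for (measure in c("PC", "WD")) {
    dvec <- if (measure == "PC") dmg$pc_damage else dmg$wd_damage
    for (scope in c("whole", "LH", "RH")) {
      # real group: one r over the mask-aligned damage values
      real_perm <- permutation_p(dvec[align], q_real[[scope]],
                                 n_perm = n_perm, side = side,
                                 seed = child_seed(seed, k <- k + 1))
      corr_rows[[length(corr_rows) + 1L]] <- data.frame(
        scope = scope, measure = measure, group = "REAL",
        mean_r = real_perm$r, p_perm = real_perm$p, n = nrow(q_real),
        stringsAsFactors = FALSE)
      if (scope != "RH") {
        grp <- group_permutation_p(dvec, q_pseudo[[scope]], n_perm = n_perm,
                                   side = side,
                                   seed = child_seed(seed, k <- k + 1))
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          scope = scope, measure = measure, group = "PSEUDO",
          mean_r = grp$mean_r, p_perm = grp$p, n = n_masks,
          stringsAsFactors = FALSE)
        bt <- bootstrap_compare(real_perm$r, grp$r_values, n_boot = n_boot,
                                seed = child_seed(seed, k <- k + 1))
        boot_rows[[length(boot_rows) + 1L]] <- data.frame(
          scope = scope, measure = measure, real_r = real_perm$r,
          pseudo_mean_r = grp$mean_r, p_boot = bt$p,
          stringsAsFactors = FALSE)
      }
    }
  }

  ttests <- group_ttests(
    list(hc_vs_pseudo = list(a = q_hc$whole, b = as.vector(q_pseudo$whole)),
         hc_vs_real = list(a = q_hc$whole, b = q_real$whole),
         pseudo_vs_real = list(a = as.vector(q_pseudo$whole), b = q_real$whole)),
    design = "independent", n_comparisons = 3)

  list(correlations = do.call(rbind, corr_rows),
       bootstrap = do.call(rbind, boot_rows),
       ttests = ttests,
       q_hc = q_hc, q_real = q_real, q_pseudo = q_pseudo,
       rh_pseudo = "not_applicable")
}

#' Analysis 3: hub neurotopography in pseudo and real lesions
#'
#' Identifies global and local hubs for the HC, pseudo- and real-lesion
#' groups from group hub templates computed at a single proportional
#' threshold (default 25%), then compares hub sets (pseudo vs real, HC vs
#' each lesioned group) and tests the right-hemisphere laterality of each
#' group's hubs against a 50/50 split.
#'
#' @param study A [simulate_study()] result.
#' @param threshold Single proportional threshold for hub topography.
#' @return A list with `templates`, `hub_sets`, `comparisons` (named list
#'   of [compare_hub_sets()] results, per hub type), and `counts`.
#' @export
run_analysis3 <- function(study, threshold = 0.25) {
  part <- study$partition
  nt <- study$node_table
  tmpl_of <- function(conns) {
    nm <- cohort_nodal_metrics(conns, part, thresholds = threshold)
    build_hub_template(nm$pc, nm$wd)
  }
  templates <- list(HC = tmpl_of(study$hc_cohort$connectomes),
                    PSEUDO = tmpl_of(study$pseudo_cohort),
                    REAL = tmpl_of(study$real_cohort))
  hub_sets <- lapply(templates, function(t) {
    list(global = t$global_hubs, local = t$local_hubs)
  })
  comparisons <- list(
    pseudo_vs_real_global = compare_hub_sets(hub_sets$PSEUDO$global,
                                             hub_sets$REAL$global, nt),
    pseudo_vs_real_local = compare_hub_sets(hub_sets$PSEUDO$local,
                                            hub_sets$REAL$local, nt),
    hc_vs_pseudo_global = compare_hub_sets(hub_sets$HC$global,
                                           hub_sets$PSEUDO$global, nt),
    hc_vs_pseudo_local = compare_hub_sets(hub_sets$HC$local,
                                          hub_sets$PSEUDO$local, nt),
    hc_vs_real_global = compare_hub_sets(hub_sets$HC$global,
                                         hub_sets$REAL$global, nt),
    hc_vs_real_local = compare_hub_sets(hub_sets$HC$local,
                                        hub_sets$REAL$local, nt))
  counts <- do.call(rbind, lapply(names(hub_sets), function(g) {
    data.frame(group = g,
               n_global = length(hub_sets[[g]]$global),
               n_local = length(hub_sets[[g]]$local),
               stringsAsFactors = FALSE)
  }))
  list(templates = templates, hub_sets = hub_sets,
       comparisons = comparisons, counts = counts)
}
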