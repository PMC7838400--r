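#' Pearson correlation with input validation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    pl_stop("pl_incompatible_input", "x and y must have equal length")
  }
  if (length(x) < 3) pl_stop("pl_degenerate_input", "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pl_stop("pl_degenerate_input", "zero variance input")
  }
  stats::cor(x, y)
}

# n x n_perm matrix of permutation indices, drawn under the current RNG state
perm_index_matrix <- function(n, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

#' Permutation p-value for a Pearson correlation
#'
#' Permutes `y` `n_perm` times and computes
#' `p = (1 + n_as_extreme) / (n_perm + 1)` (add-one correction, so p is
#' never 0). The default side is one-sided in the direction of the
#' observed r: the null count is of permuted correlations at least as
#' extreme as the observed one *in its own sign direction*. `"two_sided"`
#' counts `|r*| >= |r|`. Note that choosing the side from the observed
#' sign doubles the null rejection rate relative to a fixed-direction
#' test; use `"two_sided"` when no direction is prespecified.
#'
#' @param x,y Numeric vectors (see [pearson_r()]).
#' @param n_perm Number of permutations (default 10000).
#' @param side `"one_sided"` (default; direction of the observed r) or
#'   `"two_sided"`.
#' @param seed Integer seed.
#' @return A list with `r`, `p`, `n_perm`, `side`, `seed`.
#' @export
permutation_p <- function(x, y, n_perm = 10000,
                          side = c("one_sided", "two_sided"), seed = 1) {
  side <- match.arg(side)
  r_obs <- pearson_r(x, y)
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  withr::with_seed(as.integer(seed), {
    P <- perm_index_matrix(n, n_perm)
  })
  r_null <- as.vector(crossprod(xs, matrix(ys[P], nrow = n))) / (n - 1)
  extreme <- if (side == "two_sided") {
    sum(abs(r_null) >= abs(r_obs))
  } else if (r_obs >= 0) {
    sum(r_null >= r_obs)
  } else {
    sum(r_null <= r_obs)
  }
  list(r = r_obs, p = (1 + extreme) / (n_perm + 1), n_perm = n_perm,
       side = side, seed = as.integer(seed))
}

#' Group permutation test for damage-modularity coupling
#'
#' For a pseudo-lesion cohort of `n_masks x n_controls` modularity values,
#' computes one Pearson r per control (between the mask-level damage
#' vector and that control's modularity column) and uses the mean r as the
#' test statistic. The null is built by permuting the damage vector once
#' per permutation and recomputing all per-control correlations: the masks
#' are the exchangeable units, shared across controls.
#'
#' @param damage Numeric vector of per-mask damage scores (length
#'   `n_masks`).
#' @param q_matrix Numeric `n_masks x n_controls` matrix of modularity
#'   values.
#' @param n_perm Number of permutations.
#' @param side As in [permutation_p()].
#' @param seed Integer seed.
#' @return A list with `r_values` (per control), `mean_r`, `p`, `n_perm`,
#'   `side`, `seed`.
#' @export
group_permutation_p <- function(damage, q_matrix, n_perm = 10000,
                                side = c("one_sided", "two_sided"),
                                seed = 1) {
  side <- match.arg(side)
  q_matrix <- as.matrix(q_matrix)
  n <- length(damage)
  if (nrow(q_matrix) != n) {
    pl_stop("pl_incompatible_input",
            "q_matrix has %d rows but damage has length %d", nrow(q_matrix), n)
  }
  if (stats::sd(damage) == 0) pl_stop("pl_degenerate_input", "damage vector is constant")
  sds <- apply(q_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    pl_stop("pl_degenerate_input", "constant modularity column for control(s): %s",
            paste(bad, collapse = ", "))
  }
  ds <- (damage - mean(damage)) / stats::sd(damage)
  qs <- scale(q_matrix)
  r_values <- as.vector(crossprod(ds, qs)) / (n - 1)
  mean_r <- mean(r_values)
  withr::with_seed(as.integer(seed), {
    P <- perm_index_matrix(n, n_perm)
  })
  null_means <- rowMeans(crossprod(matrix(ds[P], nrow = n), qs) / (n - 1))
  extreme <- if (side == "two_sided") {
    sum(abs(null_means) >= abs(mean_r))
  } else if (mean_r >= 0) {
    sum(null_means >= mean_r)
  } else {
    sum(null_means <= mean_r)
  }
  list(r_values = r_values, mean_r = mean_r,
       p = (1 + extreme) / (n_perm + 1), n_perm = n_perm, side = side,
       seed = as.integer(seed))
}

#' Bootstrap comparison of a single correlation against a group
#'
#' Resamples the pseudo-lesion correlation values with replacement (same
#' size), takes the mean, `n_boot` times, and compares the real-lesion
#' correlation against the bootstrap distribution:
#' `p = 2 * min(#{boot <= real}, #{boot >= real}) / n_boot`, capped at 1
#' (two-sided by tail doubling).
#'
#' @param real_r Single correlation value (real-lesion group).
#' @param pseudo_rs Numeric vector of per-control correlations (length
#'   >= 2).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list with `p`, `boot_mean`, `n_boot`, `seed`.
#' @export
bootstrap_compare <- function(real_r, pseudo_rs, n_boot = 10000, seed = 1) {
  if (length(pseudo_rs) < 2) {
    pl_stop("pl_invalid_input", "need at least 2 pseudo-group correlations")
  }
  m <- length(pseudo_rs)
  withr::with_seed(as.integer(seed), {
    draws <- matrix(sample(pseudo_rs, n_boot * m, replace = TRUE), nrow = n_boot)
  })
  boot <- rowMeans(draws)
  p <- 2 * min(sum(boot <= real_r), sum(boot >= real_r)) / n_boot
  list(p = min(p, 1), boot_mean = mean(boot), n_boot = n_boot,
       seed = as.integer(seed))
}

#' Two-sided t-tests with Bonferroni correction
#'
#' Runs one paired or independent two-sided t-test per listed comparison
#' and multiplies p-values by `n_comparisons` (capped at 1). Comparisons
#' with zero-variance differences (paired) or zero pooled variance are
#' reported as degenerate rather than producing NaN.
#'
#' @param comparisons Named list; each element is a list with numeric
#'   vectors `a` and `b`.
#' @param design `"paired"` or `"independent"`.
#' @param n_comparisons Bonferroni multiplier (defaults to the number of
#'   comparisons).
#' @return `data.frame` with columns `comparison`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `degenerate`.
#' @export
group_ttests <- function(comparisons, design = c("paired", "independent"),
                         n_comparisons = length(comparisons)) {
  design <- match.arg(design)
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    a <- cmp$a
    b <- cmp$b
    if (design == "paired" && length(a) != length(b)) {
      pl_stop("pl_incompatible_input",
              "paired comparison '%s' has misaligned groups", nm)
    }
    degenerate <- if (design == "paired") {
      length(a) < 2 || stats::sd(a - b) == 0
    } else {
      length(a) < 2 || length(b) < 2 || (stats::sd(a) == 0 && stats::sd(b) == 0)
    }
    if (degenerate) {
      data.frame(comparison = nm, t = NA_real_, df = NA_real_,
                 p_raw = NA_real_, p_bonferroni = NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b, paired = design == "paired",
                          var.equal = design == "independent")
      data.frame(comparison = nm, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * n_comparisons),
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Compare two hub sets and their laterality
#'
#' Computes lost hubs (in A but not B), new hubs (in B but not A) and
#' shared hubs, the right-hemisphere fraction of each set, and a 1-df
#' chi-square goodness-of-fit test (no continuity correction) of B's
#' left/right counts against a 50/50 split.
#'
#' @param hubs_A,hubs_B Integer node-id vectors (e.g. pseudo-group and
#'   real-group hubs).
#' @param node_table A `node_table` covering both sets.
#' @return A list of class `hub_comparison` with `lost`, `new`, `shared`,
#'   `rh_fraction_A`, `rh_fraction_B`, `chi2_B`, `p_B`.
#' @export
compare_hub_sets <- function(hubs_A, hubs_B, node_table) {
  hubs_A <- unique(as.integer(hubs_A))
  hubs_B <- unique(as.integer(hubs_B))
  if (!all(c(hubs_A, hubs_B) %in% node_table$node_id)) {
    pl_stop("pl_invalid_node", "hub sets contain ids absent from node table")
  }
  hemi <- node_hemispheres(node_table)
  rh_frac <- function(s) {
    if (length(s) == 0) NA_real_ else mean(hemi[as.character(s)] == "R")
  }
  n_b <- length(hubs_B)
  if (n_b > 0) {
    n_r <- sum(hemi[as.character(hubs_B)] == "R")
    expected <- n_b / 2
    chi2 <- (n_r - expected)^2 / expected + ((n_b - n_r) - expected)^2 / expected
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- NA_real_
  }
  structure(list(lost = setdiff(hubs_A, hubs_B),
                 new = setdiff(hubs_B, hubs_A),
                 shared = intersect(hubs_A, hubs_B),
                 rh_fraction_A = rh_frac(hubs_A),
                 rh_fraction_B = rh_frac(hubs_B),
                 chi2_B = chi2, p_B = p),
            class = "hub_comparison")
}

#' @export
print.hub_comparison <- function(x, ...) {
  cat(sprintf("<hub_comparison> lost=%d new=%d shared=%d rh(B)=%.2f chi2=%.3g p=%.3g\n",
              length(x$lost), length(x$new), length(x$shared),
              x$rh_fraction_B, x$chi2_B, x$p_B))
  invisible(x)
}
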