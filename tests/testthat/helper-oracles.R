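# Independent brute-force oracles, deliberately written as naive
# edge-enumeration loops so they share no code path with the package.

oracle_edges <- function(A) {
  out <- NULL
  n <- nrow(A)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (A[i, j] != 0) out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_q <- function(A, memb) {
  edges <- oracle_edges(A)
  L <- if (is.null(edges)) 0 else nrow(edges)
  stopifnot(L > 0)
  q <- 0
  for (s in unique(memb)) {
    l_s <- 0
    d_s <- 0
    if (!is.null(edges)) {
      for (e in seq_len(nrow(edges))) {
        i <- edges[e, 1]; j <- edges[e, 2]
        if (memb[i] == s && memb[j] == s) l_s <- l_s + 1
        if (memb[i] == s) d_s <- d_s + 1
        if (memb[j] == s) d_s <- d_s + 1
      }
    }
    q <- q + l_s / L - (d_s / (2 * L))^2
  }
  q
}

oracle_pc <- function(A, memb) {
  n <- nrow(A)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k == 0) { pc[i] <- 0; next }
    acc <- 0
    for (s in unique(memb)) {
      kis <- 0
      for (j in seq_len(n)) if (A[i, j] != 0 && memb[j] == s) kis <- kis + 1
      acc <- acc + (kis / k)^2
    }
    pc[i] <- 1 - acc
  }
  pc
}

oracle_wd <- function(A, memb) {
  n <- nrow(A)
  kappa <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (A[i, j] != 0 && memb[j] == memb[i]) kappa[i] <- kappa[i] + 1
    }
  }
  wd <- numeric(n)
  for (s in unique(memb)) {
    idx <- which(memb == s)
    mu <- mean(kappa[idx])
    sg <- sqrt(mean((kappa[idx] - mu)^2))
    for (i in idx) wd[i] <- if (sg == 0) 0 else (kappa[i] - mu) / sg
  }
  wd
}

# exact permutation p for a Pearson correlation over all n! permutations,
# one-sided in the direction of the observed r
oracle_exact_perm_p <- function(x, y, side = c("one_sided", "two_sided")) {
  side <- match.arg(side)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  r_obs <- cor(x, y)
  rs <- vapply(perms(seq_along(y)), function(p) cor(x, y[p]), numeric(1))
  if (side == "two_sided") {
    mean(abs(rs) >= abs(r_obs) - 1e-12)
  } else if (r_obs >= 0) {
    mean(rs >= r_obs - 1e-12)
  } else {
    mean(rs <= r_obs + 1e-12)
  }
}

# random binary graph + partition fixture
random_graph_case <- function(n, p_edge = 0.4, n_modules = 3) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1, p_edge)
  A <- A + t(A)
  memb <- sample.int(n_modules, n, replace = TRUE)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1
  list(A = A, memb = memb)
}

as_graph <- function(A) binary_graph(A, retained_nodes = seq_len(nrow(A)) - 1L)
as_partition <- function(memb) {
  structure(stats::setNames(as.integer(memb), as.character(seq_along(memb) - 1L)),
            class = "partition")
}

# small default study used by several pipeline tests (cached per session)
small_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- simulate_study(seed = 42)
    st
  }
})
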