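# Independent oracles and small fixture builders. These deliberately use
# naive enumeration/summation, never the package's own code paths.

# HWI by direct counting over event membership sets
oracle_hwi <- function(gbi) {
  n <- ncol(gbi)
  W <- matrix(0, n, n, dimnames = list(colnames(gbi), colnames(gbi)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      x <- 0; ya <- 0; yb <- 0
      for (k in seq_len(nrow(gbi))) {
        ina <- gbi[k, a] == 1
        inb <- gbi[k, b] == 1
        if (ina && inb) x <- x + 1
        else if (ina) ya <- ya + 1
        else if (inb) yb <- yb + 1
      }
      W[a, b] <- if (x + ya + yb > 0) x / (x + (ya + yb) / 2) else 0
    }
  }
  W
}

# weighted discrete assortativity by explicit summation over all dyads
oracle_assort <- function(W, types) {
  types <- as.character(types)
  lv <- sort(unique(types))
  e <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  n <- nrow(W)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      # each ordered pair carries half the undirected dyad's weight
      e[types[a], types[b]] <- e[types[a], types[b]] + W[a, b] / 2
    }
  }
  e <- e / sum(e)
  ai <- rowSums(e)
  (sum(diag(e)) - sum(ai^2)) / (1 - sum(ai^2))
}

# OLS via the normal equations, independent of lm.fit
oracle_ols <- function(y, X) {
  D <- cbind(1, X)
  solve(t(D) %*% D, t(D) %*% y)[, 1]
}

# random symmetric nonnegative weight matrix with zero diagonal
rand_net <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on_edges <- up[runif(length(up)) < density]
  W[on_edges] <- runif(length(on_edges), 0.05, 1)
  W <- W + t(W)
  tags <- sprintf("%05d%d", sample(10000:99999, n), sample(0:9, n, TRUE))
  dimnames(W) <- list(tags, tags)
  W
}

rand_types <- function(n, seed = 1) {
  set.seed(seed)
  factor(sample(c("odd", "even"), n, replace = TRUE, prob = c(0.5, 0.5)),
         levels = c("odd", "even"))
}

# tiny scenario used by pipeline-level unit tests (kept fast)
tiny_config <- function(seed = 1, ...) {
  demo_config(
    rng_seed = seed,
    n_individuals = 40,
    n_sites = 4,
    period_lengths_days = c(4, 8, 3),
    event_rate_per_site_day = 8,
    n_nestboxes = 12,
    ...
  )
}

# exact Mantel permutation p over all n! joint row/column permutations
oracle_mantel_exact_p <- function(m1, m2, two_sided = TRUE) {
  n <- nrow(m1)
  v1 <- m1[lower.tri(m1)]
  r_obs <- cor(v1, m2[lower.tri(m2)])
  perms <- all_permutations(n)
  rs <- apply(perms, 1, function(p) cor(v1, m2[p, p][lower.tri(m2)]))
  if (two_sided) mean(abs(rs) >= abs(r_obs) - 1e-12)
  else mean(rs >= r_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}
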