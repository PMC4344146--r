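# Weighted discrete assortativity by node type. From the mixing matrix e
# (fraction of total edge weight joining type-i to type-j ends, marginals
# a_i), r = (sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2). Perfectly
# segregated networks score 1; a single represented type leaves r
# undefined (returned as NA).

net_parts <- function(net, types) {
  if (inherits(net, "assoc_net")) {
    W <- net$W
    if (is.null(types)) types <- net$node_attrs
  } else {
    W <- net
  }
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (is.null(types)) stop("node types required")
  if (!is.null(names(types)) && !is.null(rownames(W))) {
    types <- types[rownames(W)]
  }
  if (length(types) != nrow(W) || anyNA(types)) {
    stop("every roster member needs a type")
  }
  # strip names so an already-permuted type vector is never re-aligned
  list(W = W, types = factor(unname(types)))
}

#' Mixing matrix of a typed weighted network
#'
#' Each undirected dyad contributes its weight split equally across its two
#' ordered ends, and the matrix is normalised so all entries sum to 1.
#' Marginals `a` are the row sums.
#'
#' @param net an `assoc_net` or symmetric weighted matrix.
#' @param types node types (named by tag id, or in roster order); defaults
#'   to the network's node attributes.
#' @return list with `e` (T x T matrix) and `a` (marginals).
#' @export
mixing_matrix <- function(net, types = NULL) {
  p <- net_parts(net, types)
  S <- 1 * outer(p$types, factor(levels(p$types), levels(p$types)), "==")
  colnames(S) <- levels(p$types)
  M <- t(S) %*% p$W %*% S
  tot <- sum(M)
  if (tot <= 0) stop("zero-weight network")
  e <- M / tot
  list(e = e, a = rowSums(e))
}

#' Weighted discrete assortativity coefficient
#'
#' @inheritParams mixing_matrix
#' @return scalar `r` in `[-1, 1]`, or `NA` when only one type carries
#'   edge weight (the coefficient is undefined there).
#' @examples
#' W <- matrix(0, 4, 4, dimnames = rep(list(c("a1", "a3", "b2", "b4")), 2))
#' W["a1", "a3"] <- W["a3", "a1"] <- 1   # odd-odd
#' W["b2", "b4"] <- W["b4", "b2"] <- 2   # even-even
#' assortativity_weighted(W, tag_parity(rownames(W)))  # 1
#' @export
assortativity_weighted <- function(net, types = NULL) {
  m <- mixing_matrix(net, types)
  s2 <- sum(m$a^2)
  if (isTRUE(all.equal(s2, 1))) return(NA_real_)
  (sum(diag(m$e)) - s2) / (1 - s2)
}

#' Jackknife standard error of the assortativity coefficient
#'
#' Each nonzero dyad's weight is zeroed in turn and the coefficient
#' recomputed; `se^2` is the sum of squared deviations of the
#' leave-one-dyad-out coefficients from the observed one.
#'
#' @inheritParams mixing_matrix
#' @return nonnegative scalar standard error.
#' @export
jackknife_se <- function(net, types = NULL) {
  p <- net_parts(net, types)
  W <- p$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("jackknife needs at least 2 nonzero dyads")
  r_obs <- assortativity_weighted(W, p$types)
  devs <- apply(idx, 1, function(ij) {
    Wm <- W
    Wm[ij[1], ij[2]] <- 0
    Wm[ij[2], ij[1]] <- 0
    rm <- tryCatch(assortativity_weighted(Wm, p$types),
                   error = function(e) NA_real_)
    (rm - r_obs)^2
  })
  sqrt(sum(devs, na.rm = TRUE))
}

#' Assortativity with a node-permutation null distribution
#'
#' Compares the observed weighted assortativity with coefficients from
#' networks whose node types are randomly permuted across nodes
#' (equivalently, jointly shuffling rows and columns), which preserves the
#' association pattern, each node's gregariousness and the distribution of
#' types. The p-value uses the add-one Monte-Carlo estimator
#' `(1 + #extreme) / (1 + n_perm)`, two-tailed on `|r|` by default.
#'
#' @inheritParams mixing_matrix
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"two.sided"` (on `|r|`) or `"greater"`.
#' @return object of class `assort_test`: observed `r`, `se` (jackknife,
#'   `NA` when the network has fewer than 2 edges), null 2.5/97.5
#'   percentiles, `p`, `n_perm`, `n_nodes`, and the vector of permuted
#'   coefficients in `null_r`.
#' @export
node_permutation_null <- function(net, types = NULL, n_perm = 10000,
                                  seed = 1L,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  p <- net_parts(net, types)
  r_obs <- assortativity_weighted(p$W, p$types)
  se <- if (sum(upper.tri(p$W) & p$W > 0) >= 2 && !is.na(r_obs)) {
    jackknife_se(p$W, p$types)
  } else NA_real_
  n <- nrow(p$W)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      assortativity_weighted(p$W, p$types[sample.int(n)])
    }, numeric(1))
  })
  ok <- !is.na(null_r)
  pval <- if (is.na(r_obs)) {
    NA_real_
  } else if (alternative == "two.sided") {
    (1 + sum(abs(null_r[ok]) >= abs(r_obs) - 1e-12)) / (1 + sum(ok))
  } else {
    (1 + sum(null_r[ok] >= r_obs - 1e-12)) / (1 + sum(ok))
  }
  q <- if (any(ok)) {
    quantile(null_r[ok], c(0.025, 0.975), names = FALSE, type = 7)
  } else c(NA_real_, NA_real_)
  structure(
    list(
      r = r_obs, se = se, null_lo = q[1], null_hi = q[2], p = pval,
      n_perm = as.integer(n_perm), n_nodes = n, null_r = null_r,
      alternative = alternative, seed = as.integer(seed)
    ),
    class = "assort_test"
  )
}

#' @export
print.assort_test <- function(x, digits = 3, ...) {
  cat("Weighted assortativity with node-permutation null\n")
  cat(sprintf("  r = %s +/- %s (jackknife), n = %d nodes\n",
              format(x$r, digits = digits), format(x$se, digits = digits),
              x$n_nodes))
  cat(sprintf("  null 95%% range [%s, %s], p = %s (%s, %d permutations)\n",
              format(x$null_lo, digits = digits),
              format(x$null_hi, digits = digits),
              format(x$p, digits = digits), x$alternative, x$n_perm))
  invisible(x)
}

#' @export
summary.assort_test <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
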