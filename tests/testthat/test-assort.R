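two_block_net <- function(w_within = NULL, seed = 1) {
  # 6 nodes, 3 odd / 3 even tags, edges only within parity blocks
  tags <- c("10001", "10003", "10005", "20002", "20004", "20006")
  W <- matrix(0, 6, 6, dimnames = list(tags, tags))
  set.seed(seed)
  w <- if (is.null(w_within)) runif(6, 0.1, 1) else w_within
  W[1, 2] <- W[2, 1] <- w[1]; W[1, 3] <- W[3, 1] <- w[2]
  W[2, 3] <- W[3, 2] <- w[3]
  W[4, 5] <- W[5, 4] <- w[4]; W[4, 6] <- W[6, 4] <- w[5]
  W[5, 6] <- W[6, 5] <- w[6]
  W
}

test_that("mixing matrix splits edge weight across ordered ends", {
  # one odd-even edge: e = [[0, .5], [.5, 0]]
  W <- matrix(0, 2, 2, dimnames = list(c("11", "12"), c("11", "12")))
  W[1, 2] <- W[2, 1] <- 0.7
  m <- mixing_matrix(W, tag_parity(rownames(W)))
  expect_equal(unname(m$e), rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(sum(m$a), 1)

  # two same-type nodes: all weight on the one represented type
  W2 <- matrix(0, 2, 2, dimnames = list(c("11", "13"), c("11", "13")))
  W2[1, 2] <- W2[2, 1] <- 1
  m2 <- mixing_matrix(W2, tag_parity(rownames(W2)))
  expect_equal(m2$e["odd", "odd"], 1)

  # normalisation on random weighted networks
  for (s in 1:20) {
    W <- rand_net(8, seed = s)
    m <- mixing_matrix(W, rand_types(8, seed = s))
    expect_equal(sum(m$e), 1, tolerance = 1e-12)
    expect_equal(m$e, t(m$e), tolerance = 1e-12)
  }

  expect_error(mixing_matrix(matrix(0, 2, 2,
                                    dimnames = list(c("11", "12"),
                                                    c("11", "12"))),
                             tag_parity(c("11", "12"))),
               "zero-weight")
})

test_that("assortativity hits its analytic anchor points", {
  # perfectly segregated network scores exactly 1
  expect_identical(assortativity_weighted(two_block_net(),
                                          tag_parity(rownames(two_block_net()))),
                   1)

  # a single odd-even edge scores -1
  W <- matrix(0, 2, 2, dimnames = list(c("11", "12"), c("11", "12")))
  W[1, 2] <- W[2, 1] <- 0.3
  expect_equal(assortativity_weighted(W, tag_parity(rownames(W))), -1)

  # single represented type: undefined, flagged as NA
  W2 <- matrix(0, 2, 2, dimnames = list(c("11", "13"), c("11", "13")))
  W2[1, 2] <- W2[2, 1] <- 1
  expect_true(is.na(assortativity_weighted(W2, tag_parity(rownames(W2)))))
})

test_that("assortativity matches brute-force summation and classic r", {
  for (s in 1:25) {
    n <- sample(5:10, 1)
    W <- rand_net(n, seed = s)
    ty <- rand_types(n, seed = s + 100)
    if (length(unique(ty)) < 2) next
    r <- assortativity_weighted(W, ty)
    if (is.na(r)) next
    expect_equal(r, oracle_assort(W, ty), tolerance = 1e-12)
    # scale invariance
    expect_equal(assortativity_weighted(3.7 * W, ty), r, tolerance = 1e-12)
  }

  # binary network: agrees with the classic unweighted coefficient
  set.seed(77)
  A <- matrix(rbinom(100, 1, 0.4), 10, 10)
  A <- (A + t(A) > 0) * 1
  diag(A) <- 0
  dimnames(A) <- list(sprintf("n%d", 1:10), sprintf("n%d", 1:10))
  ty <- rand_types(10, seed = 5)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(
    assortativity_weighted(A, ty),
    igraph::assortativity_nominal(g, as.integer(ty)),
    tolerance = 1e-10
  )
})

test_that("jackknife SE matches leave-one-dyad-out enumeration", {
  # 4-edge toy network, enumerated by hand
  tags <- c("11", "13", "12", "14")
  W <- matrix(0, 4, 4, dimnames = list(tags, tags))
  W[1, 2] <- W[2, 1] <- 0.8 # odd-odd
  W[3, 4] <- W[4, 3] <- 0.6 # even-even
  W[1, 3] <- W[3, 1] <- 0.2 # odd-even
  W[2, 4] <- W[4, 2] <- 0.1 # odd-even
  ty <- tag_parity(tags)
  r <- assortativity_weighted(W, ty)
  dyads <- list(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  devs <- vapply(dyads, function(d) {
    Wm <- W
    Wm[d[1], d[2]] <- Wm[d[2], d[1]] <- 0
    (assortativity_weighted(Wm, ty) - r)^2
  }, numeric(1))
  expect_equal(jackknife_se(W, ty), sqrt(sum(devs)), tolerance = 1e-12)
  expect_gte(jackknife_se(W, ty), 0)

  # symmetric all-equal case: every leave-one-out value coincides
  We <- two_block_net(w_within = rep(0.5, 6))
  se <- jackknife_se(We, tag_parity(rownames(We)))
  expect_gte(se, 0)

  W1 <- matrix(0, 2, 2, dimnames = list(tags[1:2], tags[1:2]))
  W1[1, 2] <- W1[2, 1] <- 1
  expect_error(jackknife_se(W1, ty[1:2]), "2 nonzero")
})

test_that("type shuffling is equivalent to joint row/column permutation", {
  set.seed(12)
  W <- rand_net(9, seed = 3)
  ty <- rand_types(9, seed = 4)
  for (i in 1:25) {
    p <- sample.int(9)
    # the permuted network keeps the weight multiset and weighted degrees
    expect_equal(sort(W[p, p][upper.tri(W)]), sort(W[upper.tri(W)]))
    expect_equal(sort(rowSums(W[p, p])), sort(rowSums(W)))
    # relabelling rows/columns by p equals shuffling types by its inverse
    expect_equal(
      assortativity_weighted(W[p, p], unname(ty)),
      assortativity_weighted(W, unname(ty)[order(p)]),
      tolerance = 1e-12
    )
  }
})

test_that("node-permutation null behaves and is reproducible", {
  W <- rand_net(12, seed = 21)
  ty <- rand_types(12, seed = 22)
  a1 <- node_permutation_null(W, ty, n_perm = 200, seed = 9)
  a2 <- node_permutation_null(W, ty, n_perm = 200, seed = 9)
  expect_identical(a1$null_r, a2$null_r)
  expect_true(a1$p > 0 && a1$p <= 1)
  expect_lte(a1$null_lo, a1$null_hi)
  expect_equal(a1$n_nodes, 12)

  # segregated network: observed far above the null. Blocks of 6 so that
  # partition-preserving label permutations are rare in the null.
  set.seed(33)
  tags <- sprintf("3%04d%d", 1:12, rep(c(1, 2), each = 6))
  Wb <- matrix(0, 12, 12, dimnames = list(tags, tags))
  for (blk in list(1:6, 7:12)) {
    for (a in blk) for (b in blk) if (a < b) {
      Wb[a, b] <- Wb[b, a] <- runif(1, 0.1, 1)
    }
  }
  ab <- node_permutation_null(Wb, tag_parity(rownames(Wb)),
                              n_perm = 500, seed = 1)
  expect_equal(ab$r, 1)
  expect_gt(ab$r, ab$null_hi)
  expect_lt(ab$p, 0.05)

  # assoc_net input with stored parity attributes works directly
  net <- assoc_net(Wb)
  expect_equal(node_permutation_null(net, n_perm = 50, seed = 2)$r, 1)
})
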