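# Dyadic matrix comparisons. Statistics are computed on the strictly
# lower triangles of aligned symmetric matrices (diagonal always
# excluded); significance comes from joint row/column permutations, which
# respect the non-independence of dyads sharing an individual.

lower_vec <- function(m) m[lower.tri(m)]

check_square_sym <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(name, " must be square")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop(name, " must be symmetric")
  }
  invisible(m)
}

#' Mantel test with permutation inference and bootstrap CI
#'
#' Correlates the strictly-lower-triangle entries of two aligned symmetric
#' matrices. Significance comes from joint row/column permutations of the
#' second matrix; the 95% range is a percentile interval from
#' bootstrapping individuals (resampling rows/columns jointly; dyads
#' formed by two copies of the same individual are excluded from each
#' bootstrap correlation).
#'
#' @param m1,m2 aligned symmetric matrices (same roster, same order);
#'   `assoc_net` objects are accepted.
#' @param n_perm number of permutations.
#' @param n_boot number of bootstrap resamples (0 skips the CI).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return object of class `mantel_test` with `r`, `p`, `ci_lo`, `ci_hi`,
#'   `n_perm`, `n_boot`, `n_nodes`. `r` is `NA` when either triangle has
#'   zero variance.
#' @export
mantel_test <- function(m1, m2, n_perm = 10000, n_boot = 1000, seed = 1L,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(m1, "assoc_net")) m1 <- m1$W
  if (inherits(m2, "assoc_net")) m2 <- m2$W
  check_square_sym(m1, "m1"); check_square_sym(m2, "m2")
  n <- nrow(m1)
  if (n != nrow(m2)) stop("matrices must be aligned")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share the same roster order")
  }
  if (n < 3) stop("need n >= 3")
  v1 <- lower_vec(m1)
  v2 <- lower_vec(m2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    return(structure(
      list(r = NA_real_, p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
           n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
           n_nodes = n, seed = as.integer(seed)),
      class = "mantel_test"
    ))
  }
  r <- cor(v1, v2)
  res <- with_seed(seed, {
    null_r <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      cor(v1, lower_vec(m2[idx, idx]))
    }, numeric(1))
    boot_r <- if (n_boot > 0) {
      lowmask <- lower.tri(m1)
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, replace = TRUE)
        keep <- lowmask & (outer(idx, idx, "!=")) # drop self-self dyads
        b1 <- m1[idx, idx][keep]
        b2 <- m2[idx, idx][keep]
        if (length(b1) < 3 || sd(b1) == 0 || sd(b2) == 0) return(NA_real_)
        cor(b1, b2)
      }, numeric(1))
    } else numeric()
    list(null_r = null_r, boot_r = boot_r)
  })
  pval <- if (alternative == "two.sided") {
    (1 + sum(abs(res$null_r) >= abs(r) - 1e-12)) / (1 + n_perm)
  } else {
    (1 + sum(res$null_r >= r - 1e-12)) / (1 + n_perm)
  }
  ci <- if (length(res$boot_r) && any(!is.na(res$boot_r))) {
    quantile(res$boot_r, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(
    list(r = r, p = pval, ci_lo = ci[1], ci_hi = ci[2],
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         n_nodes = n, alternative = alternative, seed = as.integer(seed)),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, digits = 3, ...) {
  cat("Mantel matrix correlation\n")
  cat(sprintf("  r = %s (95%% range %s - %s), p = %s, n = %d nodes\n",
              format(x$r, digits = digits), format(x$ci_lo, digits = digits),
              format(x$ci_hi, digits = digits), format(x$p, digits = digits),
              x$n_nodes))
  invisible(x)
}

#' Multiple regression QAP with double semi-partialing
#'
#' Regresses the lower triangle of a dependent matrix on those of one or
#' more predictor matrices by OLS (intercept included; coefficients
#' reported unstandardised). Per-predictor significance follows the double
#' semi-partialing scheme: each predictor is residualised on the remaining
#' predictors, the residual *matrix* is jointly row/column permuted, the
#' full model is refitted with the permuted residual in that predictor's
#' place, and the refitted coefficient forms the null; the p-value is the
#' add-one two-tailed proportion.
#'
#' @param dep dependent symmetric matrix (or `assoc_net`).
#' @param predictors named list of aligned symmetric predictor matrices.
#' @param n_perm permutations per predictor.
#' @param seed integer seed.
#' @return object of class `mrqap_dsp` with `coefficients` (incl.
#'   intercept), `p_dsp` per predictor, `F_full`, `r2_full`, `n_perm`,
#'   `n_nodes`.
#' @export
mrqap_dsp <- function(dep, predictors, n_perm = 10000, seed = 1L) {
  if (inherits(dep, "assoc_net")) dep <- dep$W
  predictors <- lapply(predictors, function(m) {
    if (inherits(m, "assoc_net")) m$W else m
  })
  if (length(predictors) < 1) stop("need at least one predictor")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  check_square_sym(dep, "dep")
  n <- nrow(dep)
  if (n < 4) stop("need n >= 4")
  for (nm in names(predictors)) {
    check_square_sym(predictors[[nm]], nm)
    if (nrow(predictors[[nm]]) != n) stop(nm, " is not aligned with dep")
  }
  y <- lower_vec(dep)
  X <- vapply(predictors, lower_vec, numeric(length(y)))
  k <- ncol(X)
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- setdiff(colnames(D), colnames(D)[qrD$pivot[seq_len(qrD$rank)]])
    stop("collinear predictor(s): ", paste(bad, collapse = ", "))
  }
  fit <- lm.fit(D, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  dfree <- length(y) - k - 1
  Fstat <- (r2 / k) / ((1 - r2) / dfree)

  lowmask <- lower.tri(dep)
  p_dsp <- numeric(k)
  names(p_dsp) <- names(predictors)
  for (j in seq_len(k)) {
    others <- D[, -(j + 1), drop = FALSE]
    gfit <- lm.fit(others, X[, j])
    E <- matrix(0, n, n)
    E[lowmask] <- gfit$residuals
    E <- E + t(E)
    beta_null <- with_seed(as.integer(seed) + 997L * j, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        Dp <- D
        Dp[, j + 1] <- E[idx, idx][lowmask]
        lm.fit(Dp, y)$coefficients[j + 1]
      }, numeric(1))
    })
    p_dsp[j] <- (1 + sum(abs(beta_null) >= abs(beta[j + 1]) - 1e-12)) /
      (1 + n_perm)
  }
  structure(
    list(coefficients = beta, p_dsp = p_dsp, F_full = Fstat, r2_full = r2,
         n_perm = as.integer(n_perm), n_nodes = n, n_dyads = length(y),
         seed = as.integer(seed)),
    class = "mrqap_dsp"
  )
}

#' @export
coef.mrqap_dsp <- function(object, ...) object$coefficients

#' @export
print.mrqap_dsp <- function(x, digits = 3, ...) {
  cat("MRQAP with double semi-partialing\n")
  est <- x$coefficients[-1]
  tab <- data.frame(
    estimate = signif(est, digits),
    p_dsp = signif(x$p_dsp, digits)
  )
  print(tab)
  cat(sprintf("  F = %s, R^2 = %s, %d nodes (%d dyads), %d permutations\n",
              format(x$F_full, digits = digits),
              format(x$r2_full, digits = digits),
              x$n_nodes, x$n_dyads, x$n_perm))
  invisible(x)
}

#' @export
summary.mrqap_dsp <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
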