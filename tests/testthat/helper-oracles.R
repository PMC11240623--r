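# Independent oracles used by the tests.  These deliberately avoid the
# package's computational paths (recurrences, eigen-rotated REML,
# residualized scans) and recompute the same quantities from first
# principles.

# Exact HWE p-value by direct enumeration of heterozygote counts from
# log-factorials (no recurrence).
hwe_enum_oracle <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0) return(1)
  hets <- seq.int(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Dense restricted log-likelihood for the two-component animal model,
# computed with solve()/determinant() rather than an eigendecomposition.
reml_ll_dense <- function(theta, y, X, G) {
  n <- length(y)
  V <- theta[1] * G + diag(theta[2], n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  B <- crossprod(X, Vi %*% X)
  cb <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cb)) return(-Inf)
  beta <- solve(B, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  quad <- drop(crossprod(r, Vi %*% r))
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cb))) + quad)
}

# Brute-force REML optimum: coarse 2-D grid followed by alternating
# golden-section refinement of each coordinate.
reml_grid_oracle <- function(y, X, G, rounds = 60) {
  vp <- stats::var(y)
  grid <- exp(seq(log(vp * 1e-4), log(vp * 4), length.out = 25))
  best <- c(vp / 2, vp / 2)
  best_ll <- reml_ll_dense(best, y, X, G)
  for (a in grid) for (e in grid) {
    ll <- reml_ll_dense(c(a, e), y, X, G)
    if (ll > best_ll) { best <- c(a, e); best_ll <- ll }
  }
  lo <- vp * 1e-9; hi <- vp * 10
  for (r in seq_len(rounds)) {
    o1 <- stats::optimize(function(a) reml_ll_dense(c(a, best[2]), y, X, G),
                          c(lo, hi), maximum = TRUE, tol = 1e-12)
    best[1] <- o1$maximum
    o2 <- stats::optimize(function(e) reml_ll_dense(c(best[1], e), y, X, G),
                          c(lo, hi), maximum = TRUE, tol = 1e-12)
    best[2] <- o2$maximum
  }
  list(theta = best, loglik = reml_ll_dense(best, y, X, G))
}

# Closed-form OLS slope t-test of y on [1, x], textbook formulas.
ols_t_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  list(b = b, se = se, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# Textbook two-pass VanRaden computation: explicit Z, explicit loops
# absent but a separate code path from the package's sweep/tcrossprod.
vanraden_oracle <- function(dos) {
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  Z <- dos
  for (j in seq_len(ncol(dos))) Z[, j] <- dos[, j] - 2 * p[j]
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  (Z %*% t(Z)) / denom
}
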