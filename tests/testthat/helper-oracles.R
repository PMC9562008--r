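# Independent oracles, kept deliberately separate from the package code
# paths they check.

# Exact bias-corrected percentile interval for the mean of n values:
# enumerates all n^n equiprobable resamples, applies the BC level shift
# analytically, and reads type-1 quantiles off the exact atom distribution.
exact_bc_ci <- function(v, conf_level = 0.95) {
  n <- length(v)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  means <- rowMeans(matrix(v[grid], nrow = nrow(grid)))
  theta <- mean(v)
  tol <- 1e-9 * max(1, abs(theta))
  k <- length(means)
  p0 <- (sum(means < theta - tol) + 0.5 * sum(abs(means - theta) <= tol)) / k
  p0 <- min(max(p0, 1 / (2 * k)), 1 - 1 / (2 * k))
  z0 <- qnorm(p0)
  a <- 1 - conf_level
  lev <- pnorm(2 * z0 + qnorm(c(a / 2, 1 - a / 2)))
  s <- sort(means)
  q1 <- function(p) s[min(k, max(1L, ceiling(p * k)))]
  c(q1(lev[1]), q1(lev[2]))
}

# Exhaustive hypergeometric enumeration of the two-tailed Fisher p-value.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  p <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(p[p <= p_obs * (1 + 1e-7)])
}
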