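# shared independent oracles and small utilities for the test suite

# standard-normal quantile by numeric inversion of the distribution function
# (independent of qnorm)
inv_norm <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) stats::pnorm(z) - pp,
                   interval = c(-40, 40), tol = 1e-13)$root,
    numeric(1))
}

# two-sided tail probability P(|r| > r0) for a sample Pearson correlation of
# two independent normal variables, via the exact t transform
pearson_tail <- function(r0, n) {
  tt <- r0 * sqrt((n - 2) / (1 - r0^2))
  2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

# adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# textbook two-pass Pearson correlation
pearson_twopass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# closed-form OLS via the normal equations
ols_normal_equations <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}
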