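# Independent oracles, kept deliberately naive.

# O(n^2) double-sum definition of the per-person deprivation index
rd_bruteforce <- function(y) {
  n <- length(y)
  mu <- mean(y)
  vapply(y, function(yi) sum(pmax(y - yi, 0)) / (n * mu), numeric(1))
}

# pairwise-difference definition of the Gini coefficient
gini_bruteforce <- function(y) {
  n <- length(y)
  sum(abs(outer(y, y, "-"))) / (2 * n^2 * mean(y))
}

# normal-equations OLS on the standardized design, matching rd_lm's scale
ols_oracle <- function(y, X) {
  Z <- scale(X)
  yz <- (y - mean(y)) / sd(y)
  A <- cbind(1, Z)
  solve(crossprod(A), crossprod(A, yz))[-1, 1]
}

# small cohort used across tests
tiny_cohort <- function(n = 400, seed = 42, ...) {
  generate_cohort(synth_config(n = n, seed = seed, ...))
}
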