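# Shared fixtures and independent oracles, built in code.

# Random but physiologically plausible panels.
random_panels <- function(n, seed, with_direct = FALSE) {
  set.seed(seed)
  df <- data.frame(
    tc = runif(n, 120, 300),
    hdl = runif(n, 30, 80),
    tg = runif(n, 1, 399)
  )
  if (with_direct) {
    vldl <- runif(n, 2, 60)
    df$ldl_direct <- pmax(1, df$tc - df$hdl - vldl)
  }
  lipid_cohort(df)
}

# Brute-force exact signed-rank p-value: enumerate all 2^n sign vectors of
# the midranks of |d| and tabulate the positive rank sum.
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  sp <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  sps <- signs %*% r
  p_le <- mean(sps <= sp + 1e-9)
  p_ge <- mean(sps >= sp - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exact McNemar p by direct binomial enumeration with choose().
mcnemar_enum_oracle <- function(n01, n10) {
  n <- n01 + n10
  k <- min(n01, n10)
  min(1, 2 * sum(choose(n, 0:k)) / 2^n)
}
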