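# Shared fixtures and independent oracles used across the suite.

# a valid animals-by-analytes matrix with positive values
makeValues <- function(n = 6L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rlnorm(n * 17L, meanlog = 1, sdlog = 0.4), nrow = n)
  colnames(m) <- panelNames()
  m
}

makeCohort <- function(n = 6L, seed = 1L, stressor = "control",
                       state = "NP") {
  cohortExperiment(makeValues(n, seed), stressor, state)
}

# exact permutation p-value for |r| by full enumeration of permutations of y
permPearsonExact <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  robs <- abs(cor(x, y))
  rs <- vapply(perms(y), function(p) abs(cor(x, p)), numeric(1L))
  mean(rs >= robs - 1e-12)
}

# Monte-Carlo permutation p-value for |r|
permPearsonMC <- function(x, y, draws = 100000L, seed = 1L) {
  set.seed(seed)
  robs <- abs(cor(x, y))
  rs <- replicate(draws, abs(cor(x, sample(y))))
  list(p = mean(rs >= robs - 1e-12),
       se = sqrt(mean(rs >= robs - 1e-12) *
                   (1 - mean(rs >= robs - 1e-12)) / draws))
}

# brute-force exact two-sided signed-rank p by explicit enumeration of all
# 2^n sign assignments (midranks for ties, zeros dropped) -- independent of
# the package's convolution
bruteWilcoxP <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1L, n <= 14L)
  rk <- rank(abs(d))
  wObs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% rk)
  pLe <- mean(ws <= wObs + 1e-9)
  pGe <- mean(ws >= wObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# Type II sums of squares by nested-model residual-SS differences
nestedTypeII <- function(values, f1, f2) {
  rss <- function(form) sum(residuals(lm(form))^2)
  full <- rss(values ~ f1 * f2)
  both <- rss(values ~ f1 + f2)
  c(f1 = rss(values ~ f2) - both,
    f2 = rss(values ~ f1) - both,
    interaction = both - full,
    residual = full)
}
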