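# Wilcoxon signed-rank, two-way Type II ANOVA, Tukey-Kramer.

test_that("wilcoxon handles degenerate and extreme cases exactly", {
  expect_warning(res <- wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3)),
                 "zero")
  expect_equal(res@p, 1)
  expect_equal(res@nEffective, 0L)

  res <- wilcoxonSignedRank(1:6, rep(0, 6))
  expect_equal(res@p, 2 / 64)
  expect_equal(res@method, "exact")
  expect_equal(res@statistic, 0)          # smaller one-sided rank sum
  expect_equal(res@nEffective, 6L)

  expect_error(wilcoxonSignedRank(1:5, 1:4), "equal length")
})

test_that("exact p equals brute-force sign-assignment enumeration", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(4:12, 1L)
    a <- round(rnorm(n), 1)               # rounding induces ties and zeros
    b <- round(rnorm(n), 1)
    if (all(a == b)) next
    res <- suppressWarnings(wilcoxonSignedRank(a, b))
    expect_equal(res@p, bruteWilcoxP(a, b), tolerance = 1e-12,
                 label = sprintf("draw %d", i))
  }
})

test_that("exact p matches the reference distribution for tie-free data", {
  set.seed(7)
  for (n in c(8, 14, 20)) {
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxonSignedRank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine@p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact p is invariant under common positive rescaling", {
  set.seed(10)
  a <- rnorm(12); b <- rnorm(12)
  p1 <- wilcoxonSignedRank(a, b)@p
  p2 <- wilcoxonSignedRank(100 * a, 100 * b)@p
  expect_equal(p1, p2)
})

test_that("normal approximation is close to exact at its boundary", {
  set.seed(8)
  diffs <- replicate(40, {
    n <- sample(15:20, 1L)
    a <- rnorm(n); b <- rnorm(n)
    abs(wilcoxonSignedRank(a, b)@p -
          wilcoxonSignedRank(a, b, exactLimit = 0L)@p)
  })
  expect_lt(max(diffs), 0.015)
  set.seed(9)
  a <- rnorm(25); b <- rnorm(25)
  expect_lt(abs(wilcoxonSignedRank(a, b, exactLimit = 25L)@p -
                  wilcoxonSignedRank(a, b)@p), 0.01)
})

test_that("compareNetworkParams pairs by analyte name", {
  sig <- setNames(runif(17, 4, 11), panelNames())
  expect_warning(res <- compareNetworkParams(sig, sig), "zero")
  expect_equal(res@p, 1)

  b <- sig; b["TRP"] <- b["TRP"] + 1
  res <- suppressWarnings(compareNetworkParams(sig, b))
  expect_equal(res@nEffective, 1L)
  expect_equal(res@p, 1)                  # 2^1 enumeration cannot reject

  expect_error(compareNetworkParams(sig, unname(b)), "named")
  names(b)[1L] <- "FOO"
  expect_error(compareNetworkParams(sig, b), "same analytes")

  # published control vs hypoxia hub columns differ significantly
  a <- referenceHubColumn("OGDHC", "control", "NP")
  h <- referenceHubColumn("OGDHC", "hypoxia", "NP")
  res <- compareNetworkParams(a, h)
  expect_equal(res@method, "exact")
  expect_lt(res@p, 0.05)
})

test_that("balanced two-way ANOVA matches the closed-form decomposition", {
  # 2x2, 3 replicates per cell, zero noise: SS from cell means directly
  f1 <- factor(rep(c("a", "b"), each = 6))
  f2 <- factor(rep(rep(c("x", "y"), each = 3), 2))
  mu <- c(ax = 1, ay = 3, bx = 2, by = 6)
  y <- mu[paste0(f1, f2)]
  tab <- twoWayAnova(y, f1, f2)
  # main effects: 12 * (marginal mean deviations)^2; interaction remainder
  g <- mean(mu)
  ssA <- 12 * sum((tapply(y, f1, mean) - g)^2) / 2
  ssB <- 12 * sum((tapply(y, f2, mean) - g)^2) / 2
  ssTot <- sum((y - g)^2)
  expect_equal(tab$ss[tab$effect == "stressor"], ssA)
  expect_equal(tab$ss[tab$effect == "pregnancy"], ssB)
  expect_equal(tab$ss[tab$effect == "interaction"], ssTot - ssA - ssB)
  expect_equal(tab$ss[tab$effect == "residual"], 0)
})

test_that("Type II SS equals the nested-model residual-SS oracle", {
  set.seed(33)
  for (i in 1:5) {
    n <- c(8, 17, 13, 8, 10, 11)          # unbalanced 2x3
    f1 <- factor(rep(c("control", "SP", "hypoxia"), times = c(25, 24, 18)))
    f2 <- factor(rep(rep(c("NP", "P"), 3), times = n))
    y <- rnorm(sum(n)) + as.numeric(f1) + 0.5 * as.numeric(f2)
    tab <- twoWayAnova(y, f1, f2)
    oracle <- nestedTypeII(y, f1, f2)
    expect_equal(tab$ss, unname(oracle), tolerance = 1e-8)
  }
})

test_that("constant responses give F = 0 and empty cells error", {
  f1 <- factor(rep(c("a", "b"), each = 4))
  f2 <- factor(rep(c("x", "y"), 4))
  tab <- twoWayAnova(rep(5, 8), f1, f2)
  expect_equal(tab$F[1:3], rep(0, 3))
  expect_equal(tab$p[1:3], rep(1, 3))

  f2bad <- factor(c(rep("x", 4), rep("y", 4)))
  expect_error(twoWayAnova(rnorm(8), f1, f2bad), "empty")
  expect_error(twoWayAnova(rnorm(8), factor(rep("a", 8)), f2), "two levels")
})

test_that("tukeyHsd reduces to sqrt(2)*|t| for two groups", {
  set.seed(12)
  y <- c(rnorm(8), rnorm(9, 1))
  g <- factor(rep(c("a", "b"), c(8, 9)))
  res <- tukeyHsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$q, sqrt(2) * abs(tt$statistic), ignore_attr = TRUE)
  expect_equal(res$pAdj, tt$p.value, tolerance = 1e-9)
})

test_that("tukeyHsd agrees with the stats reference implementation", {
  set.seed(13)
  y <- rnorm(40) + rep(c(0, 0.5, 2, 0), c(10, 12, 8, 10))
  g <- factor(rep(c("a", "b", "c", "d"), c(10, 12, 8, 10)))
  mine <- tukeyHsd(y, g)
  ref <- TukeyHSD(aov(y ~ g))$g
  key <- paste(mine$group2, mine$group1, sep = "-")
  expect_equal(mine$diff, ref[key, "diff"], ignore_attr = TRUE)
  expect_equal(mine$pAdj, ref[key, "p adj"], ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("tukey flags only the displaced group and respects monotonicity", {
  set.seed(14)
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  g <- factor(rep(c("a", "b", "c"), each = 10))
  res <- tukeyHsd(y, g)
  hit <- res$pAdj < 0.05
  expect_equal(hit, grepl("c", paste(res$group1, res$group2)))
  # adjusted p never below the unadjusted pairwise t-test p
  for (i in seq_len(nrow(res))) {
    sel <- g %in% c(res$group1[i], res$group2[i])
    pT <- t.test(y[sel] ~ droplevels(g[sel]), var.equal = TRUE)$p.value
    expect_gte(res$pAdj[i] + 1e-12, pT * 0.999)
  }
  expect_error(tukeyHsd(y, factor(rep("a", 30))), "two groups")
  expect_error(tukeyHsd(c(y, 1), factor(c(as.character(g), "d"))),
               "two observations")
})
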