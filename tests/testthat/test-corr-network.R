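# Pearson networks and interdependence statistics.

test_that("pearsonTest matches hand values and the t-based reference", {
  expect_equal(pearsonTest(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))$r, 1)
  res <- pearsonTest(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  ref <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(pearsonTest(x, y)$p, cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("pearsonTest rejects degenerate input and never returns p = 0", {
  expect_error(pearsonTest(rep(2, 5), 1:5), "constant")
  expect_error(pearsonTest(1:5, 1:4), "equal length")
  p <- pearsonTest(1:6, (1:6) * 3 + 1)$p
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("analytic p is close to a full permutation enumeration at n = 4-5", {
  # the t-based p is unconditional; the enumeration p conditions on the
  # sample, so agreement is approximate at tiny n
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  pPerm <- permPearsonExact(x, y)
  expect_equal(pPerm, 1 / 3)
  expect_lt(abs(pearsonTest(x, y)$p - pPerm), 0.15)
  set.seed(3)
  x <- rnorm(5); y <- rnorm(5)
  expect_lt(abs(pearsonTest(x, y)$p - permPearsonExact(x, y)), 0.1)
})

test_that("analytic p tracks a Monte-Carlo permutation oracle at n = 10", {
  set.seed(14)
  x <- rnorm(10); y <- rnorm(10)
  mc <- permPearsonMC(x, y, draws = 20000L, seed = 15L)
  # dominated by the conditional-vs-unconditional gap, a few percent at most
  expect_lt(abs(pearsonTest(x, y)$p - mc$p), 0.05)
})

test_that("buildNetwork populates all 136 pairs symmetrically", {
  net <- buildNetwork(makeCohort(5L, seed = 2L))
  r <- networkR(net); p <- networkP(net)
  off <- row(r) != col(r)
  expect_equal(sum(!is.na(r[off])), 272L)      # 136 pairs, both triangles
  expect_true(all(is.na(diag(r))))
  expect_equal(r, t(r))
  expect_equal(p, t(p))
  expect_true(all(p[off] > 0 & p[off] <= 1))
  expect_equal(networkN(net), 5L)
  expect_equal(networkGroup(net), "control.NP")
})

test_that("proportional columns correlate perfectly; constants error", {
  v <- makeValues(6L, seed = 4L)
  v[, "GLY"] <- 2.5 * v[, "ALA"]
  net <- buildNetwork(cohortExperiment(v, "control", "NP"))
  expect_equal(networkR(net)["ALA", "GLY"], 1)
  v[, "MET"] <- 3
  expect_error(buildNetwork(cohortExperiment(v, "control", "NP")), "MET")
  expect_error(buildNetwork(makeCohort(3L)), "4 animals")
})

test_that("network recovers a prescribed correlation within sampling error", {
  tc <- diag(17)
  dimnames(tc) <- list(panelNames(), panelNames())
  tc["ALA", "GLY"] <- tc["GLY", "ALA"] <- 0.9
  spec <- syntheticSpec(mean = 100, sd = 3, targetCorr = tc,
                        nAnimals = 2000L, seed = 31L, family = "normal")
  net <- buildNetwork(generateCohort(spec))
  expect_gt(networkR(net)["ALA", "GLY"], 0.85)   # Fisher-z interval
  expect_lt(networkR(net)["ALA", "GLY"], 0.95)
})

test_that("analyteSummary splits significant and trend counts by sign", {
  r <- matrix(0, 17, 17, dimnames = list(panelNames(), panelNames()))
  p <- matrix(1, 17, 17, dimnames = list(panelNames(), panelNames()))
  r["OGDHC", -1L] <- c(rep(-0.9, 10), rep(0.5, 3), rep(-0.4, 2), 0.3)
  p["OGDHC", -1L] <- c(rep(0.001, 10), rep(0.04, 3), rep(0.07, 2), 0.5)
  r[, "OGDHC"] <- r["OGDHC", ]; p[, "OGDHC"] <- p["OGDHC", ]
  net <- correlationNetwork(r, p, n = 8L)
  s <- analyteSummary(net, "OGDHC")
  expect_equal(s$sigma, 10 * 0.9 + 3 * 0.5 + 2 * 0.4 + 0.3)
  expect_equal(s$meanAbs * 16, s$sigma)
  expect_equal(s$nNeg, 10L)
  expect_equal(s$nPos, 3L)
  expect_equal(s$nNegTrend, 2L)
  expect_equal(s$nPosTrend, 0L)
  expect_error(analyteSummary(net, "FOO"), "unknown analyte")
})

test_that("null networks give zero summaries and forced cases match", {
  r <- matrix(0, 17, 17, dimnames = list(panelNames(), panelNames()))
  p <- matrix(1, 17, 17, dimnames = list(panelNames(), panelNames()))
  net <- correlationNetwork(r, p, n = 8L)
  ns <- networkSummary(net)
  tot <- summaryTotals(ns)
  expect_equal(tot$totalSigma, 0)
  expect_equal(tot$totalPos + tot$totalNeg, 0L)

  r[] <- -0.9; diag(r) <- NA
  p[] <- 0.001; diag(p) <- NA
  s <- analyteSummary(correlationNetwork(r, p, n = 8L), "GLU")
  expect_equal(s$sigma, 14.4)
  expect_equal(s$nNeg, 16L)
  expect_equal(s$nPos, 0L)
})

test_that("network summary totals count each significant pair twice", {
  net <- buildNetwork(makeCohort(8L, seed = 11L))
  ns <- networkSummary(net)
  tot <- summaryTotals(ns)
  expect_equal(tot$totalPos %% 2L, 0L)
  expect_equal(tot$totalNeg %% 2L, 0L)
  pa <- perAnalyte(ns)
  expect_equal(sum(pa$sigma), tot$totalSigma)
  expect_equal(tot$networkMean * 17 * 16, tot$totalSigma)
  # totals equal direct pair counting from the matrices
  p <- networkP(net); r <- networkR(net)
  up <- upper.tri(p)
  expect_equal(tot$totalPos, 2L * sum(p[up] <= 0.05 & r[up] > 0))
  expect_equal(tot$totalNeg, 2L * sum(p[up] <= 0.05 & r[up] < 0))
})

test_that("hub profiles preserve sign and are permutation invariant", {
  v <- runif(16, -1, 1)
  expect_equal(signedSum(hubProfile(v)), sum(v))
  expect_equal(signedSum(hubProfile(sample(v))), sum(v))
  expect_equal(signedSum(hubProfile(rep(0, 16))), 0)
  expect_error(hubProfile(c(rep(0, 15), 1.2)), "\\[-1, 1\\]")
  expect_error(hubProfile(rep(0.5, 15)), "length 16")
})

test_that("hubReport renders hub columns with their algebraic sums", {
  nets <- list(
    control.NP = networkFromHubColumn(
      "OGDHC", referenceHubColumn("OGDHC", "control", "NP"),
      group = "control.NP"),
    SP.NP = networkFromHubColumn(
      "OGDHC", referenceHubColumn("OGDHC", "SP", "NP"), group = "SP.NP"))
  rep1 <- hubReport(nets, hubs = "OGDHC")
  expect_equal(nrow(rep1), 17L)
  expect_equal(rep1$partner[1L], "TRP")
  expect_equal(rep1$partner[17L], "Sum")
  rounded <- formatHubReport(rep1)
  expect_equal(rounded[17L, "OGDHC.control.NP"], -1.24)
  expect_equal(rounded[17L, "OGDHC.SP.NP"], -5.58)

  expect_warning(r2 <- hubReport(nets, hubs = "OGDHC",
                                 groups = c("control.NP", "hypoxia.NP")),
                 "hypoxia.NP")
  expect_equal(ncol(r2), 2L)
  expect_error(hubReport(nets, hubs = character()), "non-empty")
})

test_that("two-hub reports share rows via the companion-hub convention", {
  r <- matrix(0.2, 17, 17, dimnames = list(panelNames(), panelNames()))
  p <- matrix(0.5, 17, 17, dimnames = list(panelNames(), panelNames()))
  net <- correlationNetwork(r, p, n = 10L, group = "control.NP")
  rep2 <- hubReport(list(control.NP = net))
  expect_equal(rep2$partner[1L], "TRP or OGDHC")
  expect_equal(ncol(rep2), 3L)
  expect_equal(rep2[17L, 2L], 16 * 0.2)
})
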