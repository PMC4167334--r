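test_that("median-of-ratios size factors behave on constructed matrices", {
  k <- matrix(rpois(200, 50) + 1, 50, 4)
  same <- k[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(medianOfRatios(same)), rep(1, 3))

  two <- cbind(s1 = k[, 1], s2 = 3L * k[, 1])
  sf <- medianOfRatios(two)
  expect_equal(unname(sf[2] / sf[1]), 3)
  expect_equal(unname(sf), c(1 / sqrt(3), sqrt(3)))

  # scale equivariance: scaling one column by c scales its factor by c
  # relative to the rest (geometric-mean renormalization spreads c^(1/n))
  sf0 <- medianOfRatios(k)
  k2 <- k
  k2[, 2] <- k[, 2] * 5L
  sf2 <- medianOfRatios(k2)
  expect_equal(unname(sf2[2] / sf2[1]), unname(5 * sf0[2] / sf0[1]),
               tolerance = 1e-12)

  zeros <- matrix(c(0L, 5L, 3L, 0L), 2, 2)
  expect_error(medianOfRatios(zeros), "no gene has positive counts")
})

test_that("blind dispersion: zero for constant counts, near zero for Poisson", {
  const <- matrix(7L, 40, 5, dimnames = list(paste0("g", 1:40), NULL))
  fit <- estimateDispersionBlind(const, sizeFactors = rep(1, 5))
  expect_true(all(fit@perGeneAlpha == 0))

  withr::with_seed(13, {
    mu <- 2^runif(4000, 5, 12)
    k <- matrix(rpois(4000 * 5, rep(mu, 5)), 4000, 5,
                dimnames = list(paste0("g", 1:4000), NULL))
  })
  fitP <- estimateDispersionBlind(k, sizeFactors = rep(1, 5))
  expect_true(all(dispersionAt(fitP, c(100, 1000, 1e5)) <= 0.01))
})

test_that("blind dispersion recovers planted (a0, a1) within 50%", {
  cfg <- simulationConfig(nGenes = 5000, archetypeMix = c(null_flat = 1),
                          baselineLog2Range = c(4, 12), seed = 7)
  fit <- estimateDispersionBlind(counts(simulateTimecourse(cfg)))
  expect_false(fit@fitFallback)
  expect_gt(fit@fitParams[1], 0.01)
  expect_lt(fit@fitParams[1], 0.03)
  expect_gt(fit@fitParams[2], 1)
  expect_lt(fit@fitParams[2], 3)
})

test_that("exact NB test matches enumeration and is symmetric", {
  # hand-sized example: 0 vs 10 at constant dispersion 0.1
  expect_equal(nbExactTest(0, 10, 1, 1, fit = 0.1),
               oracleNbExact(0, 10, 1, 1, 0.1), tolerance = 1e-12)
  # symmetric split has p = 1
  expect_equal(nbExactTest(12, 12, 1, 1, fit = 0.05), 1)
  # swapping the libraries leaves p unchanged
  p1 <- nbExactTest(3, 19, 0.8, 1.3, fit = 0.07)
  p2 <- nbExactTest(19, 3, 1.3, 0.8, fit = 0.07)
  expect_equal(p1, p2, tolerance = 1e-12)
  # double zero is 1 by convention
  expect_equal(nbExactTest(0, 0, 1, 2, fit = 0.1), 1)
  # Poisson limit (alpha = 0)
  expect_equal(nbExactTest(2, 9, 1, 1, fit = 0),
               oracleNbExact(2, 9, 1, 1, 0), tolerance = 1e-12)
})

test_that("exact NB test agrees with enumeration across totals and size factors", {
  cases <- expand.grid(total = c(1, 2, 3, 7, 20, 51, 120, 200),
                       frac = c(0, 0.33, 0.5),
                       alpha = c(0.02, 0.3),
                       sB = c(1, 2.5))
  for (i in seq_len(nrow(cases))) {
    kA <- round(cases$total[i] * cases$frac[i])
    kB <- cases$total[i] - kA
    p <- nbExactTest(kA, kB, 1, cases$sB[i], fit = cases$alpha[i])
    po <- oracleNbExact(kA, kB, 1, cases$sB[i], cases$alpha[i])
    expect_equal(p, po, tolerance = 1e-10)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("null p-values are stochastically no smaller than uniform", {
  tce <- allNullScenario(seed = 3, nGenes = 10000)
  k <- counts(tce)
  sf <- medianOfRatios(k)
  fit <- estimateDispersionBlind(k, sf)
  p <- nbExactTest(k[, 1], k[, 4], sf[1], sf[4], fit)
  expect_lte(mean(p <= 0.05), 0.06)
})

test_that("BH adjustment reproduces hand calculations and is order-invariant", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.123), 0.123)
  withr::with_seed(8, {
    p <- runif(50)
    perm <- sample(50)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_true(all(bhAdjust(p) >= p))
  })
})

test_that("VST matches quadrature of the variance function and stabilizes SD", {
  a0 <- 0.02; a1 <- 2
  vfun <- function(m) (1 + a1) * m + a0 * m^2
  shift <- log2((1 + a1) / (4 * a0))
  for (mu in c(1, 10, 147, 1e3, 3e4, 1e6)) {
    quad <- integrate(function(t) 1 / sqrt(vfun(t)), 0, mu,
                      rel.tol = 1e-12)$value
    oracle <- quad * sqrt(a0) / log(2) + shift
    expect_equal(vstClosedForm(mu, a0, a1), oracle, tolerance = 1e-6)
  }
  # closed-form spot value: raw transform at a0 = 0.1, a1 = 0, mu = 10
  v10 <- vstClosedForm(10, 0.1, 0)
  raw <- (v10 - log2(1 / (4 * 0.1))) * log(2) / sqrt(0.1)
  expect_equal(raw, 2 / sqrt(0.1) * asinh(1), tolerance = 1e-12)
  expect_equal(raw, 5.5745, tolerance = 1e-4)

  # monotone in counts within a sample
  x <- vstClosedForm(0:500, a0, a1)
  expect_true(all(diff(x) > 0))

  # replicate-count SD varies < 20% across means 2^4..2^14
  withr::with_seed(42, {
    sds <- sapply(4:14, function(e) {
      mu <- 2^e
      k <- rnbinom(4000, mu = mu, size = mu / (a1 + a0 * mu))
      sd(vstClosedForm(k, a0, a1))
    })
  })
  expect_lt(max(sds) / min(sds), 1.2)

  # Poisson limit message and form
  expect_message(v0 <- vstClosedForm(9, 0, 1), "Poisson")
  expect_equal(v0, 2 * sqrt(9 / 2))
})

test_that("pairwise DE covers all time-point pairs and flags by padj", {
  tce <- leafScenario(seed = 2, nGenes = 400)
  de <- suppressMessages(pairwiseDE(tce, alpha = 0.05))
  expect_length(de@results, choose(5, 2))
  r <- de@results[[1]]
  expect_true(all(r$padj >= r$pval))
  expect_identical(r$significant, r$padj < 0.05)
  expect_true(all(r$pval > 0 & r$pval <= 1))

  mer <- simulateTimecourse(simulationConfig(grid = meristemTimeGrid(),
                                             nGenes = 300, seed = 4))
  deM <- suppressMessages(pairwiseDE(mer))
  expect_length(deM@results, choose(3, 2))
})

test_that("all-zero genes are dropped and reported", {
  tce <- leafScenario(seed = 6, nGenes = 200)
  k <- counts(tce)
  k[1:3, ] <- 0L
  tce2 <- TimecourseExperiment(k, as.data.frame(
    SummarizedExperiment::colData(tce)))
  expect_message(de <- pairwiseDE(tce2), "3 gene")
  expect_setequal(de@droppedGenes, rownames(k)[1:3])
  expect_false(any(rownames(k)[1:3] %in% de@results[[1]]$gene))
})

test_that("infinite fold-change sentinels appear only with a zero side", {
  tce <- leafScenario(seed = 8, nGenes = 150)
  de <- suppressMessages(pairwiseDE(tce))
  for (r in de@results) {
    inf <- is.infinite(r$log2FoldChange)
    zeroSide <- r$baseMeanA == 0 | r$baseMeanB == 0
    expect_true(all(!inf | zeroSide))
  }
})
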