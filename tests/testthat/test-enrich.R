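test_that("MDS recovers planar configurations exactly", {
  # 6 samples lying in a 2-D affine subspace of gene space
  withr::with_seed(1, {
    basis <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
    coords <- matrix(rnorm(12, sd = 3), 2, 6)
  })
  X <- basis %*% coords + 5
  fit <- mdsEmbedding(X, dims = 2)
  expect_equal(as.matrix(dist(fit$points)), as.matrix(dist(t(X))),
               tolerance = 1e-8, ignore_attr = TRUE)

  # three equidistant samples embed as an equilateral triangle
  Y <- diag(3) * sqrt(2)
  fitY <- mdsEmbedding(rbind(Y, Y), dims = 2)
  dd <- as.numeric(dist(fitY$points))
  expect_equal(max(dd) / min(dd), 1, tolerance = 1e-8)

  expect_error(mdsEmbedding(X[, 1:2], dims = 2), "at least")
})

test_that("MDS agrees with an independent eigendecomposition oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, X <- matrix(rnorm(30 * 6), 30, 6))
    fit <- mdsEmbedding(X, dims = 2)
    orc <- oracleMds(X, dims = 2)
    expect_equal(fit$eig, orc$eig, tolerance = 1e-8)
    # coordinates agree up to per-axis sign
    for (j in 1:2)
      expect_equal(abs(unname(fit$points[, j])), abs(orc$points[, j]),
                   tolerance = 1e-8)
    # projection property: embedded distances never exceed input distances
    expect_true(all(dist(fit$points) <= dist(t(X)) + 1e-8))
    expect_true(all(fit$eig > -1e-8 * max(abs(fit$eig))))
  }
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # constructed example: 10-gene study (5 with term), 100-gene universe
  # (10 with term)
  universe <- sprintf("g%03d", 1:100)
  withTerm <- universe[1:10]
  study <- c(universe[1:5], universe[11:15])
  ann <- setNames(lapply(universe, function(g)
    if (g %in% withTerm) "T0001" else character(0)), universe)
  res <- fisherEnrichment(study, universe, ann, cutoff = 0.01)
  expect_equal(res$pval, oracleFisher2Sided(5, 5, 5, 85), tolerance = 1e-12)
  expect_true(res$enriched)
  expect_equal(res$direction, "over")

  # study == universe: degenerate table, p = 1, nothing enriched
  resAll <- fisherEnrichment(universe, universe, ann)
  expect_equal(resAll$pval, 1)
  expect_false(any(resAll$enriched))

  # a term absent from the universe is skipped
  ann2 <- ann
  ann2[["absent_gene"]] <- "T9999"
  res2 <- fisherEnrichment(study, universe, ann2)
  expect_false("T9999" %in% res2$term)

  expect_error(fisherEnrichment(c(study, "not_there"), universe, ann),
               "subset")
})

test_that("Fisher p-values match enumeration on random tables, universe <= 500", {
  withr::with_seed(99, {
    for (i in 1:120) {
      N <- sample(10:500, 1)
      m <- sample(1:(N - 1), 1)
      k <- sample(1:(N - 1), 1)
      rng <- max(0, k + m - N):min(k, m)
      a <- rng[sample.int(length(rng), 1)]
      universe <- sprintf("u%04d", 1:N)
      study <- universe[1:k]
      withTerm <- c(universe[seq_len(a)],
                    universe[k + seq_len(m - a)])
      ann <- split(rep("T1", length(withTerm)), withTerm)
      res <- fisherEnrichment(study, universe, ann)
      expect_equal(res$pval,
                   oracleFisher2Sided(a, k - a, m - a, N - k - (m - a)),
                   tolerance = 1e-9)
    }
  })
})

test_that("overlap summary obeys inclusion-exclusion", {
  s <- list(A = letters[1:10], B = letters[6:15], C = LETTERS[1:4])
  ov <- overlapSummary(s)
  ab <- ov[ov$setA == "A" & ov$setB == "B", ]
  expect_equal(ab$common, 5)
  expect_equal(ab$specificA, 5)
  expect_equal(ab$specificB, 5)
  ac <- ov[ov$setA == "A" & ov$setB == "C", ]
  expect_equal(ac$common, 0)
  same <- overlapSummary(list(x = letters[1:7], y = letters[1:7]))
  expect_equal(same$common, 7)
  expect_equal(same$specificA + same$specificB, 0)
  withr::with_seed(4, {
    for (i in 1:20) {
      A <- sample(letters, sample(5:20, 1))
      B <- sample(letters, sample(5:20, 1))
      o <- overlapSummary(list(A = A, B = B))
      expect_equal(o$sizeA, o$common + o$specificA)
      expect_equal(o$sizeB, o$common + o$specificB)
    }
  })
})

test_that("comparison matrix is symmetric with zero diagonal", {
  tce <- leafScenario(seed = 5, nGenes = 300)
  de <- suppressMessages(pairwiseDE(tce))
  cm <- comparisonMatrix(de)
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 0))
  expect_equal(dim(cm), c(5, 5))
  # counts agree with the per-comparison tables
  expect_equal(cm["d0", "d63"],
               sum(de@results[["d0_vs_d63"]]$significant))
})
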