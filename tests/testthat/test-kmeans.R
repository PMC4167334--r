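test_that("weighted distance evaluates the quadrature form", {
  w <- timeWeights(leafTimeGrid())
  x <- c(0, 1, 0, 0, 0)
  expect_equal(weightedDist(x, x, w), 0)
  expect_equal(weightedDist(x, rep(0, 5), w), sqrt(0.2))
  # constant offset has distance |c| on any grid
  expect_equal(weightedDist(rep(2.5, 5), rep(-1, 5), w), 3.5)
  g2 <- TimeGrid(c(0, 9), c("pre_induction", "long_day"), "leaf")
  expect_equal(weightedDist(c(4, 4), c(1, 1), timeWeights(g2)), 3)
  expect_error(weightedDist(1:3, 1:4, w), "equal length")
})

test_that("k-means++ seeding is deterministic and exhaustive at K = n", {
  w <- timeWeights(leafTimeGrid())
  withr::with_seed(2, X <- matrix(rnorm(40 * 5), 40, 5))
  i1 <- kmeansppInit(X, 6, w, seed = 99)
  i2 <- kmeansppInit(X, 6, w, seed = 99)
  expect_identical(i1, i2)
  i3 <- kmeansppInit(X, 6, w, seed = 100)
  expect_false(identical(i1, i3))

  small <- X[1:7, ]
  init <- kmeansppInit(small, 7, w, seed = 1)
  # every profile becomes a centre, in some order
  expect_equal(nrow(init), 7)
  expect_true(all(apply(init, 1, function(cc)
    any(apply(small, 1, function(r) all(r == cc))))))
  expect_equal(anyDuplicated(init), 0)

  expect_error(kmeansppInit(small[c(1, 1, 2), ], 3, w, seed = 1),
               "distinct profiles")
})

test_that("weighted Lloyd equals standard K-means on sqrt(w)-scaled coordinates", {
  g <- leafTimeGrid()
  w <- timeWeights(g)@weights
  for (seed in 1:6) {
    withr::with_seed(seed + 500, X <- matrix(rnorm(200 * 5), 200, 5))
    m <- fitTimeKmeans(X, g, K = 5, seed = seed, nRestarts = 1, tol = 0)
    init <- kmeansppInit(X, 5, timeWeights(g), seed)
    km <- suppressWarnings(stats::kmeans(
      sweep(X, 2, sqrt(w), "*"), centers = sweep(init, 2, sqrt(w), "*"),
      iter.max = 500, algorithm = "Lloyd"))
    expect_identical(unname(m@assignments), as.integer(km$cluster))
    expect_equal(m@inertia, km$tot.withinss, tolerance = 1e-10)
    expect_equal(sweep(m@centroids, 2, sqrt(w), "*"),
                 unname(km$centers), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("K = 1 gives the weighted total variance in closed form", {
  g <- meristemTimeGrid()
  w <- timeWeights(g)@weights
  withr::with_seed(3, X <- matrix(rnorm(30 * 3, sd = 2), 30, 3))
  m <- fitTimeKmeans(X, g, K = 1, seed = 1, nRestarts = 2)
  expect_equal(unname(m@centroids[1, ]), colMeans(X))
  expect_equal(m@inertia,
               sum(t(w * t((X - rep(colMeans(X), each = 30))^2))))
})

test_that("two well-separated groups are recovered at the brute-force optimum", {
  g <- leafTimeGrid()
  w <- timeWeights(g)@weights
  withr::with_seed(17, {
    X <- rbind(matrix(rnorm(15, 0, 0.1), 3, 5),
               matrix(rnorm(15, 8, 0.1), 3, 5))
  })
  m <- fitTimeKmeans(X, g, K = 2, seed = 4, nRestarts = 5)
  expect_equal(length(unique(m@assignments[1:3])), 1)
  expect_equal(length(unique(m@assignments[4:6])), 1)
  expect_false(m@assignments[1] == m@assignments[4])
  expect_equal(m@inertia, oracleBest2Partition(X, w), tolerance = 1e-10)
})

test_that("fitted weighted SSE matches exhaustive 2-partition enumeration", {
  g <- leafTimeGrid()
  w <- timeWeights(g)@weights
  for (seed in 1:30) {
    withr::with_seed(seed, {
      n <- sample(4:8, 1)
      X <- matrix(rnorm(n * 5), n, 5)
    })
    m <- fitTimeKmeans(X, g, K = 2, seed = seed, nRestarts = 40)
    expect_equal(m@inertia, oracleBest2Partition(X, w), tolerance = 1e-10)
  }
})

test_that("inertia is non-increasing across Lloyd iterations", {
  g <- leafTimeGrid()
  w <- timeWeights(g)@weights
  withr::with_seed(23, X <- matrix(rnorm(300 * 5), 300, 5))
  init <- kmeansppInit(X, 8, timeWeights(g), seed = 1)
  sol <- vernclust:::.lloydWeighted(X, init, w, maxIter = 300, tol = 0)
  expect_true(all(diff(sol$trace) <= 1e-12))
})

test_that("duplicated profiles share a cluster", {
  g <- meristemTimeGrid()
  withr::with_seed(5, X <- matrix(rnorm(20 * 3), 20, 3))
  X <- rbind(X, X[3, ], X[3, ])
  m <- fitTimeKmeans(X, g, K = 4, seed = 2, nRestarts = 5)
  expect_equal(length(unique(m@assignments[c(3, 21, 22)])), 1)
})

test_that("permuting profile order permutes the partition, same inertia", {
  g <- leafTimeGrid()
  withr::with_seed(31, {
    X <- rbind(matrix(rnorm(50, 0, 0.3), 10, 5),
               matrix(rnorm(50, 4, 0.3), 10, 5),
               matrix(rnorm(50, 8, 0.3), 10, 5))
    perm <- sample(30)
  })
  m1 <- fitTimeKmeans(X, g, K = 3, seed = 1, nRestarts = 10)
  m2 <- fitTimeKmeans(X[perm, ], g, K = 3, seed = 1, nRestarts = 10)
  expect_equal(m1@inertia, m2@inertia, tolerance = 1e-10)
  # same partition up to cluster relabeling
  expect_equal(mclust::adjustedRandIndex(m1@assignments[perm],
                                         m2@assignments), 1)
})

test_that("cluster report is consistent and round-trips through TSV", {
  g <- leafTimeGrid()
  withr::with_seed(7, X <- matrix(rnorm(25 * 5), 25, 5,
    dimnames = list(sprintf("g%02d", 1:25), NULL)))
  m <- fitTimeKmeans(X, g, K = 3, seed = 1)
  rep <- clusterReport(m)
  expect_equal(sum(rep$centroids$size), 25)
  expect_equal(nrow(rep$assignments), 25)
  dir <- withr::local_tempdir()
  writeClusterModel(m, dir)
  back <- readClusterReport(dir)
  expect_equal(back$assignments, rep$assignments)
  expect_equal(back$centroids$cluster, rep$centroids$cluster)
  expect_equal(as.matrix(back$centroids[, -(1:2)]),
               as.matrix(rep$centroids[, -(1:2)]), tolerance = 1e-12,
               ignore_attr = TRUE)

  single <- fitTimeKmeans(X[1, , drop = FALSE], g, K = 1, seed = 1)
  repS <- clusterReport(single, geneIds = "g01")
  expect_equal(repS$centroids$size, 1)
  expect_equal(unname(as.numeric(repS$centroids[1, -(1:2)])),
               unname(X[1, ]))
})

test_that("degenerate requests fail loudly", {
  g <- leafTimeGrid()
  X <- matrix(rnorm(10 * 5), 10, 5)
  expect_error(fitTimeKmeans(X, g, K = 11, seed = 1), "exceeds")
  expect_error(fitTimeKmeans(X[, 1:3], g, K = 2, seed = 1), "time points")
})
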