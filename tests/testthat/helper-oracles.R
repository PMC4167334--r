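# independent oracles used across the suite; deliberately naive

# exact conditional NB test by direct enumeration over all splits of the
# total, on the probability scale
oracleNbExact <- function(kA, kB, sA, sB, alpha) {
  total <- kA + kB
  if (total == 0) return(1)
  q <- (kA / sA + kB / sB) / 2
  probs <- numeric(total + 1)
  for (a in 0:total) {
    b <- total - a
    if (alpha <= 0) {
      probs[a + 1] <- dpois(a, sA * q) * dpois(b, sB * q)
    } else {
      probs[a + 1] <- dnbinom(a, size = 1 / alpha, mu = sA * q) *
        dnbinom(b, size = 1 / alpha, mu = sB * q)
    }
  }
  pObs <- probs[kA + 1]
  sum(probs[probs <= pObs * (1 + 1e-7)]) / sum(probs)
}

# brute-force minimum weighted SSE over all 2-partitions (both parts
# non-empty) of <= 8 profiles
oracleBest2Partition <- function(X, w) {
  n <- nrow(X)
  sse <- function(idx) {
    if (!length(idx)) return(0)
    c0 <- colMeans(X[idx, , drop = FALSE])
    sum(t(w * t((X[idx, , drop = FALSE] - rep(c0, each = length(idx)))^2)))
  }
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    inA <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    inB <- setdiff(seq_len(n), inA)
    best <- min(best, sse(inA) + sse(inB))
  }
  best
}

# classical MDS by explicit double centering + eigendecomposition
oracleMds <- function(X, dims = 2) {
  D2 <- as.matrix(dist(t(X)))^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pts <- e$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(dims)], 0)), dims)
  list(points = pts, eig = e$values)
}

# two-sided Fisher p by hypergeometric enumeration: P(X = a | margins), sum
# of outcomes no more likely than observed
oracleFisher2Sided <- function(a, b, cc, dd) {
  m <- a + cc       # total with term
  n <- b + dd       # total without term
  k <- a + b        # study size
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# default leaf scenario used by several end-to-end checks
leafScenario <- function(seed = 1L, nGenes = 2000L) {
  simulateTimecourse(simulationConfig(nGenes = nGenes, seed = seed))
}

allNullScenario <- function(seed = 3L, nGenes = 2000L) {
  simulateTimecourse(simulationConfig(
    nGenes = nGenes, archetypeMix = c(null_flat = 1), seed = seed))
}
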