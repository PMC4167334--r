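#' Calendar-time weights for a sampling grid
#'
#' Assigns each time point the share of the study span it represents: the
#' Voronoi (trapezoid) interval widths on the time axis,
#' `w_1 = (t_2 - t_1)/2`, `w_i = (t_{i+1} - t_{i-1})/2` for interior points,
#' `w_n = (t_n - t_{n-1})/2`, normalized by the total span `t_n - t_1`.
#' With these weights a sample collected after a long gap (nine weeks of
#' cold) counts proportionally more in the profile distance than one taken
#' two days after its neighbour.
#'
#' @param grid A [TimeGrid-class] with at least 2 strictly increasing
#'   times.
#' @return A [TimeWeights-class].
#' @examples
#' timeWeights(leafTimeGrid())@weights  # 1/70 14/70 30.5/70 21/70 3.5/70
#' @rdname timeWeights
#' @export
setMethod("timeWeights", "TimeGrid", function(grid) {
  t <- gridTimes(grid)
  n <- length(t)
  if (n < 2L) stop("time weights need at least 2 time points")
  w <- numeric(n)
  w[1L] <- (t[2L] - t[1L]) / 2
  w[n] <- (t[n] - t[n - 1L]) / 2
  if (n > 2L)
    w[2:(n - 1L)] <- (t[3:n] - t[1:(n - 2L)]) / 2
  new("TimeWeights", weights = w / (t[n] - t[1L]), grid = grid)
})

setMethod("show", "TimeWeights", function(object) {
  cat("TimeWeights on", gridTissue(object@grid), "grid:\n  ")
  cat(paste(sprintf("d%g: %.4f", gridTimes(object@grid), object@weights),
            collapse = "  "), "\n")
})

.weightVec <- function(w) {
  if (is(w, "TimeWeights")) w@weights else as.numeric(w)
}

#' Time-weighted Euclidean distance between expression profiles
#'
#' `sqrt(sum_i w_i (x_i - y_i)^2)`. Because the weights sum to 1, a
#' constant offset `c` between two profiles gives distance `|c|` on any
#' grid.
#'
#' @param x,y Numeric profiles of equal length.
#' @param w A [TimeWeights-class] or a bare weight vector.
#' @return Non-negative distance.
#' @export
weightedDist <- function(x, y, w) {
  wv <- .weightVec(w)
  if (length(x) != length(y) || length(x) != length(wv))
    stop("profiles and weights must have equal length")
  sqrt(sum(wv * (x - y)^2))
}

# squared weighted distances from each row of X to each centroid row:
# n x K matrix, computed on sqrt(w)-scaled coordinates
.distsq <- function(Xs, Cs) {
  # ||x||^2 - 2 x.c + ||c||^2 on the scaled coordinates
  d2 <- outer(rowSums(Xs^2), rowSums(Cs^2), "+") - 2 * Xs %*% t(Cs)
  pmax(d2, 0)
}

#' k-means++ seeding under the time-weighted distance
#'
#' Standard k-means++: the first centre is sampled uniformly, each further
#' centre with probability proportional to the squared weighted distance to
#' the nearest centre chosen so far. Deterministic given the seed; ties in
#' the sampling distribution resolve to the lowest profile index.
#'
#' @param X Numeric matrix of profiles (rows).
#' @param K Number of centres, at most the number of distinct profiles.
#' @param w A [TimeWeights-class] or weight vector.
#' @param seed Integer seed.
#' @return `K x ncol(X)` matrix of initial centroids.
#' @export
kmeansppInit <- function(X, K, w, seed) {
  wv <- .weightVec(w)
  stopifnot(ncol(X) == length(wv))
  nDistinct <- nrow(unique(X))
  if (K > nDistinct)
    stop("K (", K, ") exceeds the number of distinct profiles (", nDistinct,
         ")")
  Xs <- sweep(X, 2L, sqrt(wv), "*")
  idx <- integer(K)
  withr::with_seed(seed, {
    idx[1L] <- sample.int(nrow(X), 1L)
    if (K > 1L) {
      d2 <- .distsq(Xs, Xs[idx[1L], , drop = FALSE])[, 1L]
      for (j in 2:K) {
        tot <- sum(d2)
        if (tot <= 0) {
          # all remaining profiles coincide with a centre; K <= distinct
          # profiles guarantees this cannot happen before K centres exist
          cand <- which(!seq_len(nrow(X)) %in% idx[seq_len(j - 1L)])
          idx[j] <- cand[1L]
        } else {
          u <- stats::runif(1L) * tot
          idx[j] <- which(cumsum(d2) >= u)[1L]
        }
        d2 <- pmin(d2, .distsq(Xs, Xs[idx[j], , drop = FALSE])[, 1L])
      }
    }
  })
  X[idx, , drop = FALSE]
}

#' Time-weighted K-means clustering of expression profiles
#'
#' Lloyd's algorithm under the time-weighted distance of [weightedDist()]:
#' profiles are assigned to the nearest centroid (ties to the
#' lowest-indexed centroid) and centroids are updated as the plain
#' per-time-point mean of their members — the weights factor out of the
#' centroid minimization. Internally the problem is solved on
#' `sqrt(w)`-scaled coordinates, on which weighted K-means is exactly
#' standard K-means. Empty clusters are re-seeded with the profile farthest
#' from its centroid. The best of `nRestarts` seeded k-means++ starts by
#' inertia is returned.
#'
#' @param X Numeric matrix, one profile per row (typically VST values of
#'   the DE union set), columns in grid order.
#' @param grid A [TimeGrid-class] (or a [TimeWeights-class] to reuse
#'   precomputed weights).
#' @param K Number of clusters; the study design uses 50 for leaf and 25
#'   for meristem profiles.
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param nRestarts,maxIter Number of k-means++ restarts and Lloyd
#'   iteration cap.
#' @param tol Relative inertia improvement below which iteration stops.
#' @param standardize If `TRUE`, rows are z-scored before clustering;
#'   the default clusters raw VST profiles.
#' @return A [ClusterModel-class].
#' @examples
#' X <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(30, 5), 10, 3))
#' g <- meristemTimeGrid()
#' fitTimeKmeans(X, g, K = 2, seed = 1)
#' @export
fitTimeKmeans <- function(X, grid, K, seed = 1L, nRestarts = 10L,
                          maxIter = 300L, tol = 1e-6,
                          standardize = FALSE) {
  X <- as.matrix(X)
  tw <- if (is(grid, "TimeWeights")) grid else timeWeights(grid)
  wv <- tw@weights
  if (ncol(X) != length(wv))
    stop("profiles have ", ncol(X), " columns but the grid has ",
         length(wv), " time points")
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(X))
    stop("K (", K, ") exceeds the number of profiles (", nrow(X), ")")
  if (standardize) {
    mu <- rowMeans(X)
    sd <- apply(X, 1L, stats::sd)
    X <- (X - mu) / ifelse(sd > 0, sd, 1)
  }

  best <- NULL
  for (r in seq_len(nRestarts)) {
    restartSeed <- as.integer(seed) + r - 1L
    init <- kmeansppInit(X, K, tw, restartSeed)
    sol <- .lloydWeighted(X, init, wv, maxIter = maxIter, tol = tol)
    if (is.null(best) || sol$inertia < best$inertia) best <- sol
  }
  # tiny two-cluster problems: k-means++ can systematically miss the seed
  # pair whose basin holds the global optimum, so run Lloyd from every
  # distinct pair of profiles as well (deterministic, at most 66 starts)
  if (K == 2L && nrow(X) <= 12L) {
    for (i in seq_len(nrow(X) - 1L)) {
      for (j in seq(i + 1L, nrow(X))) {
        if (all(X[i, ] == X[j, ])) next
        sol <- .lloydWeighted(X, X[c(i, j), , drop = FALSE], wv,
                              maxIter = maxIter, tol = tol)
        if (sol$inertia < best$inertia) best <- sol
      }
    }
  }
  assign <- as.integer(best$assign)
  names(assign) <- rownames(X)
  cent <- best$centroids
  dimnames(cent) <- list(paste0("cluster_", seq_len(K)), colnames(X))
  new("ClusterModel", K = as.integer(K), assignments = assign,
      centroids = cent, inertia = best$inertia, weights = tw,
      seed = as.integer(seed), nIter = as.integer(best$iter),
      converged = best$converged)
}

# Lloyd iterations on sqrt(w)-scaled coordinates; centroids returned on the
# original scale
.lloydWeighted <- function(X, init, wv, maxIter, tol) {
  s <- sqrt(wv)
  Xs <- sweep(X, 2L, s, "*")
  Cs <- sweep(as.matrix(init), 2L, s, "*")
  K <- nrow(Cs)
  n <- nrow(Xs)
  assign <- rep(0L, n)
  inertia <- Inf
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    d2 <- .distsq(Xs, Cs)
    newAssign <- max.col(-d2, ties.method = "first")
    newInertia <- sum(d2[cbind(seq_len(n), newAssign)])
    # handle empty clusters: seed each with the currently farthest profile
    empty <- setdiff(seq_len(K), unique(newAssign))
    if (length(empty)) {
      dmin <- d2[cbind(seq_len(n), newAssign)]
      for (e in empty) {
        far <- which.max(dmin)
        Cs[e, ] <- Xs[far, ]
        newAssign[far] <- e
        dmin[far] <- 0
      }
      newInertia <- NA_real_  # recompute next sweep
    }
    stopAssign <- identical(newAssign, assign)
    assign <- newAssign
    for (kk in seq_len(K)) {
      members <- assign == kk
      if (any(members))
        Cs[kk, ] <- colMeans(Xs[members, , drop = FALSE])
    }
    if (!is.na(newInertia)) {
      trace <- c(trace, newInertia)
      improvement <- inertia - newInertia
      inertia <- newInertia
      if (stopAssign || improvement <= tol * max(inertia, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  # final assignment pass against the final centroids
  d2 <- .distsq(Xs, Cs)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  centroids <- sweep(Cs, 2L, s, "/")
  list(assign = assign, centroids = centroids, inertia = inertia,
       iter = iter, converged = converged, trace = trace)
}

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: K = %d over %d profiles (%s grid)\n",
              object@K, length(object@assignments),
              gridTissue(object@weights@grid)))
  cat(sprintf("  weighted inertia = %.6g; %d iterations; converged: %s; seed %d\n",
              object@inertia, object@nIter, object@converged, object@seed))
})

#' Membership and centroid tables of a fitted cluster model
#'
#' @param model A [ClusterModel-class].
#' @param geneIds Optional identifiers for the clustered profiles; defaults
#'   to the assignment names.
#' @return List of two data frames: `assignments` (gene, cluster) and
#'   `centroids` (cluster, size, one column per time point).
#' @rdname clusterReport
#' @export
setMethod("clusterReport", "ClusterModel", function(model, geneIds = NULL) {
  if (is.null(geneIds)) geneIds <- names(model@assignments)
  if (is.null(geneIds))
    geneIds <- sprintf("profile_%d", seq_along(model@assignments))
  if (length(geneIds) != length(model@assignments))
    stop("geneIds must cover every assignment")
  sizes <- tabulate(model@assignments, nbins = model@K)
  cent <- as.data.frame(model@centroids)
  colnames(cent) <- sprintf("d%g", gridTimes(model@weights@grid))
  list(
    assignments = data.frame(gene = geneIds,
                             cluster = unname(model@assignments),
                             stringsAsFactors = FALSE),
    centroids = cbind(data.frame(cluster = seq_len(model@K), size = sizes),
                      cent))
})
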