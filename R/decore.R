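#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making counts comparable across libraries:
#' each sample's factor is the median, over genes expressed in every sample,
#' of the ratio of its count to the gene's geometric mean across samples.
#'
#' @param counts Integer matrix (genes x samples) or a
#'   [TimecourseExperiment-class].
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' k <- matrix(c(10, 100, 30, 300), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' medianOfRatios(k)  # 1/sqrt(3), sqrt(3)
#' @export
medianOfRatios <- function(counts) {
  k <- .countMatrix(counts)
  allPos <- rowSums(k > 0) == ncol(k)
  if (!any(allPos))
    stop("size-factor estimation failed: no gene has positive counts in ",
         "every sample")
  k <- k[allPos, , drop = FALSE]
  logGeoMean <- rowMeans(log(k))
  sf <- apply(k, 2L, function(col) exp(stats::median(log(col) - logGeoMean)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size-factor estimation produced non-positive factors")
  sf
}

#' Blind negative binomial dispersion estimation
#'
#' With a single library per condition, gene-wise variability cannot be
#' estimated within conditions, so all samples are treated as replicates of
#' one condition ("blind" mode). Per gene, a method-of-moments dispersion is
#' computed from the size-factor-normalized counts,
#' `alpha_g = max(0, (v_g - mu_g * xi) / mu_g^2)` with `xi` the mean
#' reciprocal size factor (the shot-noise correction), and the parametric
#' curve `alpha(mu) = a0 + a1/mu` is then fitted across genes by
#' iteratively reweighted gamma-family least squares. This deliberately
#' absorbs real between-time-point signal into the dispersion, making the
#' downstream tests conservative.
#'
#' @param counts Count matrix or [TimecourseExperiment-class].
#' @param sizeFactors Optional size factors; computed by [medianOfRatios()]
#'   when missing.
#' @param maxIter,tol IRLS iteration cap and relative convergence tolerance.
#' @return A [DispersionFit-class].
#' @export
estimateDispersionBlind <- function(counts, sizeFactors = NULL,
                                    maxIter = 25L, tol = 1e-8) {
  k <- .countMatrix(counts)
  if (ncol(k) < 2L)
    stop("blind dispersion estimation needs at least 2 samples")
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(k)
  q <- sweep(k, 2L, sizeFactors, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1L, stats::var)
  xi <- mean(1 / sizeFactors)
  alpha <- ifelse(mu > 0, pmax(0, (v - mu * xi) / mu^2), 0)
  names(alpha) <- names(mu) <- rownames(k)

  use <- mu > 0
  fit <- .fitGammaIRLS(alpha[use], mu[use], maxIter = maxIter, tol = tol)
  new("DispersionFit", perGeneAlpha = alpha, baseMeans = mu,
      fitParams = fit$params, mode = "blind", fitFallback = fit$fallback)
}

# gamma-family IRLS for alpha ~ a0 + a1/mu: weighted least squares with
# weights 1/fitted^2, refitted to convergence; tolerates alpha == 0 rows,
# which a Gamma GLM would reject. With no replicates, real between-condition
# signal inflates the per-gene moments dispersions and hence the fit: the
# resulting tests are deliberately conservative, which is the accepted cost
# of the blind design.
.fitGammaIRLS <- function(alpha, mu, maxIter = 25L, tol = 1e-8) {
  x <- 1 / mu
  fallback <- FALSE
  params <- tryCatch({
    f <- pmax(stats::median(alpha), 1e-8)
    f <- rep(f, length(alpha))
    coefs <- c(stats::median(alpha), 0)
    for (i in seq_len(maxIter)) {
      w <- 1 / pmax(f, 1e-8)^2
      ls <- stats::lm.wfit(cbind(1, x), alpha, w)
      newCoefs <- ls$coefficients
      if (any(!is.finite(newCoefs))) stop("singular dispersion fit")
      fNew <- pmax(newCoefs[1] + newCoefs[2] * x, 1e-8)
      if (max(abs(newCoefs - coefs)) <= tol * (1 + max(abs(coefs)))) {
        coefs <- newCoefs
        f <- fNew
        break
      }
      coefs <- newCoefs
      f <- fNew
    }
    pmax(unname(coefs), 0)
  }, error = function(e) {
    fallback <<- TRUE
    message("parametric dispersion fit failed (", conditionMessage(e),
            "); falling back to the median per-gene dispersion")
    c(max(stats::median(alpha), 0), 0)
  })
  list(params = params, fallback = fallback)
}

#' Evaluate a fitted dispersion at given means
#'
#' @param fit A [DispersionFit-class].
#' @param mu Normalized mean counts.
#' @return `a0 + a1 / mu` (and `a0` where `mu` is 0 or negative).
#' @export
dispersionAt <- function(fit, mu) {
  a <- fit@fitParams
  ifelse(mu > 0, a[1] + a[2] / mu, a[1])
}

#' Exact conditional negative binomial test for a pair of single libraries
#'
#' Tests whether two counts from single libraries are consistent with a
#' common underlying expression level. With pooled mean estimate
#' `q = (kA/sA + kB/sB) / 2`, the counts in the two libraries are modelled
#' as independent NB variables with means `sA*q`, `sB*q` and dispersion
#' `alpha(q)`; conditioning on the observed total, the p-value is the
#' probability of all splits of the total no more likely than the observed
#' one.
#'
#' @param kA,kB Observed counts (non-negative integers), vectorized.
#' @param sA,sB Size factors of the two libraries.
#' @param fit A [DispersionFit-class], or a single non-negative number used
#'   as a constant dispersion.
#' @return P-values in (0, 1]; the pair (0, 0) returns 1 by convention.
#' @examples
#' nbExactTest(0, 10, 1, 1, fit = 0.1)
#' @export
nbExactTest <- function(kA, kB, sA, sB, fit) {
  stopifnot(length(kA) == length(kB), all(kA >= 0), all(kB >= 0),
            sA > 0, sB > 0)
  alphaOf <- if (is(fit, "DispersionFit")) {
    function(q) dispersionAt(fit, q)
  } else {
    stopifnot(is.numeric(fit), length(fit) == 1L, fit >= 0)
    function(q) fit
  }
  vapply(seq_along(kA), function(i)
    .nbExactOne(kA[i], kB[i], sA, sB, alphaOf), numeric(1))
}

.nbExactOne <- function(kA, kB, sA, sB, alphaOf) {
  total <- kA + kB
  if (total == 0) return(1)
  q <- (kA / sA + kB / sB) / 2
  alpha <- alphaOf(q)
  a <- 0:total
  b <- total - a
  muA <- sA * q
  muB <- sB * q
  if (alpha <= 0) {
    logP <- stats::dpois(a, muA, log = TRUE) +
      stats::dpois(b, muB, log = TRUE)
  } else {
    size <- 1 / alpha
    logP <- stats::dnbinom(a, size = size, mu = muA, log = TRUE) +
      stats::dnbinom(b, size = size, mu = muB, log = TRUE)
  }
  logObs <- logP[kA + 1L]
  # log-sum-exp; tolerance guards equal-probability ties against roundoff
  keep <- logP <= logObs + 1e-7
  m <- max(logP)
  p <- sum(exp(logP[keep] - m)) / sum(exp(logP - m))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, each in `[p, 1]`, monotone in `p`.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Closed-form variance-stabilizing transformation
#'
#' Under the dispersion model `alpha(mu) = a0 + a1/mu`, a count with
#' normalized mean `mu` has variance `v(mu) = (1 + a1) mu + a0 mu^2`. The
#' antiderivative of `1/sqrt(v(mu))` is
#' `raw(mu) = (2/sqrt(a0)) * asinh(sqrt(a0 * mu / (1 + a1)))`, which maps
#' counts to a scale of approximately constant standard deviation. The
#' transform is calibrated affinely so that for large `mu` a doubling of
#' expression raises the value by 1 (log2-like units):
#' `vst(mu) = 2/log(2) * asinh(sqrt(a0*mu/(1+a1))) + log2((1+a1)/(4*a0))`.
#'
#' @param counts Count matrix or [TimecourseExperiment-class].
#' @param sizeFactors Optional size factors ([medianOfRatios()] if missing).
#' @param fit A [DispersionFit-class] (estimated blind if missing), or
#'   `c(a0, a1)` given directly.
#' @return Matrix of variance-stabilized values, same shape as the counts.
#' @seealso [vstClosedForm()] for the scalar transform.
#' @export
vstTransform <- function(counts, sizeFactors = NULL, fit = NULL) {
  k <- .countMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(k)
  if (is.null(fit)) fit <- estimateDispersionBlind(k, sizeFactors)
  params <- if (is(fit, "DispersionFit")) fit@fitParams else as.numeric(fit)
  q <- sweep(k, 2L, sizeFactors, "/")
  out <- vstClosedForm(q, params[1], params[2])
  dimnames(out) <- dimnames(k)
  out
}

#' @rdname vstTransform
#' @param mu Normalized counts or means (non-negative).
#' @param a0,a1 Dispersion-model parameters, `a0 >= 0`, `a1 >= 0`.
#' @export
vstClosedForm <- function(mu, a0, a1) {
  stopifnot(a0 >= 0, a1 >= 0)
  if (a0 == 0) {
    message("a0 = 0: using the Poisson-limit transform 2*sqrt(mu/(1+a1)), ",
            "which has no log2-like calibration")
    return(2 * sqrt(mu / (1 + a1)))
  }
  2 / log(2) * asinh(sqrt(a0 * mu / (1 + a1))) + log2((1 + a1) / (4 * a0))
}

#' Pairwise differential expression across all time points
#'
#' Runs the exact conditional NB test ([nbExactTest()]) for every unordered
#' pair of time points of a tissue, using blind dispersion estimated from
#' all samples, and adjusts p-values per comparison by Benjamini-Hochberg.
#' Genes with zero counts at every time point are dropped before testing
#' (their number is reported). The union of genes significant in at least
#' one comparison is the input set for profile clustering.
#'
#' @param x A [TimecourseExperiment-class] with one library per time point.
#' @param alpha Significance level applied to adjusted p-values.
#' @param fit Optional pre-computed [DispersionFit-class].
#' @param sizeFactors Optional pre-computed size factors.
#' @return A [PairwiseDEResults-class].
#' @examples
#' tce <- simulateTimecourse(simulationConfig(nGenes = 100, seed = 3))
#' de <- pairwiseDE(tce, alpha = 0.05)
#' length(deUnion(de))
#' @export
pairwiseDE <- function(x, alpha = 0.05, fit = NULL, sizeFactors = NULL) {
  stopifnot(is(x, "TimecourseExperiment"))
  grid <- timeGrid(x)
  times <- gridTimes(grid)
  cd <- SummarizedExperiment::colData(x)
  if (anyDuplicated(cd$time_days))
    stop("pairwiseDE expects one library per time point; sum technical ",
         "replicates first")
  k <- .countMatrix(x)
  keep <- rowSums(k) > 0
  dropped <- rownames(k)[!keep]
  if (length(dropped))
    message(length(dropped), " gene(s) with zero counts at every time ",
            "point dropped before testing")
  k <- k[keep, , drop = FALSE]
  if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(k)
  if (is.null(fit)) fit <- estimateDispersionBlind(k, sizeFactors)

  ord <- order(cd$time_days)
  k <- k[, ord, drop = FALSE]
  sizeFactors <- sizeFactors[ord]
  pairs <- utils::combn(seq_along(times), 2L)
  results <- vector("list", ncol(pairs))
  cmpNames <- character(ncol(pairs))
  comparisons <- matrix(NA_real_, ncol(pairs), 2L,
                        dimnames = list(NULL, c("timeA", "timeB")))
  for (j in seq_len(ncol(pairs))) {
    iA <- pairs[1L, j]; iB <- pairs[2L, j]
    kA <- k[, iA]; kB <- k[, iB]
    sA <- sizeFactors[iA]; sB <- sizeFactors[iB]
    pval <- nbExactTest(kA, kB, sA, sB, fit)
    baseA <- kA / sA
    baseB <- kB / sB
    log2fc <- log2(baseB / baseA)  # +/-Inf when one side is 0, NaN for 0/0
    padj <- bhAdjust(pval)
    results[[j]] <- S4Vectors::DataFrame(
      gene = rownames(k), baseMeanA = baseA, baseMeanB = baseB,
      log2FoldChange = log2fc, pval = pval, padj = padj,
      significant = padj < alpha, row.names = rownames(k))
    comparisons[j, ] <- c(times[iA], times[iB])
    cmpNames[j] <- sprintf("d%g_vs_d%g", times[iA], times[iB])
  }
  names(results) <- cmpNames
  new("PairwiseDEResults", results = results, comparisons = comparisons,
      alpha = alpha, grid = grid, fit = fit, sizeFactors = sizeFactors,
      droppedGenes = dropped)
}

#' Union set of differentially expressed genes
#'
#' Genes significant in at least one pairwise time-point comparison.
#'
#' @param object A [PairwiseDEResults-class].
#' @return Character vector of gene identifiers.
#' @rdname deUnion
#' @export
setMethod("deUnion", "PairwiseDEResults", function(object) {
  sig <- lapply(object@results, function(r) r$gene[r$significant])
  sort(unique(unlist(sig, use.names = FALSE)))
})

setMethod("show", "PairwiseDEResults", function(object) {
  cat(sprintf("PairwiseDEResults: %d comparisons on the %s grid\n",
              length(object@results), gridTissue(object@grid)))
  cat(sprintf("  alpha = %g; %d genes in the DE union; %d all-zero genes dropped\n",
              object@alpha, length(deUnion(object)),
              length(object@droppedGenes)))
  cat(sprintf("  dispersion fit: a0 = %.4g, a1 = %.4g%s\n",
              object@fit@fitParams[1], object@fit@fitParams[2],
              if (object@fit@fitFallback) " (fallback)" else ""))
})

setMethod("show", "DispersionFit", function(object) {
  cat(sprintf("DispersionFit (%s): alpha(mu) = %.4g + %.4g/mu over %d genes%s\n",
              object@mode, object@fitParams[1], object@fitParams[2],
              length(object@perGeneAlpha),
              if (object@fitFallback) " (median fallback)" else ""))
})

# internal: accept either a bare matrix or a TimecourseExperiment
.countMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "counts"))
  stopifnot(is.matrix(x), all(x >= 0))
  x
}

#' Time grid of a TimecourseExperiment
#'
#' Reconstructs the [TimeGrid-class] from the sample metadata (one grid
#' point per distinct `time_days`, ordered).
#'
#' @param object A [TimecourseExperiment-class].
#' @rdname timeGrid
#' @export
setMethod("timeGrid", "TimecourseExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  ord <- order(cd$time_days)
  dup <- !duplicated(cd$time_days[ord])
  TimeGrid(cd$time_days[ord][dup], as.character(cd$phase[ord][dup]),
           as.character(cd$tissue[1]))
})
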