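#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

.PHASE_LEVELS <- c("pre_induction", "early_cold", "mid_cold", "late_cold",
                   "long_day")
.TISSUE_LEVELS <- c("leaf", "meristem")

#' TimeGrid: an ordered calendar-time sampling schedule
#'
#' A `TimeGrid` holds the calendar times (in days) at which a tissue was
#' sampled, together with an induction-phase label per time point. It is the
#' backbone shared by the simulator, the pairwise differential-expression
#' tests, the time-weighted K-means distance, and the centroid classifier.
#'
#' @slot times Numeric vector of strictly increasing calendar days.
#' @slot phases Character vector, one label per time point, each one of
#'   `pre_induction`, `early_cold`, `mid_cold`, `late_cold`, `long_day`.
#' @slot tissue Either `"leaf"` or `"meristem"`.
#'
#' @seealso [leafTimeGrid()], [meristemTimeGrid()], [timeWeights()]
#' @export
setClass("TimeGrid",
  representation(times = "numeric", phases = "character",
                 tissue = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@times)
    if (n < 2L)
      msg <- c(msg, "a TimeGrid needs at least 2 time points")
    if (any(!is.finite(object@times)))
      msg <- c(msg, "times must be finite")
    if (n >= 2L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@phases) != n)
      msg <- c(msg, "need exactly one phase label per time point")
    bad <- setdiff(object@phases, .PHASE_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown phase label(s): ",
                           paste(bad, collapse = ", ")))
    if (length(object@tissue) != 1L ||
        !object@tissue %in% .TISSUE_LEVELS)
      msg <- c(msg, "tissue must be exactly one of 'leaf', 'meristem'")
    if (is.null(msg)) TRUE else msg
  })

#' TimeWeights: quadrature weights over a TimeGrid
#'
#' Per-time-point non-negative weights that sum to one, each proportional to
#' the span of calendar time the sampling point represents (the Voronoi /
#' trapezoid interval on the time axis). Used by [weightedDist()] and
#' [fitTimeKmeans()] so that unevenly spaced collections contribute to the
#' profile distance in proportion to the time they cover.
#'
#' @slot weights Numeric vector summing to 1, one entry per grid point.
#' @slot grid The [TimeGrid-class] the weights were derived from.
#' @export
setClass("TimeWeights",
  representation(weights = "numeric", grid = "TimeGrid"),
  validity = function(object) {
    msg <- NULL
    if (length(object@weights) != length(object@grid@times))
      msg <- c(msg, "one weight per grid point required")
    if (any(object@weights < 0))
      msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-12)
      msg <- c(msg, "weights must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' TimecourseExperiment: counts on a sampling time grid
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `counts` assay holds
#' non-negative integer read counts (genes x samples) and whose `colData`
#' carries the study design: `sample`, `genotype`, `tissue`, `time_days` and
#' `phase`. One column per (tissue, time point) library, matching a design
#' with a single pooled library per collection.
#'
#' Simulated objects additionally carry the planted truth in `rowData`
#' (`planted_label`, `is_null`, and per-time-point planted means) and the
#' planted size factors in `metadata(x)$planted_size_factors`.
#'
#' @seealso [TimecourseExperiment()], [simulateTimecourse()], [readCounts()]
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'counts' is required")
    else {
      k <- SummarizedExperiment::assay(object, "counts")
      if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(k != round(k))) msg <- c(msg, "counts must be integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("genotype", "tissue", "time_days", "phase")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      msg <- c(msg, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "gene identifiers must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' DispersionFit: blind negative-binomial dispersion estimate
#'
#' Result of treating all samples of a tissue as replicates of a single
#' condition ("blind" mode): per-gene method-of-moments dispersions and the
#' parametric mean-dispersion fit alpha(mu) = a0 + a1 / mu.
#'
#' @slot perGeneAlpha Named numeric, raw method-of-moments dispersion per
#'   gene (zero-truncated below).
#' @slot baseMeans Named numeric, size-factor-normalized mean per gene.
#' @slot fitParams Numeric of length 2, `c(a0, a1)` of the parametric fit.
#' @slot mode Character scalar, currently always `"blind"`.
#' @slot fitFallback Logical, `TRUE` if the gamma-family fit failed and the
#'   median per-gene dispersion was used as a flat fallback.
#' @seealso [estimateDispersionBlind()], [dispersionAt()], [vstTransform()]
#' @export
setClass("DispersionFit",
  representation(perGeneAlpha = "numeric", baseMeans = "numeric",
                 fitParams = "numeric", mode = "character",
                 fitFallback = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fitParams) != 2L || any(!is.finite(object@fitParams)))
      msg <- c(msg, "fitParams must be two finite numbers (a0, a1)")
    if (length(object@fitParams) == 2L && any(object@fitParams < 0))
      msg <- c(msg, "fitted (a0, a1) must be non-negative")
    if (!identical(object@mode, "blind"))
      msg <- c(msg, "only 'blind' dispersion mode is supported")
    if (is.null(msg)) TRUE else msg
  })

#' PairwiseDEResults: exact-test results for all time-point pairs
#'
#' One table per unordered pair of time points, each with per-gene base
#' means, log2 fold change (infinite when one side is zero), exact-test
#' p-value, Benjamini-Hochberg adjusted p-value, and a significance flag at
#' the configured level.
#'
#' @slot results Named list of `DataFrame`s, one per comparison, named
#'   `"tA_vs_tB"` in days.
#' @slot comparisons Two-column matrix of the compared times (days).
#' @slot alpha Significance level applied to the adjusted p-values.
#' @slot grid The [TimeGrid-class] the comparisons cover.
#' @slot fit The [DispersionFit-class] used by the tests.
#' @slot sizeFactors Per-sample size factors used for normalization.
#' @slot droppedGenes Character vector of genes with zero counts at every
#'   time point, excluded before testing.
#' @seealso [pairwiseDE()], [deUnion()], [comparisonMatrix()]
#' @export
setClass("PairwiseDEResults",
  representation(results = "list", comparisons = "matrix", alpha = "numeric",
                 grid = "TimeGrid", fit = "DispersionFit",
                 sizeFactors = "numeric", droppedGenes = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must be in (0, 1)")
    if (nrow(object@comparisons) != length(object@results))
      msg <- c(msg, "one comparison row per result table required")
    if (is.null(msg)) TRUE else msg
  })

#' ClusterModel: a fitted time-weighted K-means solution
#'
#' @slot K Number of clusters.
#' @slot assignments Named integer vector, cluster id in `1..K` per profile.
#' @slot centroids `K x n_timepoints` matrix of cluster centres on the
#'   expression (VST) scale.
#' @slot inertia Total weighted within-cluster sum of squared distances.
#' @slot weights The [TimeWeights-class] used in the distance.
#' @slot seed Integer seed the fit was started from.
#' @slot nIter Lloyd iterations used by the best restart.
#' @slot converged Logical, whether the best restart converged before the
#'   iteration cap.
#' @seealso [fitTimeKmeans()], [clusterReport()], [classifyModel()]
#' @export
setClass("ClusterModel",
  representation(K = "integer", assignments = "integer",
                 centroids = "matrix", inertia = "numeric",
                 weights = "TimeWeights", seed = "integer",
                 nIter = "integer", converged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (length(object@assignments) &&
        (min(object@assignments) < 1L || max(object@assignments) > object@K))
      msg <- c(msg, "assignments must lie in 1..K")
    if (nrow(object@centroids) != object@K)
      msg <- c(msg, "need one centroid row per cluster")
    if (any(!is.finite(object@centroids)))
      msg <- c(msg, "centroids must be finite")
    if (object@inertia < 0) msg <- c(msg, "inertia must be non-negative")
    if (is.null(msg)) TRUE else msg
  })
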