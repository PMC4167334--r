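#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on the Euclidean distances between sample columns of a
#' variance-stabilized expression matrix: the squared-distance matrix is
#' double-centred and the top eigenvectors, scaled by the square root of
#' their eigenvalues, give the embedding.
#'
#' @param vst Matrix of variance-stabilized values (genes x samples), as
#'   produced by [vstTransform()].
#' @param dims Number of embedding dimensions (default 2).
#' @return List with `points` (samples x dims coordinates) and `eig` (all
#'   eigenvalues of the double-centred matrix).
#' @export
mdsEmbedding <- function(vst, dims = 2L) {
  vst <- as.matrix(vst)
  if (ncol(vst) < dims + 1L)
    stop("need at least dims + 1 = ", dims + 1L, " samples for a ", dims,
         "-dimensional embedding")
  d <- stats::dist(t(vst))
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  pts <- fit$points
  # a configuration lying in fewer than `dims` dimensions returns fewer
  # columns; pad with zero coordinates
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(points = pts, eig = fit$eig)
}

#' Fisher's exact term enrichment
#'
#' For each annotation term, tests over- or under-representation of the
#' term among a study gene set relative to a universe, with a two-sided
#' Fisher's exact test on the 2x2 table (in study x carries term). Terms
#' annotated to no gene of the universe are skipped.
#'
#' @param study Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector of gene ids.
#' @param annotation Named list mapping gene id to a character vector of
#'   term ids (empty vectors allowed), or a two-column data frame
#'   (gene, term).
#' @param cutoff Raw p-value significance cutoff (default 0.01).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param adjust If `TRUE`, additionally reports BH-adjusted p-values and
#'   flags enrichment on those.
#' @return Data frame with one row per term: study/universe counts and
#'   sizes, odds ratio, `pval`, `enriched`, and `direction` (`"over"` when
#'   the odds ratio exceeds 1).
#' @export
fisherEnrichment <- function(study, universe, annotation, cutoff = 0.01,
                             alternative = c("two.sided", "greater", "less"),
                             adjust = FALSE) {
  alternative <- match.arg(alternative)
  study <- unique(study)
  universe <- unique(universe)
  if (!all(study %in% universe))
    stop("the study set must be a subset of the universe")
  ann <- .annotationList(annotation)
  ann <- ann[names(ann) %in% universe]
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  if (!length(terms)) {
    message("no annotation term covers the universe; nothing to test")
    return(data.frame(term = character(), studyCount = integer(),
                      studySize = integer(), universeCount = integer(),
                      universeSize = integer(), oddsRatio = numeric(),
                      pval = numeric(), enriched = logical(),
                      direction = character()))
  }
  nStudy <- length(study)
  nUniv <- length(universe)
  geneHasTerm <- function(term) names(ann)[vapply(ann, function(ts)
    term %in% ts, logical(1))]
  rows <- lapply(terms, function(term) {
    withTerm <- geneHasTerm(term)
    a <- sum(study %in% withTerm)            # study, term
    b <- nStudy - a                          # study, no term
    cc <- length(withTerm) - a               # rest, term
    dd <- (nUniv - nStudy) - cc              # rest, no term
    ft <- stats::fisher.test(matrix(c(a, b, cc, dd), 2L, byrow = TRUE),
                             alternative = alternative)
    expected <- nStudy * length(withTerm) / nUniv
    data.frame(term = term, studyCount = a, studySize = nStudy,
               universeCount = length(withTerm), universeSize = nUniv,
               oddsRatio = unname(ft$estimate), pval = ft$p.value,
               direction = if (a >= expected) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj <- bhAdjust(out$pval)
    out$enriched <- out$padj < cutoff
  } else {
    out$enriched <- out$pval < cutoff
  }
  out[order(out$pval), ]
}

.annotationList <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(ncol(annotation) >= 2L)
    return(split(as.character(annotation[[2L]]),
                 as.character(annotation[[1L]])))
  }
  stopifnot(is.list(annotation), !is.null(names(annotation)))
  annotation
}

#' Common and specific genes across named DE sets
#'
#' Pairwise intersection and difference sizes across named gene sets (for
#' example the DE unions of two tissues or genotypes).
#'
#' @param sets Named list of at least two character vectors.
#' @return Data frame with one row per unordered pair: set names, set
#'   sizes, `common`, `specificA`, `specificB`. Inclusion-exclusion holds
#'   exactly: `sizeA = common + specificA`.
#' @export
overlapSummary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  pairs <- utils::combn(names(sets), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    common <- length(intersect(sets[[a]], sets[[b]]))
    data.frame(setA = a, setB = b, sizeA = length(sets[[a]]),
               sizeB = length(sets[[b]]), common = common,
               specificA = length(sets[[a]]) - common,
               specificB = length(sets[[b]]) - common,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-pair differential-expression counts
#'
#' Symmetric time-point x time-point table of the number of genes called
#' significant in each pairwise comparison.
#'
#' @param object A [PairwiseDEResults-class].
#' @return Symmetric integer matrix with zero diagonal, one row/column per
#'   time point.
#' @rdname comparisonMatrix
#' @export
setMethod("comparisonMatrix", "PairwiseDEResults", function(object) {
  times <- gridTimes(object@grid)
  n <- length(times)
  m <- matrix(0L, n, n, dimnames = list(sprintf("d%g", times),
                                        sprintf("d%g", times)))
  for (j in seq_along(object@results)) {
    iA <- match(object@comparisons[j, 1L], times)
    iB <- match(object@comparisons[j, 2L], times)
    nSig <- sum(object@results[[j]]$significant)
    m[iA, iB] <- m[iB, iA] <- nSig
  }
  m
})
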