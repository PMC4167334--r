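#' Construct a TimecourseExperiment from a count matrix and sample sheet
#'
#' @param counts Integer matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames matching the sample sheet.
#' @param sampleData Data frame (or `DataFrame`) with columns `sample`,
#'   `genotype`, `tissue`, `time_days`, `phase`, one row per count column.
#' @return A validated [TimecourseExperiment-class].
#' @export
TimecourseExperiment <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  sampleData <- S4Vectors::DataFrame(sampleData)
  if (is.null(rownames(sampleData)) ||
      all(rownames(sampleData) == as.character(seq_len(nrow(sampleData)))))
    rownames(sampleData) <- sampleData$sample
  missing <- setdiff(colnames(counts), rownames(sampleData))
  if (length(missing))
    stop("sample sheet lacks sample(s): ", paste(missing, collapse = ", "))
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts), colData = sampleData)
  new("TimecourseExperiment", se)
}

#' Read a count matrix and sample sheet from TSV
#'
#' The counts file must be tab-separated with a header row of sample names
#' and gene identifiers in the first column. Duplicate gene ids, negative
#' or non-integer counts are rejected with the offending line (or cell)
#' named.
#'
#' @param countsPath Path to the counts TSV.
#' @param samplesPath Path to the sample sheet TSV (columns `sample`,
#'   `genotype`, `tissue`, `time_days`, `phase`).
#' @return A [TimecourseExperiment-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(countsPath, samplesPath) {
  tab <- utils::read.delim(countsPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no genes in counts file '", countsPath, "'")
  geneIds <- as.character(tab[[1L]])
  dup <- which(duplicated(geneIds))
  if (length(dup))
    stop("duplicate gene id '", geneIds[dup[1L]], "' at line ",
         dup[1L] + 1L, " of '", countsPath, "'")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count '", mat[bad[1L, 1L], bad[1L, 2L]], "' for gene '",
         geneIds[bad[1L, 1L]], "', sample '", colnames(mat)[bad[1L, 2L]],
         "' (line ", bad[1L, 1L] + 1L, ")")
  storage.mode(mat) <- "integer"
  rownames(mat) <- geneIds
  samples <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  TimecourseExperiment(mat, samples)
}

#' Write a TimecourseExperiment to TSV
#'
#' Writes the counts matrix (first column `gene`), the sample sheet and,
#' for simulated data, the planted truth, with a JSON metadata sidecar.
#' [readCounts()] inverts the counts + sample sheet pair losslessly.
#'
#' @param x A [TimecourseExperiment-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
writeCounts <- function(x, dir, prefix = "timecourse") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  countsPath <- file.path(dir, paste0(prefix, "_counts.tsv"))
  samplesPath <- file.path(dir, paste0(prefix, "_samples.tsv"))
  .writeTsv(data.frame(gene = rownames(x),
                       SummarizedExperiment::assay(x, "counts"),
                       check.names = FALSE), countsPath)
  .writeTsv(as.data.frame(SummarizedExperiment::colData(x)), samplesPath)
  paths <- c(counts = countsPath, samples = samplesPath)
  rd <- SummarizedExperiment::rowData(x)
  if ("planted_label" %in% colnames(rd)) {
    truthPath <- file.path(dir, paste0(prefix, "_truth.tsv"))
    .writeTsv(data.frame(gene = rownames(x),
                         planted_label = rd$planted_label,
                         is_null = rd$is_null), truthPath)
    paths <- c(paths, truth = truthPath)
  }
  meta <- S4Vectors::metadata(x)
  metaPath <- file.path(dir, paste0(prefix, "_meta.json"))
  .writeJson(.serializableMeta(meta), metaPath)
  invisible(c(paths, meta = metaPath))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

.serializableMeta <- function(meta) {
  lapply(meta, function(m) {
    if (inherits(m, "SimulationConfig")) {
      m$grid <- list(times = gridTimes(m$grid), phases = gridPhases(m$grid),
                     tissue = gridTissue(m$grid))
      unclass(m)
    } else m
  })
}

#' Read and write gene sets (one id per line)
#'
#' @param path File path.
#' @return `readGeneSet` a character vector.
#' @export
readGeneSet <- function(path) {
  out <- readLines(path)
  out[nzchar(out)]
}

#' @rdname readGeneSet
#' @param genes Character vector of gene ids.
#' @export
writeGeneSet <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' A two-column TSV (`gene`, `term`), one term per row; genes may repeat.
#'
#' @param path File path.
#' @return Named list mapping gene id to its character vector of terms.
#' @export
readAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .annotationList(tab)
}

#' Write the per-comparison differential-expression tables
#'
#' One TSV per pairwise comparison, plus the union gene set and a JSON
#' metadata sidecar (significance level, dispersion-fit parameters, size
#' factors, dropped genes).
#'
#' @param de A [PairwiseDEResults-class].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
writeDEResults <- function(de, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(de@results)) {
    p <- file.path(dir, paste0("de_", nm, ".tsv"))
    .writeTsv(as.data.frame(de@results[[nm]]), p)
    paths <- c(paths, p)
  }
  unionPath <- file.path(dir, "de_union.txt")
  writeGeneSet(deUnion(de), unionPath)
  metaPath <- file.path(dir, "de_meta.json")
  .writeJson(list(alpha = de@alpha,
                  dispersion_fit = list(a0 = de@fit@fitParams[1],
                                        a1 = de@fit@fitParams[2],
                                        mode = de@fit@mode,
                                        fallback = de@fit@fitFallback),
                  size_factors = as.list(de@sizeFactors),
                  n_dropped_genes = length(de@droppedGenes),
                  dropped_genes = de@droppedGenes), metaPath)
  invisible(c(paths, union = unionPath, meta = metaPath))
}

#' Write a fitted cluster model
#'
#' Assignments TSV (gene, cluster), centroid TSV (cluster, size, one column
#' per time point) and a model JSON (K, seed, inertia, weights,
#' convergence).
#'
#' @param model A [ClusterModel-class].
#' @param dir Output directory.
#' @param labels Optional centroid classification (from [classifyModel()]),
#'   written alongside.
#' @return Invisibly, the paths written.
#' @export
writeClusterModel <- function(model, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- clusterReport(model)
  aPath <- file.path(dir, "cluster_assignments.tsv")
  cPath <- file.path(dir, "cluster_centroids.tsv")
  .writeTsv(rep$assignments, aPath)
  .writeTsv(rep$centroids, cPath)
  mPath <- file.path(dir, "cluster_model.json")
  .writeJson(list(K = model@K, seed = model@seed, inertia = model@inertia,
                  n_iter = model@nIter, converged = model@converged,
                  time_weights = as.list(stats::setNames(
                    model@weights@weights,
                    sprintf("d%g", gridTimes(model@weights@grid))))),
             mPath)
  paths <- c(assignments = aPath, centroids = cPath, model = mPath)
  if (!is.null(labels)) {
    lPath <- file.path(dir, "cluster_labels.tsv")
    .writeTsv(labels, lPath)
    paths <- c(paths, labels = lPath)
  }
  invisible(paths)
}

#' Read back a cluster report
#'
#' @param dir Directory written by [writeClusterModel()].
#' @return List with `assignments` and `centroids` data frames.
#' @export
readClusterReport <- function(dir) {
  list(assignments = utils::read.delim(
         file.path(dir, "cluster_assignments.tsv"),
         stringsAsFactors = FALSE),
       centroids = utils::read.delim(
         file.path(dir, "cluster_centroids.tsv"), check.names = FALSE,
         stringsAsFactors = FALSE))
}
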