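#' Configuration for an end-to-end run
#'
#' @param counts,samples Paths to the counts and sample-sheet TSVs; leave
#'   `NULL` to simulate instead (the `simulate` stage must then be on).
#' @param annotation Optional path to a gene-to-term annotation TSV; the
#'   `enrich` stage is skipped without one.
#' @param outdir Output directory.
#' @param stages Character vector of stages to run, in any order; executed
#'   in dependency order. Available: `simulate`, `de`, `vst`, `mds`,
#'   `cluster`, `classify`, `enrich`, `report`.
#' @param alpha Significance level for the DE stage.
#' @param K Number of clusters; defaults to 50 on a leaf grid and 25 on a
#'   meristem grid when `NULL`.
#' @param tau Classifier activation threshold.
#' @param seed Integer seed driving every stochastic stage.
#' @param simulation A [simulationConfig()] for the `simulate` stage;
#'   a default configuration (with this `seed`) when `NULL`.
#' @param nRestarts K-means restarts.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(counts = NULL, samples = NULL, annotation = NULL,
                      outdir = "vernclust_out",
                      stages = c("simulate", "de", "vst", "mds", "cluster",
                                 "classify", "enrich", "report"),
                      alpha = 0.05, K = NULL, tau = 1, seed = 1L,
                      simulation = NULL, nRestarts = 10L) {
  known <- c("simulate", "de", "vst", "mds", "cluster", "classify",
             "enrich", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"simulate" %in% stages && (is.null(counts) || is.null(samples)))
    stop("without the simulate stage, counts and samples paths are required")
  if (!is.null(counts) && !file.exists(counts))
    stop("counts file does not exist: ", counts)
  if (!is.null(samples) && !file.exists(samples))
    stop("sample sheet does not exist: ", samples)
  if (!is.null(annotation) && !file.exists(annotation))
    stop("annotation file does not exist: ", annotation)
  structure(list(counts = counts, samples = samples, annotation = annotation,
                 outdir = outdir, stages = stages, alpha = alpha, K = K,
                 tau = tau, seed = as.integer(seed), simulation = simulation,
                 nRestarts = as.integer(nRestarts)),
            class = "RunConfig")
}

#' Run the full analysis chain
#'
#' Executes the enabled stages in dependency order: simulate (or read)
#' counts, pairwise differential expression, variance stabilization, MDS,
#' time-weighted K-means on the DE union set, centroid classification,
#' term enrichment of the DE union against all genes, and summary reports.
#' A stage whose prerequisite is disabled is skipped with a notice. All
#' randomness flows from the configured seed, so a rerun with the same
#' configuration reproduces every data output byte-identically; timings go
#' to a separate log file (`run.log`) to keep the data outputs
#' deterministic.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the run metadata and the in-memory stage
#'   results (`tce`, `de`, `vst`, `mds`, `model`, `labels`, `enrichment`).
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  clock <- function(name, expr) {
    tA <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - tA, 3)
    out
  }
  enabled <- function(s) s %in% config$stages
  skipNote <- function(s, why) message("stage '", s, "' skipped: ", why)
  res <- list()

  if (enabled("simulate")) {
    sim <- config$simulation
    if (is.null(sim)) sim <- simulationConfig(seed = config$seed)
    res$tce <- clock("simulate", simulateTimecourse(sim))
    writeCounts(res$tce, config$outdir, "simulated")
  } else {
    res$tce <- clock("read", readCounts(config$counts, config$samples))
  }
  tce <- res$tce
  grid <- timeGrid(tce)

  if (enabled("de")) {
    res$de <- clock("de", pairwiseDE(tce, alpha = config$alpha))
    writeDEResults(res$de, config$outdir)
  }

  if (enabled("vst")) {
    fit <- if (!is.null(res$de)) res$de@fit else NULL
    sf <- if (!is.null(res$de)) res$de@sizeFactors else NULL
    res$vst <- clock("vst", vstTransform(tce, sizeFactors = sf, fit = fit))
    .writeTsv(data.frame(gene = rownames(res$vst), res$vst,
                         check.names = FALSE),
              file.path(config$outdir, "vst.tsv"))
  }

  if (enabled("mds")) {
    if (is.null(res$vst)) skipNote("mds", "requires the vst stage")
    else {
      res$mds <- clock("mds", mdsEmbedding(res$vst))
      .writeTsv(data.frame(sample = rownames(res$mds$points),
                           res$mds$points, check.names = FALSE),
                file.path(config$outdir, "mds.tsv"))
    }
  }

  if (enabled("cluster")) {
    if (is.null(res$de) || is.null(res$vst))
      skipNote("cluster", "requires the de and vst stages")
    else {
      genes <- deUnion(res$de)
      if (length(genes) < 2L)
        skipNote("cluster", "fewer than 2 genes in the DE union")
      else {
        K <- config$K
        if (is.null(K)) K <- if (gridTissue(grid) == "leaf") 50L else 25L
        K <- min(K, length(genes))
        res$model <- clock("cluster", fitTimeKmeans(
          res$vst[genes, , drop = FALSE], grid, K = K, seed = config$seed,
          nRestarts = config$nRestarts))
      }
    }
  }

  if (enabled("classify")) {
    if (is.null(res$model))
      skipNote("classify", "requires the cluster stage")
    else
      res$labels <- clock("classify", classifyModel(
        res$model, grid, classifierConfig(tau = config$tau)))
  }
  if (!is.null(res$model))
    writeClusterModel(res$model, config$outdir, labels = res$labels)

  if (enabled("enrich")) {
    if (is.null(config$annotation))
      skipNote("enrich", "no annotation table configured")
    else if (is.null(res$de))
      skipNote("enrich", "requires the de stage")
    else {
      ann <- readAnnotation(config$annotation)
      res$enrichment <- clock("enrich", fisherEnrichment(
        deUnion(res$de), rownames(tce), ann))
      .writeTsv(res$enrichment, file.path(config$outdir, "enrichment.tsv"))
    }
  }

  if (enabled("report")) {
    if (!is.null(res$de)) {
      cm <- comparisonMatrix(res$de)
      .writeTsv(data.frame(time = rownames(cm), cm, check.names = FALSE),
                file.path(config$outdir, "comparison_matrix.tsv"))
    }
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("vernclust")),
    seed = config$seed,
    stages_run = intersect(c("simulate", "de", "vst", "mds", "cluster",
                             "classify", "enrich", "report"),
                           config$stages),
    alpha = config$alpha, tau = config$tau,
    K = if (!is.null(res$model)) res$model@K else config$K,
    n_genes = nrow(tce), n_samples = ncol(tce),
    n_de_union = if (!is.null(res$de)) length(deUnion(res$de)) else NULL,
    n_dropped_genes = if (!is.null(res$de))
      length(res$de@droppedGenes) else NULL)
  .writeJson(meta, file.path(config$outdir, "run_meta.json"))
  writeLines(c(sprintf("total_elapsed_s\t%.3f",
                       proc.time()[["elapsed"]] - t0),
               sprintf("%s\t%.3f", names(timings), unlist(timings))),
             file.path(config$outdir, "run.log"))
  res$metadata <- meta
  invisible(res)
}
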