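#' Expression-profile archetype labels
#'
#' The closed vocabulary of interpretive profile classes: transient stress
#' response (spike up or down at the first cold or first long-day point),
#' cold acclimation (up throughout cold, back down at long days), gradual
#' and late vernalization responses (up or down), long-day-specific
#' regulation, flat null, and unclassified.
#'
#' @return Character vector of the eleven labels.
#' @export
profileLabels <- function() {
  c("transient_stress_up", "transient_stress_down", "cold_acclimation",
    "gradual_vern_up", "late_vern_up", "gradual_vern_down", "late_vern_down",
    "long_day_up", "long_day_down", "null_flat", "unclassified")
}

#' Default archetype shapes on a sampling grid
#'
#' Per-time-point multiplier patterns on the log2 scale, anchored at the
#' grid's baseline point (value 0 there). A gene of archetype `a` with
#' baseline `b` and effect size `d` (log2 units) has planted log2 mean
#' `b + d * shape_a`. The five-point leaf grid carries all nine responsive
#' classes; the three-point meristem grid (no pre-vernalization sample)
#' supports only the transient one-long-day spike and long-day classes.
#'
#' @param grid A [TimeGrid-class].
#' @return Named list of numeric shape vectors, one per available archetype.
#' @examples
#' archetypeShapes(leafTimeGrid())$cold_acclimation  # 0 1 1 1 0
#' @export
archetypeShapes <- function(grid) {
  stopifnot(is(grid, "TimeGrid"))
  if (gridTissue(grid) == "leaf") {
    if (length(gridTimes(grid)) != 5L)
      stop("default leaf shapes are defined on the 5-point leaf grid")
    list(
      transient_stress_up   = c(0, 1, 0, 0, 0),
      transient_stress_down = c(0, -1, 0, 0, 0),
      cold_acclimation      = c(0, 1, 1, 1, 0),
      gradual_vern_up       = c(0, 0.15, 0.6, 1, 1),
      late_vern_up          = c(0, 0, 0.1, 1, 1),
      gradual_vern_down     = c(0, -0.15, -0.6, -1, -1),
      late_vern_down        = c(0, 0, -0.1, -1, -1),
      long_day_up           = c(0, 0, 0, 0, 1),
      long_day_down         = c(0, 0, 0, 0, -1),
      null_flat             = c(0, 0, 0, 0, 0))
  } else {
    if (length(gridTimes(grid)) != 3L)
      stop("default meristem shapes are defined on the 3-point meristem grid")
    list(
      transient_stress_up   = c(0, 1, 0),
      transient_stress_down = c(0, -1, 0),
      long_day_up           = c(0, 0, 1),
      long_day_down         = c(0, 0, -1),
      null_flat             = c(0, 0, 0))
  }
}

#' Planted log2 mean profile of one archetype
#'
#' @param label Archetype label (see [profileLabels()]).
#' @param grid A [TimeGrid-class].
#' @param baselineLog2 Log2 mean expression at the baseline point.
#' @param deltaLog2 Non-negative effect size in log2 units.
#' @param shape Optional per-time-point multiplier pattern; defaults to the
#'   grid's default shape for `label`.
#' @return Numeric vector, `baselineLog2 + deltaLog2 * shape`, one value per
#'   grid point. `null_flat` returns the constant baseline.
#' @examples
#' archetypeProfile("cold_acclimation", leafTimeGrid(), 5, 2)  # 5 7 7 7 5
#' @export
archetypeProfile <- function(label, grid, baselineLog2, deltaLog2,
                             shape = NULL) {
  if (is.null(shape)) {
    shapes <- archetypeShapes(grid)
    if (!label %in% names(shapes))
      stop("no default shape for archetype '", label, "' on a ",
           gridTissue(grid), " grid")
    shape <- shapes[[label]]
  }
  if (length(shape) != length(gridTimes(grid)))
    stop("shape length (", length(shape), ") does not match grid length (",
         length(gridTimes(grid)), ")")
  if (deltaLog2 < 0) stop("deltaLog2 must be >= 0")
  if (identical(label, "null_flat"))
    return(rep(baselineLog2, length(shape)))
  baselineLog2 + deltaLog2 * shape
}

#' Simulation configuration for a synthetic time course
#'
#' Bundles everything [simulateTimecourse()] needs: the sampling grid, the
#' number of genes, the archetype mixture, the negative binomial dispersion
#' model `alpha(mu) = a0 + a1/mu`, the spread of library size factors, the
#' baseline-expression range and the common effect size.
#'
#' @param grid A [TimeGrid-class]; defaults to the leaf schedule.
#' @param nGenes Number of genes to simulate.
#' @param archetypeMix Named numeric vector of proportions (summing to 1)
#'   over archetype labels available on `grid`. The default plants 90%
#'   flat null genes and spreads the remaining 10% evenly over the
#'   responsive classes, matching the few-percent-to-ten-percent
#'   responsive fractions typical of bulk RNA-seq treatment contrasts.
#' @param dispersionParams `c(a0, a1)` of the dispersion model; the default
#'   `c(0.02, 2)` gives a 14% asymptotic coefficient of variation plus
#'   extra-Poisson noise at low counts, typical of bulk RNA-seq libraries.
#' @param sizeFactorSd Standard deviation of the log-normal per-sample
#'   library scaling (natural-log scale); 0 plants all size factors at 1.
#' @param baselineLog2Range Range the per-gene baseline log2 mean is drawn
#'   from, uniformly.
#' @param deltaLog2 Effect size, in log2 units, applied to every responsive
#'   gene (a 4-fold change at the default 2).
#' @param nReplicates Libraries per time point; the study design has 1.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   full configuration and seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(grid = leafTimeGrid(), nGenes = 2000L,
                             archetypeMix = NULL,
                             dispersionParams = c(a0 = 0.02, a1 = 2),
                             sizeFactorSd = 0.15,
                             baselineLog2Range = c(6, 10),
                             deltaLog2 = 2, nReplicates = 1L, seed = 1L) {
  if (is.null(archetypeMix)) {
    labs <- setdiff(names(archetypeShapes(grid)), "null_flat")
    archetypeMix <- c(stats::setNames(rep(0.1 / length(labs), length(labs)),
                                      labs),
                      null_flat = 0.9)
  }
  if (abs(sum(archetypeMix) - 1) > 1e-9)
    stop("archetypeMix proportions must sum to 1")
  if (any(archetypeMix < 0)) stop("archetypeMix proportions must be >= 0")
  bad <- setdiff(names(archetypeMix), names(archetypeShapes(grid)))
  if (length(bad))
    stop("archetypeMix labels not available on this grid: ",
         paste(bad, collapse = ", "))
  if (nGenes < 1L) stop("nGenes must be >= 1")
  if (length(dispersionParams) != 2L || any(dispersionParams < 0))
    stop("dispersionParams must be two non-negative numbers (a0, a1)")
  if (sizeFactorSd < 0) stop("sizeFactorSd must be >= 0")
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  structure(list(grid = grid, nGenes = as.integer(nGenes),
                 archetypeMix = archetypeMix,
                 dispersionParams = unname(dispersionParams),
                 sizeFactorSd = sizeFactorSd,
                 baselineLog2Range = baselineLog2Range,
                 deltaLog2 = deltaLog2,
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a negative binomial time-course count matrix
#'
#' Draws, per gene, an archetype label from the configured mixture, a
#' uniform baseline log2 mean, and then per-library counts
#' `K ~ NB(mean = s_j * 2^m(t_j), var = mu + alpha(mu) * mu^2)` with
#' `alpha(mu) = a0 + a1/mu` and log-normal size factors `s_j`. With
#' `a0 = a1 = 0` the counts are Poisson.
#'
#' @param config A `SimulationConfig` from [simulationConfig()].
#' @param genotype Genotype label recorded in the sample metadata.
#' @return A [TimecourseExperiment-class] whose `rowData` carries the
#'   planted truth (`planted_label`, `is_null`), whose `planted_mean` assay
#'   holds the planted per-library means, and whose metadata records the
#'   configuration and planted size factors.
#' @examples
#' tce <- simulateTimecourse(simulationConfig(nGenes = 50, seed = 7))
#' table(SummarizedExperiment::rowData(tce)$planted_label)
#' @export
simulateTimecourse <- function(config, genotype = "synthetic") {
  stopifnot(inherits(config, "SimulationConfig"))
  grid <- config$grid
  nT <- length(gridTimes(grid))
  nS <- nT * config$nReplicates
  a0 <- config$dispersionParams[1]
  a1 <- config$dispersionParams[2]
  shapes <- archetypeShapes(grid)

  withr::with_seed(config$seed, {
    labels <- sample(names(config$archetypeMix), config$nGenes,
                     replace = TRUE, prob = config$archetypeMix)
    baselines <- stats::runif(config$nGenes, config$baselineLog2Range[1],
                              config$baselineLog2Range[2])
    sizeFactors <- if (config$sizeFactorSd > 0)
      exp(stats::rnorm(nS, 0, config$sizeFactorSd)) else rep(1, nS)

    log2means <- t(vapply(seq_len(config$nGenes), function(g) {
      archetypeProfile(labels[g], grid, baselines[g], config$deltaLog2,
                       shape = shapes[[labels[g]]])
    }, numeric(nT)))
    # one column per library: replicate the time profile across replicates
    repIdx <- rep(seq_len(nT), each = config$nReplicates)
    mu <- 2^log2means[, repIdx, drop = FALSE] *
      matrix(sizeFactors, config$nGenes, nS, byrow = TRUE)
    counts <- matrix(0L, config$nGenes, nS)
    if (a0 == 0 && a1 == 0) {
      counts[] <- as.integer(stats::rpois(length(mu), mu))
    } else {
      size <- mu / (a1 + a0 * mu)
      counts[] <- as.integer(stats::rnbinom(length(mu), mu = mu, size = size))
    }
  })

  geneIds <- sprintf("gene_%05d", seq_len(config$nGenes))
  sampleNames <- if (config$nReplicates == 1L) {
    sprintf("%s_d%g", gridTissue(grid), gridTimes(grid))
  } else {
    sprintf("%s_d%g_r%d", gridTissue(grid), gridTimes(grid)[repIdx],
            sequence(rep(config$nReplicates, nT)))
  }
  dimnames(counts) <- list(geneIds, sampleNames)
  dimnames(mu) <- dimnames(counts)

  colData <- S4Vectors::DataFrame(
    sample = sampleNames, genotype = genotype, tissue = gridTissue(grid),
    time_days = gridTimes(grid)[repIdx], phase = gridPhases(grid)[repIdx],
    row.names = sampleNames)
  rowData <- S4Vectors::DataFrame(
    planted_label = labels, is_null = labels == "null_flat",
    baseline_log2 = baselines, row.names = geneIds)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts, planted_mean = mu),
    colData = colData, rowData = rowData)
  S4Vectors::metadata(se)$config <- config
  S4Vectors::metadata(se)$planted_size_factors <-
    stats::setNames(sizeFactors, sampleNames)
  new("TimecourseExperiment", se)
}

#' Planted truth table of a simulated time course
#'
#' @param x A simulated [TimecourseExperiment-class].
#' @return A `DataFrame` with one row per gene: `planted_label`, `is_null`,
#'   and the planted per-library means.
#' @export
plantedTruth <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"planted_label" %in% colnames(rd))
    stop("object carries no planted truth (not a simulated time course?)")
  out <- rd[, c("planted_label", "is_null"), drop = FALSE]
  out$planted_mean <- SummarizedExperiment::assay(x, "planted_mean")
  out
}
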