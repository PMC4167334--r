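#' Classifier configuration
#'
#' @param tau Activation threshold in within-centroid standard-deviation
#'   units; a phase must depart from the baseline by at least `tau` z-units
#'   to count as regulated, and stay within `tau/2` to count as quiet.
#' @param roles Optional character vector of phase roles (one of
#'   `baseline`, `early`, `mid`, `late`, `long_day` per grid point);
#'   derived from the grid by [phaseRoles()] when `NULL`.
#' @return A list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(tau = 1, roles = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  structure(list(tau = tau, roles = roles), class = "ClassifierConfig")
}

#' Standardize a centroid to z-units
#'
#' `(c - mean(c)) / sd(c)`; a constant centroid returns all zeros (and is
#' classified `null_flat`).
#'
#' @param centroid Numeric vector of length >= 2.
#' @return Z-scored profile of the same length.
#' @export
standardizeCentroid <- function(centroid) {
  stopifnot(length(centroid) >= 2L)
  s <- stats::sd(centroid)
  if (!is.finite(s) || s == 0) return(rep(0, length(centroid)))
  (centroid - mean(centroid)) / s
}

#' Classify a cluster centroid into an expression-profile archetype
#'
#' Formalizes the interpretive reading of time-course cluster profiles.
#' The centroid is z-scored, and per-phase departures from the baseline
#' point, `d_role = z_role - z_baseline`, are thresholded at `tau`
#' (activation) and `tau/2` (quiescence). Rules are evaluated in a fixed
#' order, first match wins:
#'
#' 1. `transient_stress_up`: up at the early point only
#'    (`d_early >= tau`, mid and late quiet).
#' 2. `cold_acclimation`: up throughout the cold
#'    (`d_early, d_mid, d_late >= tau`), back near baseline at long days.
#' 3. `gradual_vern_up`: progressive rise through vernalization
#'    (`d_late >= tau`, `d_mid >= tau/2`, early quiet), maintained into
#'    long days.
#' 4. `late_vern_up`: rise only late in the cold
#'    (`d_late >= tau`, early and mid quiet).
#' 5. `long_day_up`: up only after the shift to long days.
#' 6. The mirrored `_down` classes (thresholds negated), same internal
#'    order.
#' 7. `null_flat` for constant centroids; otherwise `unclassified`.
#'
#' A rule whose activation requirement refers to a phase the grid does not
#' sample (e.g. mid-cold on the meristem grid) is not applicable;
#' quiescence constraints on missing phases hold vacuously. Where a role is
#' sampled more than once, the mean z-value of its points is used.
#'
#' @param centroid Numeric centroid, one value per grid point.
#' @param grid The [TimeGrid-class] the centroid lives on.
#' @param cfg A [classifierConfig()].
#' @return One label from [profileLabels()].
#' @examples
#' classifyCentroid(c(0, 3, 3, 3, 0), leafTimeGrid())  # cold_acclimation
#' @export
classifyCentroid <- function(centroid, grid, cfg = classifierConfig()) {
  if (length(centroid) != length(gridTimes(grid)))
    stop("centroid length (", length(centroid),
         ") does not match grid length (", length(gridTimes(grid)), ")")
  z <- standardizeCentroid(centroid)
  if (all(z == 0)) return("null_flat")
  roles <- if (!is.null(cfg$roles)) cfg$roles else phaseRoles(grid)
  if (length(roles) != length(centroid))
    stop("phase roles must cover the grid")
  zr <- function(role) {
    i <- which(roles == role)
    if (!length(i)) NA_real_ else mean(z[i])
  }
  zb <- zr("baseline")
  if (is.na(zb)) stop("grid has no baseline point")
  d <- c(early = zr("early") - zb, mid = zr("mid") - zb,
         late = zr("late") - zb, long_day = zr("long_day") - zb)
  tau <- cfg$tau

  # activation: the phase must exist and exceed the threshold;
  # quiescence: holds vacuously for phases the grid does not sample
  act <- function(x, thr) !is.na(x) && if (thr >= 0) x >= thr else x <= thr
  quiet <- function(x, halfwidth = tau / 2) is.na(x) || abs(x) < halfwidth
  quietAbove <- function(x) is.na(x) || x < tau / 2    # not activated upward
  quietBelow <- function(x) is.na(x) || x > -tau / 2   # not activated downward

  if (act(d["early"], tau) && quiet(d["mid"]) && quiet(d["late"]))
    return("transient_stress_up")
  if (act(d["early"], tau) && act(d["mid"], tau) && act(d["late"], tau) &&
      quietAbove(d["long_day"]))
    return("cold_acclimation")
  if (act(d["late"], tau) && act(d["mid"], tau / 2) &&
      quietAbove(d["early"]) && act(d["long_day"], tau / 2))
    return("gradual_vern_up")
  if (act(d["late"], tau) && quietAbove(d["early"]) && quietAbove(d["mid"]))
    return("late_vern_up")
  if (act(d["long_day"], tau) && quiet(d["early"]) && quiet(d["mid"]) &&
      quiet(d["late"]))
    return("long_day_up")
  if (act(d["early"], -tau) && quiet(d["mid"]) && quiet(d["late"]))
    return("transient_stress_down")
  if (act(d["late"], -tau) && act(d["mid"], -tau / 2) &&
      quietBelow(d["early"]) && act(d["long_day"], -tau / 2))
    return("gradual_vern_down")
  if (act(d["late"], -tau) && quietBelow(d["early"]) && quietBelow(d["mid"]))
    return("late_vern_down")
  if (act(d["long_day"], -tau) && quiet(d["early"]) && quiet(d["mid"]) &&
      quiet(d["late"]))
    return("long_day_down")
  "unclassified"
}

#' Classify every centroid of a fitted cluster model
#'
#' @param model A [ClusterModel-class].
#' @param grid The [TimeGrid-class] the model was fitted on.
#' @param cfg A [classifierConfig()].
#' @return Data frame with one row per cluster: `cluster`, `size`,
#'   `label`; the label counts are attached as attribute `"summary"`.
#' @rdname classifyModel
#' @export
setMethod("classifyModel", signature("ClusterModel", "TimeGrid"),
  function(model, grid, cfg = classifierConfig()) {
    labels <- apply(model@centroids, 1L, classifyCentroid, grid = grid,
                    cfg = cfg)
    out <- data.frame(cluster = seq_len(model@K),
                      size = tabulate(model@assignments, nbins = model@K),
                      label = unname(labels), stringsAsFactors = FALSE)
    attr(out, "summary") <- table(factor(out$label,
                                         levels = profileLabels()))
    out
  })
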