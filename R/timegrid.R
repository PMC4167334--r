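#' Construct a TimeGrid
#'
#' @param times Strictly increasing calendar times in days.
#' @param phases One induction-phase label per time point, each one of
#'   `"pre_induction"`, `"early_cold"`, `"mid_cold"`, `"late_cold"`,
#'   `"long_day"`.
#' @param tissue `"leaf"` or `"meristem"`.
#'
#' @return A [TimeGrid-class] object.
#' @examples
#' TimeGrid(c(0, 2, 28, 63, 70),
#'          c("pre_induction", "early_cold", "mid_cold", "late_cold",
#'            "long_day"), "leaf")
#' @export
TimeGrid <- function(times, phases, tissue = c("leaf", "meristem")) {
  tissue <- match.arg(tissue)
  new("TimeGrid", times = as.numeric(times), phases = as.character(phases),
      tissue = tissue)
}

#' Default sampling grids of the vernalization study design
#'
#' The leaf schedule samples before vernalization (day 0), after two days,
#' four weeks and nine weeks of cold (days 2, 28, 63), and after seven long
#' days of secondary induction (day 70). The enriched-meristem schedule
#' samples at nine weeks of vernalization (day 63) and after one and seven
#' long days (days 64, 70).
#'
#' @return A [TimeGrid-class].
#' @examples
#' gridTimes(leafTimeGrid())      # 0 2 28 63 70
#' gridTimes(meristemTimeGrid())  # 63 64 70
#' @export
leafTimeGrid <- function() {
  TimeGrid(c(0, 2, 28, 63, 70),
           c("pre_induction", "early_cold", "mid_cold", "late_cold",
             "long_day"),
           "leaf")
}

#' @rdname leafTimeGrid
#' @export
meristemTimeGrid <- function() {
  TimeGrid(c(63, 64, 70), c("late_cold", "long_day", "long_day"), "meristem")
}

#' TimeGrid accessors
#'
#' @param grid A [TimeGrid-class].
#' @return `gridTimes` the calendar days, `gridPhases` the phase labels,
#'   `gridTissue` the tissue.
#' @export
gridTimes <- function(grid) grid@times

#' @rdname gridTimes
#' @export
gridPhases <- function(grid) grid@phases

#' @rdname gridTimes
#' @export
gridTissue <- function(grid) grid@tissue

setMethod("show", "TimeGrid", function(object) {
  cat(sprintf("TimeGrid (%s): %d time points\n", object@tissue,
              length(object@times)))
  cat("  days  :", paste(format(object@times), collapse = " "), "\n")
  cat("  phase :", paste(object@phases, collapse = " "), "\n")
})

#' Map grid points to classifier phase roles
#'
#' Assigns each grid point one role among `baseline`, `early`, `mid`,
#' `late`, `long_day`. The baseline is the pre-induction point where one
#' exists; a meristem grid, which starts at nine weeks of vernalization,
#' uses its first point as baseline. When several points share the
#' `long_day` phase, the first is treated as the early (transient) point of
#' secondary induction and the last as the long-day endpoint.
#'
#' @param grid A [TimeGrid-class].
#' @return Character vector of roles, one per grid point.
#' @export
phaseRoles <- function(grid) {
  phases <- grid@phases
  n <- length(phases)
  roles <- character(n)
  roles[phases == "pre_induction"] <- "baseline"
  roles[phases == "early_cold"] <- "early"
  roles[phases == "mid_cold"] <- "mid"
  roles[phases == "late_cold"] <- "late"
  ld <- which(phases == "long_day")
  if (length(ld)) {
    roles[ld[length(ld)]] <- "long_day"
    if (length(ld) > 1L) roles[ld[-length(ld)]] <- "early"
  }
  if (!"baseline" %in% roles) {
    # no pre-induction sample: anchor at the first collection
    roles[1L] <- "baseline"
  }
  roles
}
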