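# Turntable acquisition planning: scenarios and camera-station plans.

#' Canonical imaging-parameter values
#'
#' The acquisition design varies three parameters: imaging style
#' (focus-stacked `"FS"` vs single-exposure `"NFS"`), horizontal step between
#' turntable positions (degrees), and the set of vertical tilt rings. The base
#' turntable step is 11.25 degrees, giving 32 stations per full ring; coarser
#' steps are obtained by removing stations from the full series rather than by
#' re-spacing them.
#'
#' @format `imaging_styles` and `tilt_set_names` are character vectors;
#'   `horizontal_steps` is a numeric vector of degrees; `base_step_deg` is the
#'   11.25-degree base step and `stations_per_ring` the 32 stations of a full
#'   ring.
#' @name acquisition-constants
NULL

#' @rdname acquisition-constants
#' @export
imaging_styles <- c("FS", "NFS")

#' @rdname acquisition-constants
#' @export
horizontal_steps <- c(11.25, 22.5, 33.75)

#' @rdname acquisition-constants
#' @export
tilt_set_names <- c("C20-40", "C20", "C40")

#' @rdname acquisition-constants
#' @export
base_step_deg <- 11.25

#' @rdname acquisition-constants
#' @export
stations_per_ring <- 32L

#' Tilt angles of a named tilt set
#'
#' `"C20-40"` is the five-ring set (-40, -20, 0, 20, 40), `"C20"` the
#' three-ring set (-20, 0, 20) and `"C40"` the three-ring set (-40, 0, 40).
#' The center (0 degree) ring is present in every set.
#'
#' @param name One of `"C20-40"`, `"C20"`, `"C40"`.
#' @return Numeric vector of tilt angles in degrees, ascending.
#' @export
tilt_set_values <- function(name) {
  switch(as.character(name),
    "C20-40" = c(-40, -20, 0, 20, 40),
    "C20"    = c(-20, 0, 20),
    "C40"    = c(-40, 0, 40),
    stop("unknown tilt set: '", name, "' (expected one of ",
         paste(tilt_set_names, collapse = ", "), ")", call. = FALSE)
  )
}

#' Construct an imaging scenario
#'
#' A scenario is one cell of the acquisition grid: style x horizontal step x
#' tilt set.
#'
#' @param style `"FS"` or `"NFS"`. Style is metadata only: focus stacking
#'   multiplies the raw frames per station but does not change station
#'   geometry.
#' @param horizontal_step Degrees between retained stations; must be an
#'   integer multiple of the 11.25-degree base step.
#' @param tilt_set Tilt-set name (see [tilt_set_values()]), or a numeric
#'   vector of tilt angles in `[-40, 40]` that includes the 0-degree center
#'   ring.
#' @return An object of class `imaging_scenario`.
#' @examples
#' imaging_scenario("NFS", 11.25, "C20-40")
#' imaging_scenario("NFS", 11.25, 0)  # a single center ring
#' @export
imaging_scenario <- function(style, horizontal_step, tilt_set) {
  if (!is.character(style) || length(style) != 1L || !style %in% imaging_styles)
    stop("unknown style: '", style, "' (expected FS or NFS)", call. = FALSE)
  if (length(horizontal_step) != 1L || !is.numeric(horizontal_step))
    stop("horizontal_step must be a single number", call. = FALSE)
  m <- horizontal_step / base_step_deg
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop("horizontal_step (", horizontal_step,
         ") must be a positive integer multiple of ", base_step_deg,
         call. = FALSE)
  if (is.numeric(tilt_set)) {
    tilts <- sort(unique(tilt_set))
    if (any(tilts < -40 | tilts > 40))
      stop("tilt angles must lie in [-40, 40]", call. = FALSE)
    if (!0 %in% tilts)
      stop("the center (0 degree) ring must be present", call. = FALSE)
    tilt_set <- paste(tilts, collapse = "/")
  } else {
    tilts <- tilt_set_values(tilt_set)  # validates the name
  }
  structure(
    list(style = style, horizontal_step = horizontal_step,
         tilt_set = as.character(tilt_set), tilts = tilts),
    class = "imaging_scenario"
  )
}

#' @export
format.imaging_scenario <- function(x, ...) {
  sprintf("%s (%s, %g)", x$style, x$tilt_set, x$horizontal_step)
}

#' @export
print.imaging_scenario <- function(x, ...) {
  cat("<imaging_scenario>", format(x), "\n")
  invisible(x)
}

#' Enumerate imaging scenarios
#'
#' Cartesian product of styles, horizontal steps and tilt sets, in
#' deterministic order (style varies slowest, tilt set fastest). The full
#' default grid has 2 x 3 x 3 = 18 scenarios.
#'
#' @param styles Character vector of styles.
#' @param steps Numeric vector of horizontal steps (degrees).
#' @param tilt_sets Character vector of tilt-set names.
#' @return List of [imaging_scenario()] objects.
#' @examples
#' length(enumerate_scenarios())  # 18
#' @export
enumerate_scenarios <- function(styles = imaging_styles,
                                steps = horizontal_steps,
                                tilt_sets = tilt_set_names) {
  if (length(styles) == 0L || length(steps) == 0L || length(tilt_sets) == 0L)
    stop("styles, steps and tilt_sets must each be non-empty", call. = FALSE)
  if (anyDuplicated(styles) || anyDuplicated(steps) || anyDuplicated(tilt_sets))
    stop("duplicate values in scenario arguments", call. = FALSE)
  out <- list()
  for (st in styles)
    for (hs in steps)
      for (ts in tilt_sets)
        out[[length(out) + 1L]] <- imaging_scenario(st, hs, ts)
  out
}

#' Scenario grid as a data frame
#'
#' @param scenarios List of scenarios, as from [enumerate_scenarios()].
#' @return Data frame with columns `style`, `step`, `tilts` and a formatted
#'   `label` column, one row per scenario in input order.
#' @export
scenario_grid <- function(scenarios = enumerate_scenarios()) {
  data.frame(
    style = vapply(scenarios, `[[`, character(1), "style"),
    step = vapply(scenarios, `[[`, numeric(1), "horizontal_step"),
    tilts = vapply(scenarios, `[[`, character(1), "tilt_set"),
    label = vapply(scenarios, format, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Plan camera stations for a scenario
#'
#' The base ring holds 32 stations at azimuths `k * 11.25` degrees,
#' `k = 0..31`. A coarser horizontal step with decimation factor
#' `m = horizontal_step / 11.25` retains the stations with `k mod m == 0`
#' (`ceiling(32 / m)` per ring), mirroring removal of images from a captured
#' full series. One ring is planned per tilt angle, rings ordered by ascending
#' tilt; decimated rings are phase-aligned with the center ring (same `k`
#' indices). Note 33.75 does not divide 360, so the `m = 3` ring has 11
#' stations and one wrap-around gap of 22.5 degrees.
#'
#' @param scenario An [imaging_scenario()].
#' @return An `acquisition_plan`: list with the `scenario`, a `stations` data
#'   frame (`ring_index`, `station_index`, `tilt_deg`, `azimuth_deg`) and
#'   `n_stations`.
#' @examples
#' plan_stations(imaging_scenario("NFS", 11.25, "C20-40"))$n_stations  # 160
#' @export
plan_stations <- function(scenario) {
  if (!inherits(scenario, "imaging_scenario"))
    stop("scenario must be an imaging_scenario", call. = FALSE)
  m <- as.integer(round(scenario$horizontal_step / base_step_deg))
  k <- seq.int(0L, stations_per_ring - 1L)
  keep <- k[k %% m == 0L]
  rings <- lapply(seq_along(scenario$tilts), function(r) {
    data.frame(
      ring_index = r,
      station_index = seq_along(keep),
      tilt_deg = scenario$tilts[r],
      azimuth_deg = keep * base_step_deg
    )
  })
  stations <- do.call(rbind, rings)
  rownames(stations) <- NULL
  structure(
    list(scenario = scenario, stations = stations,
         n_stations = nrow(stations)),
    class = "acquisition_plan"
  )
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("<acquisition_plan>", format(x$scenario), "-", x$n_stations,
      "stations on", length(x$scenario$tilts), "rings\n")
  invisible(x)
}

#' Write a camera-station shot list to CSV
#'
#' @param plan An [plan_stations()] result.
#' @param path Output CSV path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_shot_list <- function(plan, path) {
  if (!inherits(plan, "acquisition_plan"))
    stop("plan must be an acquisition_plan", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  utils::write.csv(plan$stations, path, row.names = FALSE)
  invisible(path)
}

#' Read a shot list written by [write_shot_list()]
#'
#' @param path CSV path.
#' @return Data frame of stations.
#' @export
read_shot_list <- function(path) {
  stations <- utils::read.csv(path)
  need <- c("ring_index", "station_index", "tilt_deg", "azimuth_deg")
  if (!all(need %in% names(stations)))
    stop("shot list is missing columns: ",
         paste(setdiff(need, names(stations)), collapse = ", "), call. = FALSE)
  stations
}
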