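#' Build an ordered acquisition stack
#'
#' An acquisition stack is the SAR time series: one co-registered grid per
#' acquisition date, all sharing a unit tag. Dates must be strictly
#' increasing with no duplicates.
#'
#' @param dates Vector coercible to `Date`, one per grid.
#' @param grids List of [sar_grid] objects on one common grid.
#' @return An object of class `acq_stack`.
#' @export
acq_stack <- function(dates, grids) {
  dates <- as.Date(dates)
  if (length(dates) != length(grids) || length(dates) == 0L)
    stop("`dates` and `grids` must be non-empty and of equal length",
         call. = FALSE)
  if (any(diff(dates) <= 0))
    stop("acquisition dates must be strictly increasing", call. = FALSE)
  units <- vapply(grids, function(g) g$unit, character(1))
  if (length(unique(units)) != 1L)
    stop("all grids in a stack must share one unit tag", call. = FALSE)
  if (length(grids) > 1L) check_coregistered(grids)
  structure(list(dates = dates, grids = grids, unit = units[1]),
            class = "acq_stack")
}

#' @export
print.acq_stack <- function(x, ...) {
  cat(sprintf("<acq_stack> %d acquisitions (%s .. %s), unit '%s'\n",
              length(x$dates), min(x$dates), max(x$dates), x$unit))
  invisible(x)
}

#' Phenology calendar for the three rice seasons
#'
#' For each rice type the calendar names two closed date windows: the early
#' growth stage (sowing/transplanting — fields are flooded, backscatter is
#' at its trough) and the middle growth stage (canopy closure — backscatter
#' peaks). Both bounds are inclusive. [default_calendar()] ships the 2016
#' Poyang Lake Plain windows: the early-rice windows follow the published
#' field calendar (31 March – 6 May and 18 May – 17 July); the middle- and
#' late-rice windows are documented stand-ins derived from the regional crop
#' calendar and should be overridden with survey-informed dates where
#' available.
#'
#' @param early,middle,late Each a list with elements `early_growth` and
#'   `middle_growth`, both length-2 date vectors `c(start, end)`.
#' @return An object of class `pheno_calendar`.
#' @export
pheno_calendar <- function(early, middle, late) {
  norm <- function(w, type) {
    for (nm in c("early_growth", "middle_growth")) {
      iv <- as.Date(w[[nm]])
      if (length(iv) != 2L || any(is.na(iv)) || iv[1] > iv[2])
        stop(sprintf("%s/%s must be a valid closed date interval", type, nm),
             call. = FALSE)
      w[[nm]] <- iv
    }
    w[c("early_growth", "middle_growth")]
  }
  structure(list(early = norm(early, "early"), middle = norm(middle, "middle"),
                 late = norm(late, "late")),
            class = "pheno_calendar")
}

#' @rdname pheno_calendar
#' @export
default_calendar <- function() {
  pheno_calendar(
    early  = list(early_growth  = c("2016-03-31", "2016-05-06"),
                  middle_growth = c("2016-05-18", "2016-07-17")),
    middle = list(early_growth  = c("2016-05-05", "2016-06-15"),
                  middle_growth = c("2016-06-25", "2016-08-05")),
    late   = list(early_growth  = c("2016-06-25", "2016-08-05"),
                  middle_growth = c("2016-08-15", "2016-09-25"))
  )
}

#' Composite a time series over a date window
#'
#' Reduces all acquisitions whose date falls inside the closed window with
#' pixelwise `min` or `max`, ignoring nodata observations; a pixel is nodata
#' only when every in-window observation there is nodata.
#'
#' @param stack An [acq_stack].
#' @param window Closed date interval `c(start, end)`.
#' @param reducer `"min"` or `"max"`.
#' @return A [sar_grid] with the stack's unit.
#' @export
window_composite <- function(stack, window, reducer = c("min", "max")) {
  stopifnot(inherits(stack, "acq_stack"))
  reducer <- match.arg(reducer)
  window <- as.Date(window)
  inside <- stack$dates >= window[1] & stack$dates <= window[2]
  if (!any(inside))
    stop(sprintf("no acquisition falls inside window %s..%s",
                 window[1], window[2]), call. = FALSE)
  sel <- stack$grids[inside]
  arr <- vapply(sel, function(g) g$values, sel[[1]]$values)
  dim(arr) <- c(length(sel[[1]]$values), length(sel))
  fn <- if (reducer == "min") function(r) suppressWarnings(min(r, na.rm = TRUE))
        else function(r) suppressWarnings(max(r, na.rm = TRUE))
  red <- apply(arr, 1L, fn)
  red[!is.finite(red)] <- NA_real_
  out <- sel[[1]]$values
  out[] <- red
  grid_like(sel[[1]], out)
}

new_enhanced_image <- function(band_min, band_max) {
  check_coregistered(band_min, band_max)
  diff_vals <- band_max$values - band_min$values
  structure(list(band_min = band_min, band_max = band_max,
                 band_diff = grid_like(band_min, diff_vals)),
            class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %d x %d pixels (bands: min, max, diff)\n",
              nrow(x$band_min$values), ncol(x$band_min$values)))
  invisible(x)
}

#' Build the 3-band rice-enhanced image for one rice type
#'
#' Composites the dB backscatter series into the minimum over the rice
#' type's early growth window (flooded fields: the trough), the maximum over
#' its middle growth window (closed canopy: the peak), and their difference.
#' Rice pixels show a large difference while water (~ -24 dB) and
#' forest/built-up (~ -10 dB) barely move, which is what makes the product
#' separable by an unsupervised classifier.
#'
#' @param stack An [acq_stack] in dB.
#' @param calendar A [pheno_calendar].
#' @param rice_type `"early"`, `"middle"` or `"late"`.
#' @return An `enhanced_image`: list of [sar_grid] bands `band_min`,
#'   `band_max`, `band_diff` (`band_diff = band_max - band_min`).
#' @export
build_enhanced_image <- function(stack, calendar,
                                 rice_type = c("early", "middle", "late")) {
  stopifnot(inherits(stack, "acq_stack"), inherits(calendar, "pheno_calendar"))
  rice_type <- match.arg(rice_type)
  if (stack$unit != "dB")
    stop(sprintf("stack has unit '%s' but 'dB' is required", stack$unit),
         call. = FALSE)
  win <- calendar[[rice_type]]
  band_min <- window_composite(stack, win$early_growth, "min")
  band_max <- window_composite(stack, win$middle_growth, "max")
  new_enhanced_image(band_min, band_max)
}

#' Build the 3-band seasonal NDVI cropland image
#'
#' Cropland is green in the growing season but bare after harvest, while
#' evergreen forest is green year-round and open water is negative in NDVI
#' at all times. The cropland image stacks the pixelwise maximum NDVI over
#' the growing-season dates, the pixelwise minimum over the winter dates,
#' and their difference (growing max minus winter min). Unlike the SAR
#' enhanced image the difference band may be negative (e.g. winter-turbid
#' water); no clamp is applied — classification handles such pixels.
#'
#' @param growing_ndvi Non-empty list of NDVI [sar_grid]s (growing season).
#' @param winter_ndvi Non-empty list of NDVI [sar_grid]s (winter).
#' @return An `enhanced_image` with bands min (winter), max (growing), diff.
#' @export
build_cropland_image <- function(growing_ndvi, winter_ndvi) {
  if (length(growing_ndvi) == 0L || length(winter_ndvi) == 0L)
    stop("both NDVI lists must be non-empty", call. = FALSE)
  all_grids <- c(growing_ndvi, winter_ndvi)
  if (length(all_grids) > 1L) check_coregistered(all_grids)
  pixelwise <- function(grids, fn) {
    arr <- vapply(grids, function(g) g$values, grids[[1]]$values)
    dim(arr) <- c(length(grids[[1]]$values), length(grids))
    red <- apply(arr, 1L, function(r) suppressWarnings(fn(r, na.rm = TRUE)))
    red[!is.finite(red)] <- NA_real_
    out <- grids[[1]]$values
    out[] <- red
    grid_like(grids[[1]], out)
  }
  new_enhanced_image(band_min = pixelwise(winter_ndvi, min),
                     band_max = pixelwise(growing_ndvi, max))
}
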