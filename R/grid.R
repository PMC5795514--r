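#' @useDynLib ricesar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Recognised unit tags for a sar_grid. Operations check them so that, e.g.,
# dB conversion cannot silently run twice.
.grid_units <- c("linear-power", "dB", "reflectance", "index", "label")

#' Create a georeferenced single-band grid
#'
#' `sar_grid` is the package's raster container: a numeric matrix (row 1 is
#' the northern edge) with a unit tag, square pixel size in ground meters and
#' the map coordinate of the grid's upper-left corner. Missing observations
#' are encoded as `NA` and treated as nodata by every operation.
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param unit One of `"linear-power"`, `"dB"`, `"reflectance"`, `"index"`,
#'   `"label"`.
#' @param pixel_size Ground meters per pixel edge (square pixels); must be
#'   positive.
#' @param xmin,ymax Map coordinates of the upper-left corner of the grid, in
#'   meters. The grid is north-up.
#' @return An object of class `sar_grid`.
#' @examples
#' g <- sar_grid(matrix(0.1, 4, 5), unit = "linear-power")
#' dim(g$values)
#' @export
sar_grid <- function(values, unit, pixel_size = 30, xmin = 0, ymax = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  unit <- match.arg(unit, .grid_units)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  if (is.null(ymax)) ymax <- nrow(values) * pixel_size
  structure(
    list(values = values, unit = unit, pixel_size = as.numeric(pixel_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax)),
    class = "sar_grid"
  )
}

#' @export
print.sar_grid <- function(x, ...) {
  cat(sprintf("<sar_grid> %d x %d pixels, %g m, unit '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$unit))
  cat(sprintf("  origin (%g, %g); %d nodata pixels\n",
              x$xmin, x$ymax, sum(is.na(x$values))))
  invisible(x)
}

is_sar_grid <- function(x) inherits(x, "sar_grid")

check_unit <- function(grid, expected, what = "grid") {
  if (!identical(grid$unit, expected))
    stop(sprintf("%s has unit '%s' but '%s' is required",
                 what, grid$unit, expected), call. = FALSE)
  invisible(grid)
}

#' Check that grids share shape and geotransform
#'
#' Every multi-grid operation in the pipeline requires its inputs to be on
#' one common analysis grid. This verifies identical dimensions and a
#' geotransform match (pixel size and origin) within `tol`.
#'
#' @param ... Two or more `sar_grid` objects.
#' @param tol Absolute tolerance on pixel size and origin coordinates.
#' @return Invisibly `TRUE`; otherwise an error describing the mismatch.
#' @export
check_coregistered <- function(..., tol = 1e-6) {
  grids <- list(...)
  if (length(grids) == 1L && is.list(grids[[1]]) && !is_sar_grid(grids[[1]]))
    grids <- grids[[1]]
  stopifnot(length(grids) >= 2L)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(dim(g$values), dim(ref$values)))
      stop(sprintf("grids are not co-registered: shape %dx%d vs %dx%d",
                   nrow(g$values), ncol(g$values),
                   nrow(ref$values), ncol(ref$values)), call. = FALSE)
    if (abs(g$pixel_size - ref$pixel_size) > tol ||
        abs(g$xmin - ref$xmin) > tol || abs(g$ymax - ref$ymax) > tol)
      stop("grids are not co-registered: geotransforms differ beyond tolerance",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Clone geometry/unit of `template` with new values.
grid_like <- function(template, values, unit = template$unit) {
  sar_grid(values, unit = unit, pixel_size = template$pixel_size,
           xmin = template$xmin, ymax = template$ymax)
}
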