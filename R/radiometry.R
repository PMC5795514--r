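#' Convert linear backscatter to decibels
#'
#' The calibrated backscattering coefficient sigma-nought is expressed on
#' the decibel scale as `10 * log10(sigma0)`. Calibrated products routinely
#' contain zero (or negative, after thermal-noise removal) power values;
#' those pixels become nodata rather than raising an error, keeping the
#' pipeline total.
#'
#' @param sigma0 A [sar_grid] with unit `"linear-power"`.
#' @return A [sar_grid] in `"dB"` with identical geometry.
#' @examples
#' g <- sar_grid(matrix(c(1, 0.1, 0, 0.01), 2), unit = "linear-power")
#' to_decibel(g)$values
#' @export
to_decibel <- function(sigma0) {
  stopifnot(is_sar_grid(sigma0))
  check_unit(sigma0, "linear-power", "sigma0")
  v <- sigma0$values
  v[!is.na(v) & v <= 0] <- NA_real_
  grid_like(sigma0, 10 * log10(v), unit = "dB")
}

#' Suppress speckle with a windowed median filter
#'
#' Replaces each valid pixel by the median of the `window` x `window`
#' neighbourhood centered on it. Borders are handled by reflect padding;
#' nodata neighbours are excluded from the window and nodata pixels remain
#' nodata (if every neighbour is nodata the output pixel is nodata too).
#'
#' @param grid A [sar_grid] (typically dB backscatter).
#' @param window Odd window edge length in pixels, `>= 3`. The pipeline
#'   default is 5, i.e. a 5 x 5 window.
#' @return Filtered [sar_grid], same unit and geometry.
#' @export
despeckle_median <- function(grid, window = 5L) {
  stopifnot(is_sar_grid(grid))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (min(dim(grid$values)) < window)
    stop("grid smaller than the filter window", call. = FALSE)
  grid_like(grid, .median_filter_cpp(grid$values, window))
}

#' Resample a grid to a new pixel size by nearest neighbour
#'
#' Covers the same extent on the target resolution; each output pixel takes
#' the value of the source pixel whose center is nearest the output pixel
#' center. When two source centers are equidistant the smaller row index,
#' then the smaller column index, wins — a deterministic tie-break. No value
#' is ever interpolated, so every output value exists in the input.
#'
#' @param grid A [sar_grid].
#' @param target_pixel_size Target ground meters per pixel edge.
#' @return A [sar_grid] on the target resolution; unit preserved.
#' @export
resample_nearest <- function(grid, target_pixel_size) {
  stopifnot(is_sar_grid(grid))
  if (!is.numeric(target_pixel_size) || length(target_pixel_size) != 1L ||
      target_pixel_size <= 0)
    stop("`target_pixel_size` must be a single positive number", call. = FALSE)
  src <- grid$pixel_size
  if (isTRUE(all.equal(src, target_pixel_size))) return(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  out_nr <- ceiling(nr * src / target_pixel_size)
  out_nc <- ceiling(nc * src / target_pixel_size)
  # offset of output pixel centers from the grid's upper-left corner, in
  # source-pixel units
  nearest_idx <- function(n_out, n_src) {
    u <- (seq_len(n_out) - 0.5) * target_pixel_size / src
    # center of source pixel i sits at u = i - 0.5; ties (u integral) go to
    # the smaller index
    i <- ifelse(u == floor(u) & u >= 1, u, floor(u) + 1)
    pmin(pmax(as.integer(i), 1L), n_src)
  }
  ri <- nearest_idx(out_nr, nr)
  ci <- nearest_idx(out_nc, nc)
  sar_grid(grid$values[ri, ci, drop = FALSE], unit = grid$unit,
           pixel_size = target_pixel_size, xmin = grid$xmin, ymax = grid$ymax)
}
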