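#' Normalized Difference Vegetation Index
#'
#' `NDVI = (nir - red) / (nir + red)` per pixel. Pixels where the band sum
#' is zero are nodata (the ratio is undefined); output is clipped to the
#' theoretical `[-1, 1]` range to absorb reflectance overshoot from
#' atmospheric correction.
#'
#' @param red,nir [sar_grid]s of surface reflectance, co-registered.
#' @return A [sar_grid] with unit `"index"`.
#' @examples
#' r <- sar_grid(matrix(0.1, 2, 2), unit = "reflectance")
#' n <- sar_grid(matrix(0.5, 2, 2), unit = "reflectance")
#' ndvi(red = r, nir = n)$values[1, 1]  # 0.666...
#' @export
ndvi <- function(red, nir) {
  stopifnot(is_sar_grid(red), is_sar_grid(nir))
  check_unit(red, "reflectance", "red")
  check_unit(nir, "reflectance", "nir")
  check_coregistered(red, nir)
  s <- nir$values + red$values
  d <- nir$values - red$values
  v <- ifelse(!is.na(s) & s == 0, NA_real_, d / s)
  v <- pmin(pmax(v, -1), 1)
  grid_like(red, v, unit = "index")
}
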