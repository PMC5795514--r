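#' Read a grid from an ESRI ASCII raster
#'
#' Grids are exchanged as ESRI ASCII grids (`.asc`), a plain-text raster
#' format with a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `nodata_value`) followed by rows of numbers, north row first.
#' The unit tag, which the format itself cannot carry, lives in a JSON
#' sidecar `<file>.json` with key `"unit"`; when the sidecar is absent the
#' `unit` argument is used.
#'
#' @param path Path to the `.asc` file.
#' @param unit Fallback unit tag when no sidecar is present.
#' @return A [sar_grid].
#' @export
read_asc <- function(path, unit = "dB") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("value block does not match header dimensions in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$unit)) unit <- meta$unit
  }
  sar_grid(m, unit = unit, pixel_size = hdr$cellsize, xmin = hdr$xllcorner,
           ymax = hdr$yllcorner + nr * hdr$cellsize)
}

#' Write a grid to an ESRI ASCII raster
#'
#' Writes the `.asc` file plus a JSON sidecar `<file>.json` carrying the unit
#' tag, so that [read_asc()] round-trips values, nodata, geotransform and
#' unit exactly (values are printed with full double precision).
#'
#' @param grid A [sar_grid].
#' @param path Output path (`.asc`).
#' @param nodata Sentinel written for `NA` pixels.
#' @return Invisibly, `path`.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  stopifnot(is_sar_grid(grid))
  m <- grid$values
  if (any(!is.na(m) & m == nodata))
    stop("grid contains the nodata sentinel ", nodata, " as a real value",
         call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nr * grid$pixel_size),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("nodata_value %.10g", nodata)
  )
  m[is.na(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(list(unit = grid$unit), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a categorical map with its legend
#'
#' A categorical map is a label grid plus an ordered legend (integer code
#' `i` means `legend[i]`). The legend travels in the JSON sidecar.
#'
#' @param map A `rice_map` (see [fuse_early_middle()]).
#' @param path Output `.asc` path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "rice_map"))
  write_asc(map$grid, path)
  jsonlite::write_json(list(unit = "label", legend = map$legend),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @param path Path to the `.asc` written by [write_map()].
#' @export
read_map <- function(path) {
  grid <- read_asc(path, unit = "label")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$legend))
    stop("no legend in sidecar for ", path, call. = FALSE)
  new_rice_map(grid, meta$legend)
}
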