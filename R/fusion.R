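#' Categorical rice map
#'
#' A complete partition of the valid pixels: integer code `i` in the label
#' grid means `legend[i]`. Produced by the decision-tree fusion operations.
#'
#' @param grid A [sar_grid] with unit `"label"`.
#' @param legend Ordered character vector of category names.
#' @return An object of class `rice_map`.
#' @export
new_rice_map <- function(grid, legend) {
  stopifnot(is_sar_grid(grid))
  v <- grid$values
  ok <- v[!is.na(v)]
  if (length(ok) && (any(ok != round(ok)) || any(ok < 1) ||
                     any(ok > length(legend))))
    stop("label values must be integer codes within the legend", call. = FALSE)
  structure(list(grid = grid, legend = as.character(legend)),
            class = "rice_map")
}

#' @export
print.rice_map <- function(x, ...) {
  tab <- table(factor(x$legend[x$grid$values], levels = x$legend))
  cat(sprintf("<rice_map> %d x %d pixels\n",
              nrow(x$grid$values), ncol(x$grid$values)))
  print(tab)
  invisible(x)
}

# Shared engine: `layers` is an ordered list of list(test = function(masks)
# logical-vector, label = name); first matching rule wins, fall-through is
# "other". A pixel nodata in any input layer is nodata in the output.
fuse_layers <- function(masks, rules, legend) {
  check_coregistered(lapply(masks, function(l) l$mask))
  vals <- lapply(masks, function(l) as.vector(l$mask$values))
  nodata <- Reduce(`|`, lapply(vals, is.na))
  out <- rep(match("other", legend), length(vals[[1]]))
  assigned <- rep(FALSE, length(out))
  for (r in rules) {
    hit <- !assigned & !nodata & r$test(vals)
    out[hit] <- match(r$label, legend)
    assigned <- assigned | hit
  }
  out[nodata] <- NA_real_
  template <- masks[[1]]$mask
  g <- grid_like(template, matrix(out, nrow(template$values)), unit = "label")
  new_rice_map(g, legend)
}

#' Priority decision-tree fusion: early + middle rice map
#'
#' Fuses five binary layers into one categorical map. Rules are tested in a
#' fixed priority order and the first match wins: water; else forest; else
#' middle rice (cropland AND middle); else early rice (cropland AND early);
#' else other. Rice can only be mapped where the cropland layer agrees (the
#' cropland gate), and middle rice is deliberately tested before early rice:
#' middle rice is sometimes mistaken for early rice by the per-season
#' classifications, but not the reverse, so giving middle rice priority
#' resolves the conflict. The order is fixed, not configurable.
#'
#' @param water,forest,cropland,middle,early Co-registered [class_layer]s.
#' @return A [new_rice_map()] with legend
#'   `c("water","forest","middle_rice","early_rice","other")`.
#' @export
fuse_early_middle <- function(water, forest, cropland, middle, early) {
  masks <- list(water = water, forest = forest, cropland = cropland,
                middle = middle, early = early)
  rules <- list(
    list(test = function(v) v$water == 1, label = "water"),
    list(test = function(v) v$forest == 1, label = "forest"),
    list(test = function(v) v$cropland == 1 & v$middle == 1,
         label = "middle_rice"),
    list(test = function(v) v$cropland == 1 & v$early == 1,
         label = "early_rice")
  )
  fuse_layers(masks, rules,
              c("water", "forest", "middle_rice", "early_rice", "other"))
}

#' Priority decision-tree fusion: late rice map
#'
#' Same priority scheme as [fuse_early_middle()] with a single rice rule:
#' water; else forest; else late rice (cropland AND late); else other.
#'
#' @param water,forest,cropland,late Co-registered [class_layer]s.
#' @return A [new_rice_map()] with legend
#'   `c("water","forest","late_rice","other")`.
#' @export
fuse_late <- function(water, forest, cropland, late) {
  masks <- list(water = water, forest = forest, cropland = cropland,
                late = late)
  rules <- list(
    list(test = function(v) v$water == 1, label = "water"),
    list(test = function(v) v$forest == 1, label = "forest"),
    list(test = function(v) v$cropland == 1 & v$late == 1,
         label = "late_rice")
  )
  fuse_layers(masks, rules, c("water", "forest", "late_rice", "other"))
}

#' Area of double-cropped rice
#'
#' Early and late rice share fields within one year; the double-cropping
#' area is the area of pixels mapped early rice on the early/middle map AND
#' late rice on the late map.
#'
#' @param early_map,late_map Co-registered [new_rice_map()]s.
#' @param pixel_size Ground meters per pixel edge.
#' @return Area in square kilometers.
#' @export
double_crop_area <- function(early_map, late_map, pixel_size = NULL) {
  stopifnot(inherits(early_map, "rice_map"), inherits(late_map, "rice_map"))
  check_coregistered(early_map$grid, late_map$grid)
  if (is.null(pixel_size)) pixel_size <- early_map$grid$pixel_size
  e <- early_map$legend[early_map$grid$values]
  l <- late_map$legend[late_map$grid$values]
  n <- sum(e == "early_rice" & l == "late_rice", na.rm = TRUE)
  n * pixel_size^2 / 1e6
}

# Extract the named category as a 0/1 layer from a categorical map.
map_class_layer <- function(map, category) {
  stopifnot(inherits(map, "rice_map"))
  code <- match(category, map$legend)
  if (is.na(code)) stop("category not in legend: ", category, call. = FALSE)
  v <- map$grid$values
  m <- ifelse(is.na(v), NA_real_, as.numeric(v == code))
  dim(m) <- dim(v)
  class_layer(grid_like(map$grid, m), category)
}
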