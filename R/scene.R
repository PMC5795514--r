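# Generator land-cover classes. forest and built-up land share a SAR
# signature (~ -10 dB, flat) and are generated as one class; the three
# cropland classes differ only in what is planted.
.scene_classes <- c("water", "forest_builtup", "cropland_early_late",
                    "cropland_middle", "cropland_other", "other")

#' Synthetic scene configuration
#'
#' Defines the study conditions a generated scene emulates: a 12-day SAR
#' acquisition cadence from 31 March to 21 October 2016 with three missing
#' dates (23 June, 29 July, 3 September), five optical dates (three
#' growing-season, two winter), flat water (-24 dB) and forest/built-up
#' (-10 dB) backscatter, and rice whose backscatter troughs (~ -20 dB)
#' during flooded transplanting and peaks (~ -11 dB) at canopy closure —
#' double-cropped early-late fields trough twice. Noise is Gaussian with
#' sd 1 dB (the "+/- 1 dB" spread of the flat signatures) and sd 0.05 in
#' NDVI units.
#'
#' @param rows,cols Grid dimensions in pixels.
#' @param pixel_size Ground meters per pixel edge.
#' @param class_fractions Named fractions over the generator classes
#'   (`water`, `forest_builtup`, `cropland_early_late`, `cropland_middle`,
#'   `cropland_other`, `other`), summing to 1.
#' @param sar_dates SAR acquisition dates (strictly increasing).
#' @param growing_dates,winter_dates Optical acquisition dates.
#' @param noise_sd_db,noise_sd_ndvi Gaussian noise standard deviations.
#' @param calendar A [pheno_calendar] driving the rice temporal profiles.
#' @param seed Integer seed; the scene is bit-reproducible from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(rows = 200L, cols = 200L, pixel_size = 30,
                         class_fractions = c(water = 0.15,
                                             forest_builtup = 0.20,
                                             cropland_early_late = 0.25,
                                             cropland_middle = 0.10,
                                             cropland_other = 0.15,
                                             other = 0.15),
                         sar_dates = NULL,
                         growing_dates = as.Date(c("2016-06-23", "2016-07-25",
                                                   "2016-09-27")),
                         winter_dates = as.Date(c("2016-02-16", "2016-12-16")),
                         noise_sd_db = 1, noise_sd_ndvi = 0.05,
                         calendar = default_calendar(), seed = 42L) {
  if (is.null(sar_dates)) {
    sar_dates <- seq(as.Date("2016-03-31"), as.Date("2016-10-21"), by = 12)
    sar_dates <- setdiff_dates(sar_dates,
                               as.Date(c("2016-06-23", "2016-07-29",
                                         "2016-09-03")))
  }
  sar_dates <- as.Date(sar_dates)
  if (any(diff(sar_dates) <= 0))
    stop("`sar_dates` must be strictly increasing", call. = FALSE)
  if (!setequal(names(class_fractions), .scene_classes))
    stop("`class_fractions` must be named with exactly: ",
         paste(.scene_classes, collapse = ", "), call. = FALSE)
  class_fractions <- class_fractions[.scene_classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must be non-negative and sum to 1", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, class_fractions = class_fractions,
                 sar_dates = sar_dates,
                 growing_dates = as.Date(growing_dates),
                 winter_dates = as.Date(winter_dates),
                 noise_sd_db = noise_sd_db, noise_sd_ndvi = noise_sd_ndvi,
                 calendar = calendar, seed = as.integer(seed)),
            class = "scene_config")
}

setdiff_dates <- function(a, b) a[!(a %in% b)]

#' Mean SAR backscatter of a generator class on a date
#'
#' The noise-free dB level each class is generated around. Water is flat at
#' -24 dB and forest/built-up flat at -10 dB; the two are the scene's fixed
#' reference levels. Rice classes follow a piecewise-linear trajectory
#' anchored on the phenology calendar: off-season baseline (-14 dB), trough
#' (-20 dB) at the midpoint of the early growth window, peak (-11 dB) at the
#' midpoint of the middle growth window, then decline back to baseline.
#' Double-cropped fields chain the early-rice and late-rice trajectories,
#' giving two troughs. Non-rice cropland and "other" land sit near baseline
#' all season.
#'
#' @param cls A generator class name.
#' @param dates Date vector.
#' @param calendar A [pheno_calendar].
#' @return Numeric vector of mean dB values, one per date.
#' @export
temporal_profile <- function(cls, dates, calendar = default_calendar()) {
  cls <- match.arg(cls, .scene_classes)
  dates <- as.Date(dates)
  base <- -14; trough <- -20; peak <- -11
  lead <- 6; decline <- 30
  rice_anchors <- function(win) {
    list(x = c(win$early_growth[1] - lead,
               mean(win$early_growth), mean(win$middle_growth),
               win$middle_growth[2] + decline),
         y = c(base, trough, peak, base))
  }
  anch <- switch(cls,
    water = return(rep(-24, length(dates))),
    forest_builtup = return(rep(-10, length(dates))),
    other = return(rep(-13, length(dates))),
    cropland_other = return(rep(base, length(dates))),
    cropland_middle = rice_anchors(calendar$middle),
    cropland_early_late = {
      e <- calendar$early; l <- calendar$late
      list(x = c(e$early_growth[1] - lead, mean(e$early_growth),
                 mean(e$middle_growth), mean(l$early_growth),
                 mean(l$middle_growth), l$middle_growth[2] + decline),
           y = c(base, trough, peak, trough, peak, base))
    })
  stats::approx(as.numeric(anch$x), anch$y, xout = as.numeric(dates),
                rule = 2)$y
}

#' Mean NDVI of a generator class by season
#'
#' Cropland classes are green in the growing season (~ 0.7) and bare in
#' winter (~ 0.15); evergreen forest stays green year-round (0.8 / 0.7);
#' water is negative in both seasons (-0.3); other land is low and flat
#' (0.2). These contrasts are what the cropland image exploits.
#'
#' @param cls A generator class name.
#' @param date_tag `"growing"` or `"winter"`.
#' @return Mean NDVI value.
#' @export
ndvi_profile <- function(cls, date_tag = c("growing", "winter")) {
  cls <- match.arg(cls, .scene_classes)
  date_tag <- match.arg(date_tag)
  lut <- list(water = c(growing = -0.3, winter = -0.3),
              forest_builtup = c(growing = 0.8, winter = 0.7),
              cropland_early_late = c(growing = 0.7, winter = 0.15),
              cropland_middle = c(growing = 0.7, winter = 0.15),
              cropland_other = c(growing = 0.7, winter = 0.15),
              other = c(growing = 0.2, winter = 0.2))
  unname(lut[[cls]][date_tag])
}

# Largest-remainder apportionment of `total` pixels over fractions.
apportion <- function(fractions, total) {
  raw <- fractions * total
  n <- floor(raw)
  left <- total - sum(n)
  if (left > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(left)]] <- n[ord[seq_len(left)]] + 1
  }
  as.integer(n)
}

# Multi-class seeded region growth: contiguous patches whose per-class
# pixel counts equal `quota` exactly. Round-robin growth from per-class
# frontiers; an exhausted frontier re-seeds at a random unassigned pixel.
grow_patches <- function(rows, cols, quota, n_seeds) {
  n <- rows * cols
  lab <- integer(n)
  k <- length(quota)
  frontier <- vector("list", k)
  remaining <- quota
  neighbours <- function(i) {
    r <- (i - 1L) %% rows + 1L
    c <- (i - 1L) %/% rows + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, i - 1L)
    if (r < rows) nb <- c(nb, i + 1L)
    if (c > 1L) nb <- c(nb, i - rows)
    if (c < cols) nb <- c(nb, i + rows)
    nb
  }
  claim <- function(cls, i) {
    lab[i] <<- cls
    remaining[cls] <<- remaining[cls] - 1L
    frontier[[cls]] <<- c(frontier[[cls]], neighbours(i))
  }
  for (cls in seq_len(k)) {
    if (quota[cls] == 0L) next
    seeds <- sample(which(lab == 0L), min(n_seeds[cls], remaining[cls]))
    for (s in seeds) claim(cls, s)
  }
  while (any(remaining > 0L)) {
    for (cls in seq_len(k)) {
      if (remaining[cls] == 0L) next
      grown <- FALSE
      while (length(frontier[[cls]]) > 0L) {
        pick <- sample.int(length(frontier[[cls]]), 1L)
        cand <- frontier[[cls]][pick]
        frontier[[cls]] <- frontier[[cls]][-pick]
        if (lab[cand] == 0L) { claim(cls, cand); grown <- TRUE; break }
      }
      if (!grown && remaining[cls] > 0L) {
        free <- which(lab == 0L)
        claim(cls, if (length(free) == 1L) free else sample(free, 1L))
      }
    }
  }
  matrix(lab, rows, cols)
}

#' Generate a synthetic co-registered scene
#'
#' Produces everything the pipeline consumes, with known truth: a dB SAR
#' acquisition stack, optical red/NIR reflectance pairs (constructed to
#' invert exactly to the target NDVI before noise), a binary water layer,
#' and truth labels with per-season rice masks. Land cover is laid out as
#' contiguous patches by seeded region growth whose class pixel counts match
#' the configured fractions exactly (largest-remainder rounding). All
#' randomness derives from `config$seed`, so the same config yields
#' bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @return List with `sar` ([acq_stack]), `optical` (list of
#'   `list(date, tag, red, nir)`), `water_layer` ([class_layer]),
#'   `truth` (labels as a [new_rice_map()] over the generator classes, plus
#'   logical masks `early`, `middle`, `late`, `double_crop`, `cropland`,
#'   `forest`, `water`), and the `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    rows <- config$rows; cols <- config$cols
    quota <- apportion(config$class_fractions, rows * cols)
    n_seeds <- pmax(1L, as.integer(round(config$class_fractions * 20)))
    lab <- grow_patches(rows, cols, quota, n_seeds)

    mk_grid <- function(values)
      sar_grid(values, unit = "dB", pixel_size = config$pixel_size)
    grids <- lapply(config$sar_dates, function(d) {
      mu <- vapply(.scene_classes, function(cl)
        temporal_profile(cl, d, config$calendar), numeric(1))
      v <- matrix(mu[lab], rows, cols) +
        matrix(stats::rnorm(rows * cols, 0, config$noise_sd_db), rows, cols)
      mk_grid(v)
    })
    sar <- acq_stack(config$sar_dates, grids)

    mk_optical <- function(d, tag) {
      mu <- vapply(.scene_classes, function(cl) ndvi_profile(cl, tag),
                   numeric(1))
      v <- matrix(mu[lab], rows, cols) +
        matrix(stats::rnorm(rows * cols, 0, config$noise_sd_ndvi), rows, cols)
      v <- pmin(pmax(v, -0.99), 0.99)
      # invert NDVI at a fixed band sum of 0.5 reflectance
      nir <- 0.25 * (1 + v); red <- 0.25 * (1 - v)
      list(date = d, tag = tag,
           red = sar_grid(red, unit = "reflectance",
                          pixel_size = config$pixel_size),
           nir = sar_grid(nir, unit = "reflectance",
                          pixel_size = config$pixel_size))
    }
    optical <- c(lapply(config$growing_dates, mk_optical, tag = "growing"),
                 lapply(config$winter_dates, mk_optical, tag = "winter"))

    cls_of <- function(...) {
      ids <- match(c(...), .scene_classes)
      matrix(lab %in% ids, rows, cols)
    }
    water_mask <- cls_of("water")
    truth <- list(
      labels = new_rice_map(grid_like(grids[[1]], matrix(as.numeric(lab),
                                                         rows, cols),
                                      unit = "label"),
                            .scene_classes),
      early = cls_of("cropland_early_late"),
      middle = cls_of("cropland_middle"),
      late = cls_of("cropland_early_late"),
      double_crop = cls_of("cropland_early_late"),
      cropland = cls_of("cropland_early_late", "cropland_middle",
                        "cropland_other"),
      forest = cls_of("forest_builtup"),
      water = water_mask
    )
    water_layer <- class_layer(
      grid_like(grids[[1]], matrix(as.numeric(water_mask), rows, cols),
                unit = "label"), "water")
    list(sar = sar, optical = optical, water_layer = water_layer,
         truth = truth, config = config)
  })
}

#' Truth categorical map in fused-map legend
#'
#' Re-expresses the generator truth labels in the legend the fusion step
#' produces, for direct map-to-map accuracy assessment.
#'
#' @param truth The `truth` element of [generate_scene()] output.
#' @param which `"early_middle"` or `"late"`.
#' @return A [new_rice_map()].
#' @export
truth_fused_map <- function(truth, which = c("early_middle", "late")) {
  which <- match.arg(which)
  src <- truth$labels
  cls <- src$legend[src$grid$values]
  if (which == "early_middle") {
    legend <- c("water", "forest", "middle_rice", "early_rice", "other")
    out <- ifelse(cls == "water", "water",
           ifelse(cls == "forest_builtup", "forest",
           ifelse(cls == "cropland_middle", "middle_rice",
           ifelse(cls == "cropland_early_late", "early_rice", "other"))))
  } else {
    legend <- c("water", "forest", "late_rice", "other")
    out <- ifelse(cls == "water", "water",
           ifelse(cls == "forest_builtup", "forest",
           ifelse(cls == "cropland_early_late", "late_rice", "other")))
  }
  m <- matrix(match(out, legend), nrow(src$grid$values))
  new_rice_map(grid_like(src$grid, m, unit = "label"), legend)
}
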