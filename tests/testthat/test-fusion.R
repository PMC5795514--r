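# Build the five early/middle fusion inputs from per-pixel rule tuples.
tuple_layers <- function(tuples) {
  m <- do.call(rbind, tuples)
  mk <- function(col) layer_of(matrix(m[, col], nrow(m), 1), col)
  list(water = mk(1), forest = mk(2), cropland = mk(3), middle = mk(4),
       early = mk(5))
}

test_that("early/middle fusion applies the priority rules in order", {
  ly <- tuple_layers(list(c(1, 1, 1, 1, 1),   # water wins everything
                          c(0, 1, 1, 1, 1),   # then forest
                          c(0, 0, 1, 1, 1),   # middle precedes early
                          c(0, 0, 1, 0, 1),   # early needs cropland + early
                          c(0, 0, 0, 0, 1),   # early without cropland -> other
                          c(0, 0, 0, 0, 0)))  # fall-through
  map <- fuse_early_middle(ly$water, ly$forest, ly$cropland, ly$middle,
                           ly$early)
  expect_equal(map$legend[map$grid$values[, 1]],
               c("water", "forest", "middle_rice", "early_rice", "other",
                 "other"))
})

test_that("late fusion applies the same scheme with a single rice rule", {
  m <- rbind(c(1, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 0, 1), c(0, 1, 0, 1))
  mk <- function(col, nm) layer_of(matrix(m[, col], 4, 1), nm)
  map <- fuse_late(mk(1, "water"), mk(2, "forest"), mk(3, "cropland"),
                   mk(4, "late"))
  expect_equal(map$legend[map$grid$values[, 1]],
               c("water", "late_rice", "other", "forest"))
})

test_that("nodata in any input layer propagates to the fused map", {
  w <- matrix(0, 2, 2); w[1, 1] <- NA
  map <- fuse_late(layer_of(w, "water"), layer_of(matrix(0, 2, 2), "forest"),
                   layer_of(matrix(1, 2, 2), "cropland"),
                   layer_of(matrix(1, 2, 2), "late"))
  expect_true(is.na(map$grid$values[1, 1]))
  expect_equal(map$legend[map$grid$values[2, 2]], "late_rice")
})

random_layers <- function(n = 40, seed) {
  set.seed(seed)
  lapply(c("water", "forest", "cropland", "middle", "early", "late"),
         function(nm) layer_of(matrix(stats::rbinom(n, 1, 0.4), 5), nm)) |>
    stats::setNames(c("water", "forest", "cropland", "middle", "early",
                      "late"))
}

test_that("fusion output is a complete partition of the valid pixels", {
  for (seed in 1:10) {
    ly <- random_layers(seed = seed)
    map <- fuse_early_middle(ly$water, ly$forest, ly$cropland, ly$middle,
                             ly$early)
    v <- map$grid$values
    expect_false(anyNA(v))
    expect_equal(sum(table(v)), length(v))
    expect_true(all(v %in% seq_along(map$legend)))
  }
})

test_that("raising a pixel's water bit never yields a non-water label", {
  for (seed in 1:10) {
    ly <- random_layers(seed = 100 + seed)
    base <- fuse_early_middle(ly$water, ly$forest, ly$cropland, ly$middle,
                              ly$early)
    w2 <- ly$water$mask$values
    flip <- which(w2 == 0)[1]
    if (is.na(flip)) next
    w2[flip] <- 1
    up <- fuse_early_middle(layer_of(w2, "water"), ly$forest, ly$cropland,
                            ly$middle, ly$early)
    expect_equal(up$legend[up$grid$values[flip]], "water")
    # all other pixels unchanged
    expect_equal(up$grid$values[-flip], base$grid$values[-flip])
  }
})

test_that("rice labels only occur where the cropland layer agrees", {
  for (seed in 1:10) {
    ly <- random_layers(seed = 200 + seed)
    em <- fuse_early_middle(ly$water, ly$forest, ly$cropland, ly$middle,
                            ly$early)
    lt <- fuse_late(ly$water, ly$forest, ly$cropland, ly$late)
    rice_em <- em$legend[em$grid$values] %in% c("middle_rice", "early_rice")
    expect_true(all(ly$cropland$mask$values[rice_em] == 1))
    rice_lt <- lt$legend[lt$grid$values] == "late_rice"
    expect_true(all(ly$cropland$mask$values[rice_lt] == 1))
  }
})

test_that("double-cropping area counts the early/late intersection", {
  em_legend <- c("water", "forest", "middle_rice", "early_rice", "other")
  lt_legend <- c("water", "forest", "late_rice", "other")
  mk_map <- function(names, legend)
    new_rice_map(sar_grid(matrix(match(names, legend), 10, 10), "label"),
                 legend)
  # disjoint extents -> 0
  em <- mk_map(rep(c("early_rice", "other"), each = 50), em_legend)
  lt <- mk_map(rep(c("other", "late_rice"), each = 50), lt_legend)
  expect_equal(double_crop_area(em, lt), 0)
  # identical 100-pixel extents at 30 m -> 0.09 km2
  em2 <- mk_map(rep("early_rice", 100), em_legend)
  lt2 <- mk_map(rep("late_rice", 100), lt_legend)
  expect_equal(double_crop_area(em2, lt2), 0.09)
})

test_that("double-cropping area matches the generator's overlap truth", {
  sc <- small_scene()
  res <- run_pipeline(sc, seed = 7)
  truth_km2 <- sum(sc$truth$double_crop) * sc$config$pixel_size^2 / 1e6
  expect_equal(res$double_crop_km2, truth_km2, tolerance = 0.05)
})
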