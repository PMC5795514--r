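# Shared fixtures, built in code.

# Independent brute-force windowed median (reflect padding, NA-aware):
# the oracle for despeckle_median().
brute_median_filter <- function(m, window = 5L) {
  h <- window %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n - i + 1L, i)
  }
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) { out[i, j] <- NA_real_; next }
    win <- as.vector(m[reflect((i - h):(i + h), nr),
                       reflect((j - h):(j + h), nc)])
    win <- win[!is.na(win)]
    out[i, j] <- if (length(win)) stats::median(sort(win)) else NA_real_
  }
  out
}

db_grid <- function(m, pixel_size = 30) sar_grid(m, "dB", pixel_size)

# Constant-per-pixel acquisition stack from a named list date -> matrix.
stack_of <- function(mats, dates) {
  acq_stack(dates, lapply(mats, db_grid))
}

# A stack where one pixel follows `series` over `dates` and a second pixel
# is constant at `const`.
two_pixel_stack <- function(series, dates, const = -24) {
  grids <- lapply(seq_along(dates), function(i)
    db_grid(matrix(c(series[i], const), 1, 2)))
  acq_stack(dates, grids)
}

# Binary layer from a 0/1 matrix.
layer_of <- function(m, name) class_layer(sar_grid(m, "label"), name)

# Enhanced image straight from band matrices.
enhanced_of <- function(min_m, max_m)
  ricesar:::new_enhanced_image(db_grid(min_m), db_grid(max_m))

# Toy 2-category error matrix used throughout the accuracy tests:
# counts [[45,5],[10,40]], mapped areas (60,40) km2, total 100 km2.
toy_error_matrix <- function() {
  error_matrix(matrix(c(45L, 10L, 5L, 40L), 2),
               mapped_areas = c(60, 40), total_area = 100,
               categories = c("A", "B"))
}

# Small scene shared by several test files (generated once per run).
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(scene_config(rows = 60L,
                                                              cols = 60L))
    cache
  }
})
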