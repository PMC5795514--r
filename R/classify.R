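# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Squared Euclidean distances, n x k.
sqdist <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

#' K-Means clustering of an enhanced image
#'
#' Lloyd's algorithm on the 3-band feature vectors (min, max, diff) of the
#' valid pixels, with k-means++ seeding driven by an explicit seed so runs
#' are exactly reproducible. A point equidistant to several centroids is
#' assigned to the lowest centroid index; a cluster that empties is
#' re-seeded from the point farthest from its current centroid. Iteration
#' stops when assignments stabilize or after `max_iter` passes. Nodata
#' pixels stay unlabeled. The defaults — 10 classes, 20 iterations — are the
#' settings used for both the rice-enhanced and cropland images in this
#' workflow.
#'
#' @param image An `enhanced_image` (see [build_enhanced_image()]).
#' @param k Number of clusters, `>= 1`.
#' @param max_iter Maximum Lloyd iterations.
#' @param seed Integer seed controlling initialization.
#' @return A `cluster_map`: `labels` ([sar_grid], unit `"label"`, cluster
#'   ids `1..k`), `centroids` (`k x 3` matrix), `inertia` (final
#'   within-cluster sum of squares) and `inertia_trace` (one value per
#'   iteration; non-increasing).
#' @export
kmeans_classify <- function(image, k = 10L, max_iter = 20L, seed = 1L) {
  stopifnot(inherits(image, "enhanced_image"))
  k <- as.integer(k); max_iter <- as.integer(max_iter)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  feats <- cbind(min = as.vector(image$band_min$values),
                 max = as.vector(image$band_max$values),
                 diff = as.vector(image$band_diff$values))
  valid <- rowSums(is.na(feats)) == 0L
  x <- feats[valid, , drop = FALSE]
  n <- nrow(x)
  if (n < k) stop("fewer valid pixels than clusters", call. = FALSE)

  centers <- with_seed(seed, {
    # k-means++: first center uniform, then D^2-weighted
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    if (k > 1L) {
      d2 <- rowSums((x - matrix(x[idx[1], ], n, 3, byrow = TRUE))^2)
      for (j in 2:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx[j] <- sample.int(n, 1L, prob = p)
        d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, 3,
                                           byrow = TRUE))^2))
      }
    }
    x[idx, , drop = FALSE]
  })

  assign_prev <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the worst-fit point
    repeat {
      counts <- tabulate(assign_cur, nbins = k)
      empty <- which(counts == 0L)
      if (length(empty) == 0L) break
      worst <- which.max(d2[cbind(seq_len(n), assign_cur)])
      centers[empty[1], ] <- x[worst, ]
      d2[, empty[1]] <- rowSums((x - matrix(centers[empty[1], ], n, 3,
                                            byrow = TRUE))^2)
      assign_cur <- max.col(-d2, ties.method = "first")
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign_cur)]))
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_cur == j, , drop = FALSE])
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
  }
  d2 <- sqdist(x, centers)
  inertia <- sum(d2[cbind(seq_len(n), assign_prev)])

  lab <- rep(NA_real_, length(valid))
  lab[valid] <- assign_prev
  labels <- grid_like(image$band_min,
                      matrix(lab, nrow(image$band_min$values)), unit = "label")
  structure(list(labels = labels, centroids = centers, k = k,
                 inertia = inertia, inertia_trace = trace),
            class = "cluster_map")
}

#' Binary thematic layer
#'
#' @param mask A [sar_grid] with unit `"label"` and values in `{0, 1}`
#'   (`NA` = nodata).
#' @param class_name Thematic name of the layer (e.g. `"water"`, `"forest"`,
#'   `"cropland"`, `"rice"`).
#' @return An object of class `class_layer`.
#' @export
class_layer <- function(mask, class_name) {
  stopifnot(is_sar_grid(mask))
  v <- mask$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("layer mask values must be 0 or 1", call. = FALSE)
  structure(list(mask = mask, class_name = class_name), class = "class_layer")
}

#' Merge clusters into binary thematic layers
#'
#' Implements the "combine classes" step: every cluster id is mapped to a
#' thematic class name (or `"other"`), and one binary layer is emitted per
#' distinct class name. A pixel is 1 in a layer iff its cluster maps to that
#' layer's class. No layer is emitted for `"other"`.
#'
#' @param clusters A `cluster_map` from [kmeans_classify()].
#' @param mapping Character vector of length `k`: `mapping[i]` is the class
#'   name for cluster id `i` (use `"other"` to drop a cluster). May also be
#'   named by cluster id.
#' @return Named list of [class_layer]s.
#' @export
merge_clusters <- function(clusters, mapping) {
  stopifnot(inherits(clusters, "cluster_map"))
  k <- clusters$k
  mapping <- unlist(mapping)
  if (!is.null(names(mapping)) && all(nzchar(names(mapping)))) {
    full <- rep(NA_character_, k)
    full[as.integer(names(mapping))] <- unname(mapping)
    mapping <- full
  }
  if (length(mapping) != k || anyNA(mapping))
    stop("`mapping` must cover every cluster id 1..", k, call. = FALSE)
  lab <- clusters$labels$values
  out <- list()
  for (cls in setdiff(unique(mapping), "other")) {
    ids <- which(mapping == cls)
    m <- ifelse(is.na(lab), NA_real_, as.numeric(lab %in% ids))
    dim(m) <- dim(lab)
    out[[cls]] <- class_layer(grid_like(clusters$labels, m), cls)
  }
  out
}

#' Heuristic cluster-to-class mapping for unattended runs
#'
#' The survey-driven cluster merging of an operational run requires analyst
#' knowledge; this heuristic provides a documented default so the pipeline
#' runs unattended (users should override it with survey-informed mappings).
#' For a rice-enhanced product, clusters whose centroid difference band lies
#' above the across-centroid midpoint *and* whose minimum band lies below
#' the across-centroid midpoint are labeled `"rice"`. For a cropland image,
#' clusters with difference above the midpoint are `"cropland"`; remaining
#' clusters with a high maximum band (above midpoint) are `"forest"`.
#' Everything else — including the degenerate no-contrast cases (single
#' cluster, all-equal difference) — is `"other"`.
#'
#' @param clusters A `cluster_map`.
#' @param product `"rice_enhanced"` or `"cropland_image"`.
#' @return Character vector of length `k`, usable as `mapping` in
#'   [merge_clusters()].
#' @export
auto_assign_clusters <- function(clusters,
                                 product = c("rice_enhanced",
                                             "cropland_image")) {
  stopifnot(inherits(clusters, "cluster_map"))
  product <- match.arg(product)
  cen <- clusters$centroids
  k <- nrow(cen)
  mapping <- rep("other", k)
  if (k < 2L) return(mapping)
  mid <- function(v) (max(v) + min(v)) / 2
  no_contrast <- function(v) diff(range(v)) == 0
  if (product == "rice_enhanced") {
    if (no_contrast(cen[, "diff"])) return(mapping)
    rice <- cen[, "diff"] > mid(cen[, "diff"]) & cen[, "min"] < mid(cen[, "min"])
    mapping[rice] <- "rice"
  } else {
    if (no_contrast(cen[, "diff"])) return(mapping)
    crop <- cen[, "diff"] > mid(cen[, "diff"])
    forest <- !crop & cen[, "max"] > mid(cen[, "max"])
    mapping[crop] <- "cropland"
    mapping[forest] <- "forest"
  }
  mapping
}
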