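# Tight, well-separated clouds in (min, max, diff) feature space.
two_cloud_image <- function() {
  set.seed(42)
  a <- cbind(-20 + stats::rnorm(10, 0, 0.1), -11 + stats::rnorm(10, 0, 0.1))
  b <- cbind(-24 + stats::rnorm(10, 0, 0.1), -24 + stats::rnorm(10, 0, 0.1))
  pts <- rbind(a, b)
  list(img = enhanced_of(matrix(pts[, 1], 4, 5), matrix(pts[, 2], 4, 5)),
       truth = rep(c(1L, 2L), each = 10L))
}

fake_cluster_map <- function(centroids) {
  k <- nrow(centroids)
  colnames(centroids) <- c("min", "max", "diff")
  labels <- sar_grid(matrix(rep(seq_len(k), length.out = k * 2), k, 2),
                     "label")
  structure(list(labels = labels, centroids = centroids, k = k,
                 inertia = 0, inertia_trace = numeric(0)),
            class = "cluster_map")
}

test_that("k-means recovers two separated clouds exactly", {
  tc <- two_cloud_image()
  cm <- kmeans_classify(tc$img, k = 2, seed = 1)
  lab <- as.vector(cm$labels$values)
  # partition equals the true grouping up to label permutation
  expect_equal(length(unique(lab[tc$truth == 1])), 1L)
  expect_equal(length(unique(lab[tc$truth == 2])), 1L)
  expect_false(lab[1] == lab[20])
  # inertia agrees with the reference implementation's optimum
  km <- stats::kmeans(cbind(as.vector(tc$img$band_min$values),
                            as.vector(tc$img$band_max$values),
                            as.vector(tc$img$band_diff$values)),
                      centers = 2, nstart = 10)
  expect_equal(cm$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("k = 1 yields a single cluster at the feature mean", {
  tc <- two_cloud_image()
  cm <- kmeans_classify(tc$img, k = 1, seed = 3)
  expect_true(all(cm$labels$values == 1))
  expect_equal(as.vector(cm$centroids),
               c(mean(tc$img$band_min$values), mean(tc$img$band_max$values),
                 mean(tc$img$band_diff$values)))
})

test_that("k-means is deterministic under a fixed seed and leaves nodata unlabeled", {
  sc <- small_scene()
  img <- build_enhanced_image(sc$sar, sc$config$calendar, "early")
  img$band_min$values[1, 1] <- NA
  img2 <- ricesar:::new_enhanced_image(img$band_min, img$band_max)
  a <- kmeans_classify(img2, k = 5, seed = 9)
  b <- kmeans_classify(img2, k = 5, seed = 9)
  expect_identical(a$labels$values, b$labels$values)
  expect_identical(a$centroids, b$centroids)
  expect_true(is.na(a$labels$values[1, 1]))
  c2 <- kmeans_classify(img2, k = 5, seed = 10)
  expect_false(identical(a$labels$values, c2$labels$values) &&
               !isTRUE(all.equal(a$centroids, c2$centroids)))
})

test_that("Lloyd inertia is non-increasing across iterations", {
  sc <- small_scene()
  img <- build_enhanced_image(sc$sar, sc$config$calendar, "early")
  cm <- kmeans_classify(img, k = 10, max_iter = 20, seed = 4)
  expect_true(all(diff(cm$inertia_trace) <= 1e-6))
  expect_gte(cm$inertia, 0)
})

test_that("k-means refuses more clusters than valid pixels", {
  img <- enhanced_of(matrix(-20, 2, 2), matrix(-11, 2, 2))
  expect_error(kmeans_classify(img, k = 5, seed = 1), "fewer valid pixels")
})

test_that("cluster merging unions clusters into binary layers", {
  cm <- fake_cluster_map(rbind(c(-24, -24, 0), c(-10, -10, 0),
                               c(-19, -11, 8)))
  layers <- merge_clusters(cm, c("cropland", "cropland", "other"))
  expect_named(layers, "cropland")
  expect_equal(layers$cropland$mask$values,
               matrix(c(1, 1, 0, 1, 1, 0), 3, 2))
  expect_length(merge_clusters(cm, rep("other", 3)), 0L)
  expect_error(merge_clusters(cm, c("cropland", "other")), "cover")
  expect_error(merge_clusters(cm, c(`1` = "cropland", `3` = "other")),
               "cover")
})

test_that("heuristic assignment flags the trough-to-peak cluster as rice", {
  cm <- fake_cluster_map(rbind(c(-24, -24, 0), c(-10, -10, 0),
                               c(-19, -11, 8)))
  expect_equal(auto_assign_clusters(cm, "rice_enhanced"),
               c("other", "other", "rice"))
  # degenerate cases map everything to other
  expect_equal(auto_assign_clusters(fake_cluster_map(matrix(c(-19, -11, 8),
                                                            1)),
                                    "rice_enhanced"), "other")
  flat <- fake_cluster_map(rbind(c(-24, -22, 2), c(-12, -10, 2)))
  expect_equal(auto_assign_clusters(flat, "rice_enhanced"),
               c("other", "other"))
})

test_that("heuristic assignment separates cropland and forest on NDVI centroids", {
  cm <- fake_cluster_map(rbind(c(0.10, 0.78, 0.68),   # cropland
                               c(0.65, 0.85, 0.20),   # evergreen forest
                               c(-0.30, -0.25, 0.05), # water
                               c(0.15, 0.25, 0.10)))  # other land
  expect_equal(auto_assign_clusters(cm, "cropland_image"),
               c("cropland", "forest", "other", "other"))
})

test_that("per-layer classification recovers each class on a synthetic scene", {
  sc <- small_scene()
  res <- run_pipeline(sc, seed = 7)
  checks <- list(early = sc$truth$early, middle = sc$truth$middle,
                 late = sc$truth$late, cropland = sc$truth$cropland,
                 forest = sc$truth$forest)
  for (nm in names(checks)) {
    got <- res$layers[[nm]]$mask$values == 1
    truth <- checks[[nm]]
    precision <- sum(got & truth) / sum(got)
    recall <- sum(got & truth) / sum(truth)
    expect_gte(precision, 0.95)
    expect_gte(recall, 0.95)
  }
})
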