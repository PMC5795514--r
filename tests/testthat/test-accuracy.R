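test_that("proportion matrix follows the area-weighted row proportions", {
  em <- toy_error_matrix()
  pm <- proportion_matrix(em)
  # hand arithmetic: p_ij = (A_i/A_tot) * n_ij/n_i.
  expect_equal(unname(pm$p), rbind(c(0.54, 0.06), c(0.08, 0.32)),
               tolerance = 1e-12)
  expect_equal(unname(pm$column_totals[1]), 0.62)
  # independent direct computation
  direct <- (em$mapped_areas / em$total_area) * em$counts / rowSums(em$counts)
  expect_equal(unname(pm$p), unname(as.matrix(direct)))
  expect_equal(sum(pm$p), 1, tolerance = 1e-9)
})

test_that("perfect diagonal counts reproduce the mapped-area weights", {
  em <- error_matrix(diag(c(50L, 30L, 20L)), c(45, 30, 25), 100)
  pm <- proportion_matrix(em)
  expect_equal(unname(diag(pm$p)), c(0.45, 0.30, 0.25))
  expect_equal(sum(pm$p) - sum(diag(pm$p)), 0)
  acc <- accuracies(pm)
  expect_equal(unname(acc$user), rep(1, 3))
  expect_equal(unname(acc$producer), rep(1, 3))
  expect_equal(acc$overall, 1)
  expect_equal(unname(proportion_se(em)), rep(0, 3))
  expect_equal(kappa_coefficient(em), 1)
})

test_that("sampled strata are required wherever area was mapped", {
  counts <- matrix(c(10L, 0L, 5L, 0L), 2)
  em <- error_matrix(counts, c(60, 40), 100)
  expect_error(proportion_matrix(em), "no samples")
  em1 <- error_matrix(matrix(c(10L, 1L, 5L, 0L), 2), c(60, 40), 100)
  expect_error(proportion_se(em1), "fewer than 2")
})

test_that("adjusted areas scale the column proportions by the total area", {
  pm <- proportion_matrix(toy_error_matrix())
  expect_equal(unname(adjusted_area(pm, 100)), c(62, 38))
  # printed-proportion worked example: 9000 km2 x 0.1812
  expect_equal(9000 * 0.1812, 1630.8)
  # adjusted areas sum to the total when the legend is exhaustive
  expect_equal(sum(adjusted_area(pm, 100)), 100, tolerance = 1e-9)
})

test_that("the stratified SE matches direct evaluation and scales with n", {
  em <- toy_error_matrix()
  se <- proportion_se(em)
  expect_equal(unname(se[1]),
               sqrt(0.36 * 0.9 * 0.1 / 49 + 0.16 * 0.2 * 0.8 / 49),
               tolerance = 1e-12)
  expect_equal(unname(se[1]), 0.034405, tolerance = 1e-4)
  # doubling every count keeps proportions, shrinks variance per stratum by
  # (n-1)/(2n-1)
  em2 <- error_matrix(em$counts * 2L, em$mapped_areas, em$total_area)
  se2 <- proportion_se(em2)
  expect_equal(unname(se2[1]), unname(se[1]) * sqrt(49 / 99),
               tolerance = 1e-12)
})

test_that("confidence halfwidths are 1.96 x total area x SE", {
  expect_equal(confidence_interval(9000, 0.0033), 58.212)
  expect_equal(confidence_interval(9000, 0.0014), 24.696)
  expect_equal(confidence_interval(100, 0), 0)
  expect_error(confidence_interval(100, -0.1), "non-negative")
})

test_that("accuracies come from the proportion matrix, undefined as NA", {
  pm <- proportion_matrix(toy_error_matrix())
  acc <- accuracies(pm)
  expect_equal(unname(acc$user[1]), 0.54 / 0.60)
  expect_equal(unname(acc$producer[1]), 0.54 / 0.62)
  expect_equal(acc$overall, 0.86)
  # empty category: undefined, not zero
  em0 <- error_matrix(matrix(c(10L, 5L, 0L, 0L), 2), c(100, 0), 100,
                      categories = c("A", "B"))
  acc0 <- accuracies(proportion_matrix(em0))
  expect_true(is.na(acc0$user["B"]))
})

test_that("kappa is chance-corrected agreement on raw counts", {
  expect_equal(kappa_coefficient(toy_error_matrix()), 0.70)
  # statistically independent rows and columns -> 0
  ind <- error_matrix(matrix(c(36L, 24L, 24L, 16L), 2), c(60, 40), 100)
  expect_equal(kappa_coefficient(ind), 0, tolerance = 1e-12)
})

test_that("season shares reproduce percentages of the chosen grouping", {
  shares <- season_shares(c(early = 1588.39, middle = 592.15,
                            late = 3152.73), "total")
  expect_equal(unname(round(shares["middle"], 2)), 11.10)
  expect_equal(unname(round(shares["late"], 2)), 59.11)
  early_season <- season_shares(c(early = 1630.84, middle = 556.21),
                                "early_season")
  expect_equal(unname(round(early_season, 2)), c(74.57, 25.43))
  expect_equal(sum(early_season), 100)
  expect_equal(unname(season_shares(c(early = 5, middle = 0, late = 0),
                                    "total")["early"]), 100)
  expect_error(season_shares(c(early = 0, middle = 0, late = 0), "total"),
               "positive")
})

test_that("error matrices are tallied from co-registered label maps", {
  legend <- c("A", "B")
  mk <- function(v) new_rice_map(sar_grid(matrix(v, 10, 10), "label"),
                                 legend)
  # 45 agree-A, 5 map-A/ref-B, 10 map-B/ref-A, 40 agree-B
  map <- mk(rep(c(1, 2), c(50, 50)))
  ref <- mk(rep(c(1, 2, 1, 2), c(45, 5, 10, 40)))
  em <- build_error_matrix(map, ref)
  expect_equal(unname(em$counts), rbind(c(45L, 5L), c(10L, 40L)))
  expect_equal(unname(em$mapped_areas), c(50, 50) * 900 / 1e6)
  # identity maps give a diagonal matrix
  em_id <- build_error_matrix(map, map)
  expect_equal(sum(em_id$counts) - sum(diag(em_id$counts)), 0L)
  # reference label outside the legend
  ref_bad <- new_rice_map(sar_grid(matrix(3, 10, 10), "label"),
                          c("A", "B", "C"))
  expect_error(build_error_matrix(map, ref_bad), "legend")
  # quadrat-style assessment: only masked pixels are tallied
  mask <- matrix(FALSE, 10, 10); mask[1:3, ] <- TRUE
  em_q <- build_error_matrix(map, ref, sample_mask = mask)
  expect_equal(sum(em_q$counts), 30L)
  expect_equal(em_q$total_area, em$total_area)  # areas still from full map
})

test_that("analytic SE agrees with a stratified bootstrap", {
  em <- toy_error_matrix()
  boot <- bootstrap_proportion_se(em, B = 4000, seed = 2)
  se <- proportion_se(em)
  expect_lt(max(abs(boot - se) / se), 0.10)
})

test_that("repeated assessments are unbiased with near-nominal CI coverage", {
  w <- c(early = 0.1765, middle = 0.0658, late = 0.3503, other = 0.4074)
  theta <- rbind(c(0.95, 0.02, 0.02, 0.01),
                 c(0.03, 0.94, 0.02, 0.01),
                 c(0.02, 0.02, 0.94, 0.02),
                 c(0.02, 0.01, 0.02, 0.95))
  dimnames(theta) <- list(names(w), names(w))
  # per-stratum sample size at the scale of a quadrat-based reference
  # dataset (25 quadrats of 20 x 20 pixels ~ 10,000 samples); the Wald-type
  # interval needs the rare confusion cells inside the normal regime
  sim <- simulate_area_assessments(500, w, theta, n_per_stratum = 2500,
                                   total_area = 9000, seed = 8)
  mean_adj <- colMeans(sim$adjusted)
  mc_se <- apply(sim$adjusted, 2, stats::sd) / sqrt(nrow(sim$adjusted))
  expect_true(all(abs(mean_adj - sim$true_areas) <= 4 * mc_se + 1e-9))
  coverage <- colMeans(sim$covered)
  expect_true(all(abs(coverage - 0.95) <= 0.03))
})
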