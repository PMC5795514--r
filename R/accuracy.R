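#' Error matrix of sample counts with mapped areas
#'
#' Cross-tabulation of map categories (rows, `i`) against reference
#' categories (columns, `j`) at the assessment samples, together with the
#' mapped area of each category and the total map area — everything the
#' design-based area estimators need. Rows act as strata: the sample in row
#' `i` is treated as a simple random sample within the area mapped as
#' category `i`.
#'
#' @param counts `q x q` non-negative integer matrix, `counts[i, j]` =
#'   samples mapped `i` with reference `j`. Dimnames, if absent, are taken
#'   from `categories`.
#' @param mapped_areas Length-`q` non-negative vector of mapped areas, km2.
#' @param total_area Total map area, km2; must be at least
#'   `sum(mapped_areas)` (equal when the legend is exhaustive).
#' @param categories Optional category names.
#' @return An object of class `error_matrix`.
#' @export
error_matrix <- function(counts, mapped_areas, total_area,
                         categories = NULL) {
  counts <- as.matrix(counts)
  q <- nrow(counts)
  if (ncol(counts) != q) stop("`counts` must be square", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (length(mapped_areas) != q || any(mapped_areas < 0))
    stop("`mapped_areas` must be length-q and non-negative", call. = FALSE)
  if (sum(mapped_areas) > total_area + 1e-6)
    stop("mapped areas exceed the total area", call. = FALSE)
  if (is.null(categories))
    categories <- if (!is.null(rownames(counts))) rownames(counts)
                  else paste0("class_", seq_len(q))
  dimnames(counts) <- list(map = categories, reference = categories)
  names(mapped_areas) <- categories
  structure(list(counts = counts, row_totals = rowSums(counts),
                 mapped_areas = mapped_areas, total_area = total_area,
                 categories = categories),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %d categories, n = %d samples, A_tot = %g km2\n",
              length(x$categories), sum(x$counts), x$total_area))
  print(x$counts)
  invisible(x)
}

#' Tally an error matrix from co-registered label maps
#'
#' Counts every pixel valid in both maps (optionally restricted to an
#' assessment mask, e.g. rasterized survey quadrats). Mapped areas and the
#' total area come from the full map, not the sample.
#'
#' @param map,reference Co-registered [new_rice_map()]s; every sampled
#'   reference label must appear in `legend`.
#' @param legend Ordered category names; defaults to the map's legend.
#' @param sample_mask Optional logical matrix (or 0/1 [sar_grid]) selecting
#'   the assessed pixels.
#' @param pixel_size Ground meters per pixel; defaults to the map's.
#' @return An [error_matrix()].
#' @export
build_error_matrix <- function(map, reference, legend = NULL,
                               sample_mask = NULL, pixel_size = NULL) {
  stopifnot(inherits(map, "rice_map"), inherits(reference, "rice_map"))
  check_coregistered(map$grid, reference$grid)
  if (is.null(legend)) legend <- map$legend
  if (is.null(pixel_size)) pixel_size <- map$grid$pixel_size
  m <- map$legend[map$grid$values]
  r <- reference$legend[reference$grid$values]
  bad <- setdiff(unique(c(m, r)), c(legend, NA))
  if (length(bad))
    stop("labels outside the legend: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sel <- !is.na(m) & !is.na(r)
  if (!is.null(sample_mask)) {
    if (is_sar_grid(sample_mask)) sample_mask <- sample_mask$values == 1
    sel <- sel & as.vector(sample_mask) & !is.na(as.vector(sample_mask))
  }
  counts <- table(factor(m[sel], levels = legend),
                  factor(r[sel], levels = legend))
  counts <- matrix(as.integer(counts), length(legend),
                   dimnames = list(legend, legend))
  px_km2 <- pixel_size^2 / 1e6
  mapped <- vapply(legend, function(cl) sum(m == cl, na.rm = TRUE),
                   numeric(1)) * px_km2
  total <- sum(!is.na(m)) * px_km2
  error_matrix(counts, mapped, total, categories = legend)
}

#' Error matrix of estimated area proportions
#'
#' Converts sample counts to estimated area proportions,
#' `p_ij = (A_m,i / A_tot) * (n_ij / n_i.)`: each row of the count matrix is
#' scaled by its row total and weighted by the stratum's mapped-area share.
#' Rows with zero mapped area are all-zero; a stratum with mapped area but
#' no samples is undefined and raises an error. When the legend exhausts the
#' map, the grand total of `p` is 1.
#'
#' @param em An [error_matrix()].
#' @return A `proportion_matrix`: `p` (`q x q`), `row_totals` (`p_i.`),
#'   `column_totals` (`p_.j`).
#' @export
proportion_matrix <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  w <- em$mapped_areas / em$total_area
  ni <- em$row_totals
  if (any(w > 0 & ni == 0))
    stop("stratum with mapped area but no samples: ",
         paste(em$categories[w > 0 & ni == 0], collapse = ", "),
         call. = FALSE)
  p <- em$counts
  p[] <- 0
  nz <- ni > 0
  p[nz, ] <- (w[nz] / ni[nz]) * em$counts[nz, , drop = FALSE]
  structure(list(p = p, row_totals = rowSums(p), column_totals = colSums(p),
                 categories = em$categories),
            class = "proportion_matrix")
}

#' Error-adjusted category areas
#'
#' The unbiased (stratified) estimator of each category's true area:
#' `A_a,j = A_tot * p_.j`, the total area scaled by the estimated area
#' proportion of reference category `j`.
#'
#' @param pm A [proportion_matrix()].
#' @param total_area Total map area, km2.
#' @return Named numeric vector of adjusted areas, km2.
#' @export
adjusted_area <- function(pm, total_area) {
  stopifnot(inherits(pm, "proportion_matrix"))
  total_area * pm$column_totals
}

#' Standard error of the estimated area proportions
#'
#' Per reference category `j`,
#' `S(p_.j) = sqrt( sum_i (A_m,i/A_tot)^2 * (n_ij/n_i.) (1 - n_ij/n_i.) /
#' (n_i. - 1) )` — the stratified variance of a proportion, with the map
#' categories as strata. Every stratum with positive mapped area must hold
#' at least 2 samples for the within-stratum variance to be defined.
#'
#' @param em An [error_matrix()].
#' @return Named numeric vector `S(p_.j)` per category.
#' @export
proportion_se <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  w <- em$mapped_areas / em$total_area
  ni <- em$row_totals
  if (any(w > 0 & ni < 2))
    stop("stratum with mapped area but fewer than 2 samples: ",
         paste(em$categories[w > 0 & ni < 2], collapse = ", "),
         call. = FALSE)
  contrib <- w > 0
  se2 <- numeric(length(w))
  for (i in which(contrib)) {
    phat <- em$counts[i, ] / ni[i]
    se2 <- se2 + w[i]^2 * phat * (1 - phat) / (ni[i] - 1)
  }
  stats::setNames(sqrt(se2), em$categories)
}

#' 95% confidence halfwidth for an adjusted area
#'
#' `1.96 * A_tot * S(p_.j)`: the approximate 95% confidence interval of the
#' adjusted area is `A_a,j +/-` this halfwidth.
#'
#' @param total_area Total map area, km2.
#' @param se Standard error(s) of the estimated area proportion.
#' @return Halfwidth(s) in km2.
#' @export
confidence_interval <- function(total_area, se) {
  if (any(se < 0)) stop("standard errors must be non-negative", call. = FALSE)
  1.96 * total_area * se
}

#' User's, producer's and overall accuracy
#'
#' From the proportion matrix: user's accuracy `U_i = p_ii / p_i.`
#' (complement of commission error), producer's accuracy `PR_j = p_jj /
#' p_.j` (complement of omission error), overall accuracy `O = sum_j p_jj`.
#' A category with a zero denominator is reported as `NA` (undefined), never
#' silently 0.
#'
#' @param pm A [proportion_matrix()].
#' @return List with `user`, `producer` (named vectors) and `overall`.
#' @export
accuracies <- function(pm) {
  stopifnot(inherits(pm, "proportion_matrix"))
  d <- diag(pm$p)
  user <- ifelse(pm$row_totals > 0, d / pm$row_totals, NA_real_)
  producer <- ifelse(pm$column_totals > 0, d / pm$column_totals, NA_real_)
  list(user = stats::setNames(user, pm$categories),
       producer = stats::setNames(producer, pm$categories),
       overall = sum(d))
}

#' Cohen's kappa on the sample counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement (trace over total) and `p_e` the agreement expected
#' from the row and column margins. Computed on the raw sample counts (as
#' classification-accuracy reports conventionally do), not on area-weighted
#' proportions.
#'
#' @param em An [error_matrix()].
#' @return Kappa; `NA` when `p_e = 1` (constant matrix).
#' @export
kappa_coefficient <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  n <- sum(em$counts)
  if (n == 0) stop("empty error matrix", call. = FALSE)
  po <- sum(diag(em$counts)) / n
  pe <- sum(rowSums(em$counts) * colSums(em$counts)) / n^2
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Percentage shares of rice area by season
#'
#' With `grouping = "total"` each share is the area's percentage of the
#' early + middle + late sum; with `grouping = "early_season"` only early
#' and middle rice (which share the early season) enter the denominator.
#'
#' @param areas Named numeric vector/list of areas (km2) with names among
#'   `early`, `middle`, `late`.
#' @param grouping `"total"` or `"early_season"`.
#' @return Named vector of percentages (0-100).
#' @export
season_shares <- function(areas, grouping = c("total", "early_season")) {
  grouping <- match.arg(grouping)
  areas <- unlist(areas)
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  need <- if (grouping == "total") c("early", "middle", "late")
          else c("early", "middle")
  if (!all(need %in% names(areas)))
    stop("`areas` must be named with: ", paste(need, collapse = ", "),
         call. = FALSE)
  grp <- areas[need]
  if (sum(grp) <= 0) stop("group sum must be positive", call. = FALSE)
  100 * grp / sum(grp)
}

#' Full assessment report
#'
#' Runs the whole adjustment chain on one error matrix and returns a
#' per-category table (mapped area, adjusted area, proportion, SE, 95%
#' halfwidth, user's and producer's accuracy) plus overall accuracy and
#' kappa.
#'
#' @param em An [error_matrix()].
#' @return List with elements `table` (data.frame), `overall_accuracy`,
#'   `kappa`.
#' @export
assessment_report <- function(em) {
  pm <- proportion_matrix(em)
  se <- proportion_se(em)
  acc <- accuracies(pm)
  tab <- data.frame(
    category = em$categories,
    mapped_area_km2 = as.numeric(em$mapped_areas),
    proportion = as.numeric(pm$column_totals),
    adjusted_area_km2 = as.numeric(adjusted_area(pm, em$total_area)),
    se_proportion = as.numeric(se),
    ci_halfwidth_km2 = as.numeric(confidence_interval(em$total_area, se)),
    user_accuracy = as.numeric(acc$user),
    producer_accuracy = as.numeric(acc$producer),
    row.names = NULL
  )
  list(table = tab, overall_accuracy = acc$overall,
       kappa = kappa_coefficient(em))
}

#' Stratified-bootstrap standard error of the area proportions
#'
#' Independent check of the analytic standard error: resamples each map
#' stratum's reference labels (multinomial with the observed row
#' proportions, same row total), recomputes the column proportions `p_.j`
#' per replicate, and returns their standard deviation.
#'
#' @param em An [error_matrix()].
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Named vector of bootstrap SEs per category.
#' @export
bootstrap_proportion_se <- function(em, B = 2000L, seed = 1L) {
  stopifnot(inherits(em, "error_matrix"))
  q <- length(em$categories)
  w <- em$mapped_areas / em$total_area
  ni <- em$row_totals
  with_seed(seed, {
    reps <- matrix(0, B, q)
    for (b in seq_len(B)) {
      p_cols <- numeric(q)
      for (i in seq_len(q)) {
        if (ni[i] == 0 || w[i] == 0) next
        draw <- stats::rmultinom(1L, ni[i], em$counts[i, ] / ni[i])[, 1]
        p_cols <- p_cols + w[i] * draw / ni[i]
      }
      reps[b, ] <- p_cols
    }
    stats::setNames(apply(reps, 2L, stats::sd), em$categories)
  })
}

#' Simulate repeated stratified accuracy assessments
#'
#' Monte-Carlo harness for the estimator's design properties. Each
#' replicate draws, for every map stratum `i`, `n_per_stratum` reference
#' labels from the stratum's true confusion distribution `theta[i, ]`
#' (`P(reference = j | map = i)`), builds the error matrix with the fixed
#' mapped areas, and records the adjusted areas and confidence halfwidths.
#' The true area of category `j` is `A_tot * sum_i w_i * theta[i, j]`.
#'
#' @param n_reps Number of simulated assessments.
#' @param mapped_proportions Length-`q` vector `w_i` summing to 1.
#' @param theta `q x q` row-stochastic confusion matrix.
#' @param n_per_stratum Samples drawn per map stratum.
#' @param total_area Total area, km2.
#' @param seed Integer seed.
#' @return List: `true_areas` (named vector), `adjusted` (`n_reps x q`),
#'   `halfwidth` (`n_reps x q`), `covered` (logical `n_reps x q`).
#' @export
simulate_area_assessments <- function(n_reps, mapped_proportions, theta,
                                      n_per_stratum = 50L, total_area = 9000,
                                      seed = 1L) {
  q <- length(mapped_proportions)
  stopifnot(nrow(theta) == q, ncol(theta) == q,
            abs(sum(mapped_proportions) - 1) < 1e-9,
            all(abs(rowSums(theta) - 1) < 1e-9))
  cats <- rownames(theta)
  if (is.null(cats)) cats <- paste0("class_", seq_len(q))
  true_areas <- stats::setNames(
    total_area * colSums(mapped_proportions * theta), cats)
  mapped <- mapped_proportions * total_area
  with_seed(seed, {
    adj <- hw <- matrix(0, n_reps, q, dimnames = list(NULL, cats))
    for (r in seq_len(n_reps)) {
      counts <- t(vapply(seq_len(q), function(i)
        stats::rmultinom(1L, n_per_stratum, theta[i, ])[, 1],
        integer(q)))
      em <- error_matrix(counts, mapped, total_area, categories = cats)
      pm <- proportion_matrix(em)
      adj[r, ] <- adjusted_area(pm, total_area)
      hw[r, ] <- confidence_interval(total_area, proportion_se(em))
    }
    covered <- abs(adj - matrix(true_areas, n_reps, q, byrow = TRUE)) <= hw
    list(true_areas = true_areas, adjusted = adj, halfwidth = hw,
         covered = covered)
  })
}
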