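random_mz_rows <- function(n, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  items <- pmin(pmax(round(4 + cbind(z, -z, z, z, z, -z) +
                             matrix(rnorm(n * 6), n, 6)), 1), 7)
  colnames(items) <- mz_items()
  tibble::as_tibble(items)
}

test_that("loadings are orthonormal and variance percentages complete", {
  ld <- fit_mz_pca(random_mz_rows(400))
  gram <- t(ld$loadings) %*% ld$loadings
  expect_equal(gram, diag(6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(ld$pct_variance), 100, tolerance = 1e-9)
  expect_equal(ld$cumulative_pct[6], 100, tolerance = 1e-9)
  expect_true(all(diff(ld$cumulative_pct) >= -1e-12))
  expect_true(all(ld$eigenvalues >= 0))
  expect_true(all(diff(ld$eigenvalues) <= 1e-12))
})

test_that("PCA matches an independent eigendecomposition (prcomp) on toy data", {
  rows <- random_mz_rows(60, seed = 3)
  ld <- fit_mz_pca(rows)
  ref <- stats::prcomp(as.matrix(rows), center = TRUE, scale. = FALSE)
  expect_equal(ld$pct_variance,
               100 * ref$sdev^2 / sum(ref$sdev^2), tolerance = 1e-9)
  for (k in 1:6) {
    # same axis up to sign
    expect_equal(abs(sum(ld$loadings[, k] * ref$rotation[, k])), 1,
                 tolerance = 1e-9)
    # package sign convention: dominant loading positive
    j <- which.max(abs(ld$loadings[, k]))
    expect_gt(ld$loadings[j, k], 0)
  }
})

test_that("a single latent factor concentrates the explained variance", {
  set.seed(4)
  n <- 3000
  z <- rnorm(n, 0, 2)
  items <- 4 + cbind(z, z, z, z, z, z) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  colnames(items) <- mz_items()
  ld <- fit_mz_pca(items)
  expect_gt(ld$pct_variance[1], 99)
})

test_that("factor scores center, reconstruct, and respond to item shifts", {
  rows <- random_mz_rows(200, seed = 5)
  ld <- fit_mz_pca(rows)
  # record at the item means scores zero
  at_mean <- matrix(ld$item_means, 1, 6)
  expect_equal(unlist(factor_scores(at_mean, ld)), c(MZneg = 0, MZpos = 0, MZirr = 0),
               tolerance = 1e-9)
  # all six scores reconstruct the centered data exactly
  sc6 <- as.matrix(factor_scores(rows, ld, n_components = 6))
  centered <- sweep(as.matrix(rows), 2, ld$item_means)
  expect_equal(sc6 %*% t(ld$loadings), centered,
               tolerance = 1e-9, ignore_attr = TRUE)
  # raising 'sad' by 1 moves the negative factor by exactly its sad loading
  base <- matrix(4, 1, 6)
  bumped <- base; bumped[3] <- 5
  delta <- factor_scores(bumped, ld)$MZneg - factor_scores(base, ld)$MZneg
  expect_equal(delta, ld$loadings["sad", "P1"])
})

test_that("sign convention makes sadness raise the negative factor on cohort data", {
  st <- tiny_study(seed = 71, n_participants = 5, n_days = 90)
  ld <- fit_mz_pca(st$daily)
  expect_gt(ld$loadings["sad", "P1"], 0)
  expect_gt(ld$loadings["anxious", "P1"], 0)
  expect_gt(ld$loadings["elated", "P2"], 0)
  expect_gt(ld$loadings["energetic", "P2"], 0)
})

test_that("factor scores are invariant to a constant shift of one item", {
  rows <- random_mz_rows(100, seed = 6)
  ld <- fit_mz_pca(rows)
  shifted <- rows
  shifted$anxious <- shifted$anxious + 2
  ld2 <- fit_mz_pca(shifted)
  expect_equal(as.matrix(factor_scores(rows, ld)),
               as.matrix(factor_scores(shifted, ld2)), tolerance = 1e-9)
})

test_that("degenerate inputs are rejected with informative errors", {
  rows <- random_mz_rows(20, seed = 7)
  rows$elated <- 4L
  expect_error(fit_mz_pca(rows), "zero-variance.*elated")
  expect_warning(try(fit_mz_pca(random_mz_rows(5, seed = 8)), silent = TRUE),
                 "rank-deficient")
})

test_that("correlation-matrix PCA standardises before projecting", {
  rows <- random_mz_rows(300, seed = 9)
  ld <- fit_mz_pca(rows, type = "correlation")
  expect_equal(sum(ld$eigenvalues), 6, tolerance = 1e-9)
  sc <- factor_scores(rows, ld, n_components = 6)
  # total score variance equals total eigenvalue mass
  expect_equal(sum(apply(sc, 2, var)), 6,
               tolerance = 0.01)
})

test_that("congruence is 1 on an identical cohort and lower on noise", {
  st <- tiny_study(n_participants = 4, n_days = 90)
  ld <- fit_mz_pca(st$daily)
  # a study where one cohort IS the pooled data reproduces phi = 1
  one <- mz_study(st$daily, st$weekly,
                  dplyr::mutate(st$cohorts, cohort = "ALL"),
                  prompts = st$prompts)
  stab <- per_group_stability(one, fit_mz_pca(one$daily))
  expect_equal(stab$congruence, rep(1, 3), tolerance = 1e-9)
  expect_identical(stab$matched_component, c("P1", "P2", "P3"))
  # tucker congruence basics
  expect_equal(tucker_congruence(c(1, 0), c(-1, 0)), 1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  # under-sized cohorts are skipped with a warning
  small <- st
  small$cohorts$cohort[1] <- "TINY"
  keep <- small$daily$participant_id != st$cohorts$participant_id[1] |
    small$daily$date <= min(small$daily$date) + 2
  small$daily <- small$daily[keep, ]
  expect_warning(per_group_stability(small, ld), "skipped")
})

test_that("loading stability on presets: P1/P2 more stable than P3", {
  phis <- matrix(NA_real_, 3, 3)
  for (s in 1:3) {
    st <- generate_study(default_study_config(n_participants = 8,
                                              n_days = 120, seed = 100 + s))
    ld <- fit_mz_pca(st$daily)
    stab <- per_group_stability(st, ld)
    phis[s, ] <- tapply(stab$congruence, stab$component, mean)
  }
  avg <- colMeans(phis)  # P1, P2, P3
  expect_gt(avg[1], avg[3])
  expect_gt(avg[2], avg[3])
})
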