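make_curve <- function(gap, s, sizes) {
  structure(data.frame(k = seq_along(gap), log_Wk = NA_real_,
                       expected_log_Wk_ref = NA_real_, gap = gap, s = s,
                       ci_low = gap - 1.96 * s, ci_high = gap + 1.96 * s,
                       min_cluster_size = sizes),
            class = c("gap_curve", "data.frame"))
}

test_that("selection takes a unique non-overlapping maximum directly", {
  cu <- make_curve(c(0.1, 0.3, 0.9, 0.5, 0.4), 0.01, c(96, 40, 29, 20, 15))
  sel <- select_k(cu)
  expect_equal(sel$k, 3)
  expect_equal(sel$audit$candidates_ci_overlap, 3)
})

test_that("a maximal gap with an undersized cluster falls back to the overlapping candidate", {
  cu <- make_curve(c(0.2, 0.5, 0.8, 0.6, 0.9), 0.05, c(50, 20, 15, 12, 4))
  sel <- select_k(cu)
  expect_equal(sel$k, 3)
  expect_equal(sel$audit$eliminated_by_size, 5)
})

test_that("statistically indistinguishable plateau gaps resolve to the smallest k", {
  cu <- make_curve(c(0.3, 0.5, 0.800, 0.801, 0.802), 0.01, c(96, 40, 29, 15, 12))
  expect_equal(select_k(cu)$k, 3)
  # strict arg-max is available by switching the tie band off
  expect_equal(select_k(cu, se_factor = 0)$k, 5)
})

test_that("degenerate selections are handled explicitly", {
  expect_equal(select_k(make_curve(0.4, 0.01, 96))$k, 1)  # k_max = 1
  cu <- make_curve(c(0.1, 0.2, 0.3, 0.9), 0.01, c(96, 5, 4, 3))
  expect_error(select_k(cu), "no admissible k")
})

test_that("unstructured data select k = 1 in the majority of seeds", {
  ones <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, matrix(runif(30 * 8), 30, 8))
    rownames(x) <- sprintf("s%02d", 1:30)
    cu <- gap_statistic(x, k_max = 4, B = 20, n_init = 5, seed = s)
    select_k(cu, min_cluster_size = 2)$k == 1
  }, logical(1))
  expect_gt(sum(ones), 10)
})

test_that("three well-separated blobs put the maximal gap at k = 3", {
  hits <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, {
      centers <- rbind(c(0, 0, 0, 0), c(6, 0, 6, 0), c(0, 6, 0, 6))
      centers[rep(1:3, each = 15), ] + matrix(rnorm(45 * 4), 45, 4)
    })
    rownames(x) <- sprintf("s%02d", 1:45)
    cu <- gap_statistic(x, k_max = 6, B = 20, n_init = 5, seed = s)
    which.max(cu$gap) == 3
  }, logical(1))
  expect_gte(sum(hits), 16)
})

test_that("the gap curve is invariant to subject order", {
  co <- simulate_cohort(small_config(seed = 3))
  x <- t(co$expression)
  perm <- withr::with_seed(1, sample(nrow(x)))
  cu1 <- gap_statistic(x, k_max = 4, B = 10, n_init = 5, seed = 7)
  cu2 <- gap_statistic(x[perm, ], k_max = 4, B = 10, n_init = 5, seed = 7)
  for (col in c("log_Wk", "gap", "s", "min_cluster_size")) {
    expect_equal(cu1[[col]], cu2[[col]], info = col)
  }
  l1 <- attr(cu1, "clusterings")[[3]]
  l2 <- attr(cu2, "clusterings")[[3]]
  expect_equal(l1[names(l2)], l2)
})

test_that("zero-range features are dropped from reference generation with a warning", {
  x <- cbind(matrix(rnorm(60), 20, 3), 5)
  rownames(x) <- sprintf("s%02d", 1:20)
  expect_warning(gap_statistic(x, k_max = 2, B = 5, n_init = 2, seed = 1),
                 "zero-range")
})

test_that("PCA projection reports variance fractions correctly", {
  u <- matrix(rnorm(30), 30, 1) %*% matrix(rnorm(10), 1, 10)
  p1 <- pca_project(t(u), n_components = 2)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)

  set.seed(9)
  iso <- matrix(rnorm(20 * 500), 500, 20)  # genes x samples, isotropic
  pi <- pca_project(iso, n_components = 5)
  expect_true(all(diff(pi$var_explained) <= 1e-12))
  expect_true(all(pi$var_explained < 2 / 19 & pi$var_explained > 0.5 / 19))

  expect_error(pca_project(matrix(3, 5, 4)), "zero variance")
  expect_error(pca_project(matrix(rnorm(20), 5, 4), n_components = 10),
               "n_components")
})

test_that("planted subtypes separate visibly in the first two components", {
  co <- simulate_cohort(small_config(seed = 12, effect_size = 3))
  pr <- pca_project(co$expression, n_components = 2)
  expect_gt(mean_silhouette(pr$coords, as.integer(co$true_labels)), 0)
})
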