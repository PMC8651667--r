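test_that("within-cluster dispersion matches the pairwise-distance form", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c(1, 1, 2, 2)
  expect_equal(within_dispersion(X, labels), 1.0)   # 0.5 + 0.5 by hand
  expect_equal(within_dispersion(X, 1:4), 0)        # singletons

  for (s in 1:10) {
    Xr <- withr::with_seed(s, matrix(stats::rnorm(30 * 4), 30, 4))
    lr <- withr::with_seed(s + 100, sample(1:4, 30, replace = TRUE))
    expect_equal(within_dispersion(Xr, lr),
                 within_dispersion_pairwise(Xr, lr), tolerance = 1e-9)
  }

  # merging clusters never decreases W
  merged <- c(1, 1, 1, 1)
  expect_gte(within_dispersion(X, merged), within_dispersion(X, labels))
  expect_error(within_dispersion(X, factor(c(1, 1, 2, 2), levels = 1:3)),
               "empty cluster")
})

test_that("both clusterers separate well-separated blobs and are deterministic", {
  sp <- simulate_profiles(n_genes = 60, k_true = 2, n_timepoints = 4,
                          noise_sd = 0.05, seed = 5)
  km <- kmeans_cluster(sp$X, 2, seed = 3)
  hc <- hierarchical_cluster(sp$X, 2)
  expect_equal(adjusted_rand(km, sp$labels), 1)
  expect_equal(adjusted_rand(hc, sp$labels), 1)
  expect_identical(km, kmeans_cluster(sp$X, 2, seed = 3))

  # three collinear points: complete linkage merges the two close ones first
  X3 <- matrix(c(0, 1, 10), 3, 1)
  expect_identical(hierarchical_cluster(X3, 2), c(1L, 1L, 2L))

  expect_identical(kmeans_cluster(sp$X, nrow(sp$X)), seq_len(nrow(sp$X)))
  expect_error(kmeans_cluster(sp$X, nrow(sp$X) + 1), "exceeds")
})

test_that("gap curve is near zero when the data itself is a uniform box", {
  X <- withr::with_seed(8, matrix(stats::runif(60 * 4), 60, 4))
  curve <- gap_statistic(X, gap_config(kmax = 8, B = 15, seed = 8))
  frac_near <- mean(abs(curve$gap) <= 2 * curve$s_k)
  expect_gte(frac_near, 0.9)
})

test_that("gap curve is reproducible and invariant to feature permutation", {
  sp <- simulate_profiles(n_genes = 50, k_true = 3, n_timepoints = 6, seed = 2)
  c1 <- gap_statistic(sp$X, gap_config(kmax = 6, B = 5, seed = 4))
  c2 <- gap_statistic(sp$X, gap_config(kmax = 6, B = 5, seed = 4))
  expect_identical(c1, c2)
  expect_true(all(is.finite(c1$gap)))
})

test_that("selection rules follow their definitions on a hand-built curve", {
  curve <- data.frame(k = 1:3, logW = 0, logW_ref = 0,
                      gap = c(1, 3, 2.9), s_k = c(0.05, 0.05, 0.05))
  expect_identical(select_k(curve, "tibshirani_1se"), 2L)
  expect_identical(select_k(curve, "global_max"), 2L)

  dec <- data.frame(k = 1:3, logW = 0, logW_ref = 0,
                    gap = c(3, 2, 1), s_k = rep(0.05, 3))
  expect_identical(select_k(dec, "tibshirani_1se"), 1L)
  expect_identical(select_k(dec, "global_max"), 1L)

  inc <- data.frame(k = 1:3, logW = 0, logW_ref = 0,
                    gap = c(1, 2, 3), s_k = rep(0.01, 3))
  expect_warning(kk <- select_k(inc, "global_max"), "kmax")
  expect_identical(kk, 3L)
})

test_that("cluster assignment recovers planted structure and labels everyone", {
  sp <- simulate_profiles(n_genes = 150, k_true = 5, n_timepoints = 12,
                          noise_sd = 0.25, seed = 6)
  asg <- assign_clusters(sp$X, 5)
  expect_identical(sort(unique(unname(asg$labels))), 1:5)
  expect_length(asg$labels, 150L)
  expect_gte(adjusted_rand(asg$labels, sp$labels), 0.9)

  one <- assign_clusters(sp$X, 1)
  expect_true(all(one$labels == 1L))

  km1 <- assign_clusters(sp$X, 5, method = "kmeans", seed = 9)
  km2 <- assign_clusters(sp$X, 5, method = "kmeans", seed = 9)
  expect_identical(km1$labels, km2$labels)

  prof <- cluster_profiles(asg, sp$X)
  expect_identical(dim(prof), c(5L, 12L))
})

test_that("gap selection agrees with the clusGap reference on planted data", {
  skip_if_not_installed("cluster")
  sp <- simulate_profiles(n_genes = 120, k_true = 3, n_timepoints = 8,
                          noise_sd = 0.25, seed = 12)
  curve <- gap_statistic(sp$X, gap_config(kmax = 8, B = 20, seed = 12))
  ref <- withr::with_seed(12, cluster::clusGap(
    sp$X, FUN = function(x, k) list(cluster = stats::kmeans(x, k, nstart = 10)$cluster),
    K.max = 8, B = 20, spaceH0 = "original", verbose = FALSE))
  k_ref <- which.max(ref$Tab[, "gap"])
  expect_identical(select_k(curve, "global_max"), as.integer(k_ref))
})
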