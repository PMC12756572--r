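make_blobs <- function(n_per = 15, sep = 10, d = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  rownames(x) <- sprintf("S%03d", seq_len(2 * n_per))
  list(x = x, truth = rep(1:2, each = n_per))
}

brute_force_w2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (all(lab == lab[1])) next
    w <- 0
    for (g in 0:1) {
      xs <- x[lab == g, , drop = FALSE]
      w <- w + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    best <- min(best, w)
  }
  best
}

test_that("k-means recovers separated blobs and the k=1 total sum of squares", {
  b <- make_blobs()
  fit <- kmeans_endotypes(b$x, 2, seed = 1)
  expect_equal(length(unique(paste(fit$labels, b$truth))), 2)

  f1 <- kmeans_endotypes(b$x, 1, seed = 1)
  tss <- sum(sweep(b$x, 2, colMeans(b$x))^2)
  expect_equal(f1$wss, tss, tolerance = 1e-10)

  expect_error(kmeans_endotypes(b$x, nrow(b$x) + 1, seed = 1), "exceeds")
})

test_that("best-of-restarts solutions reach the exhaustive two-partition optimum", {
  for (i in 1:20) {
    set.seed(i + 300)
    n <- sample(8:12, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    fit <- kmeans_endotypes(x, 2, seed = i, n_restarts = 25)
    expect_equal(fit$wss, brute_force_w2(x), tolerance = 1e-8)
  }
})

test_that("gap statistic decomposes into reproducible W_k plus reference spread", {
  b <- make_blobs(n_per = 12, seed = 2)
  g2 <- gap_statistic(b$x, k_max = 3, B = 2, seed = 7)
  g50 <- gap_statistic(b$x, k_max = 3, B = 20, seed = 7)
  expect_equal(g2$log_wss, g50$log_wss, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(g2$gap_se, g50$gap_se)))
  expect_true(all(diff(g50$wss) < 1e-8))
  expect_true(all(g50$mean_silhouette[-1] >= -1 &
                    g50$mean_silhouette[-1] <= 1))
  expect_true(g50$k_selected %in% g50$k_grid)
  expect_error(gap_statistic(b$x, k_max = 3, B = 1), "B must")
})

test_that("silhouette matches hand arithmetic and flags anti-separation", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  good <- silhouette_mean(x, c(1, 1, 2, 2))
  manual <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                   (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(good, manual, tolerance = 1e-12)
  expect_gt(good, 1 - 0.15)
  expect_lt(silhouette_mean(x, c(1, 2, 1, 2)), 0)
  expect_error(silhouette_mean(x, c(1, 1, 1, 1)), "two clusters")
})

test_that("endotype labels follow the label-1-is-smaller convention", {
  b <- make_blobs(n_per = 10, seed = 3)
  x <- rbind(b$x, matrix(rnorm(20 * 2, mean = 10), 20, 2))
  rownames(x) <- sprintf("S%03d", 1:40)
  res <- assign_endotypes(x, seed = 3)
  expect_lte(res$sizes[1], res$sizes[2])
  expect_equal(sum(res$labels == 1), res$sizes[1])
  # rerun with another seed: same partition, same orientation
  res2 <- assign_endotypes(x, seed = 99)
  expect_identical(res$labels, res2$labels)
})

test_that("default synthetic cohort endotypes are recovered", {
  sim <- small_cohort(seed = 4)
  pp <- preprocess_pipeline(sim$expression)
  x <- t(unclass(pp$features))
  res <- assign_endotypes(x, seed = 4)
  ari <- mclust::adjustedRandIndex(res$labels, sim$truth$endotype)
  expect_gte(ari, 0.8)
  expect_lt(abs(mean(res$labels == 1) - mean(sim$truth$endotype == 1)), 0.05)
})

test_that("null cohorts yield no endotype structure", {
  sim <- small_cohort(seed = 5, marker_effect_log2 = c(0, 0),
                      dirichlet_alpha = equal_alpha())
  pp <- preprocess_pipeline(sim$expression)
  res <- assign_endotypes(t(unclass(pp$features)), seed = 5)
  ari <- mclust::adjustedRandIndex(res$labels, sim$truth$endotype)
  expect_lt(abs(ari), 0.1)
})

test_that("split and cross-validation accuracies behave at both extremes", {
  sim <- small_cohort(seed = 6)
  pp <- preprocess_pipeline(sim$expression)
  x <- t(unclass(pp$features))
  res <- assign_endotypes(x, seed = 6)
  vr <- validate_endotypes(x, res$labels, seed = 6)
  expect_gte(vr$split_accuracy, 0.95)
  expect_gte(vr$cv_accuracy, 0.95)
  expect_identical(vr, validate_endotypes(x, res$labels, seed = 6))

  set.seed(1)
  perm <- sample(res$labels)
  vp <- validate_endotypes(x, perm, seed = 6)
  expect_lt(abs(vp$cv_accuracy - max(table(perm)) / length(perm)), 0.1)

  expect_error(validate_endotypes(x, rep(1, nrow(x))), "two classes")
})
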