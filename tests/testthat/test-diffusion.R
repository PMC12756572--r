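test_that("the first diffusion component orders a 1-D manifold", {
  set.seed(1)
  pos <- sort(runif(20, 0, 10))
  x <- cbind(pos, 2 * pos, -pos)
  rownames(x) <- sprintf("S%02d", 1:20)
  dm <- diffusion_map(x)
  expect_equal(abs(cor(dm$psi1, pos, method = "spearman")), 1)
  expect_equal(dm$eigenvalues[1], 1, tolerance = 1e-8)
  expect_true(all(diff(dm$eigenvalues) <= 1e-10))
})

test_that("duplicated samples receive identical coordinates", {
  set.seed(2)
  y <- matrix(rnorm(12 * 4), 12, 4)
  dup <- rbind(y, y[1, , drop = FALSE])
  dm <- diffusion_map(dup)
  expect_equal(dm$psi1[1], dm$psi1[13], tolerance = 1e-8)
})

test_that("psi1 matches a dense power-iteration oracle", {
  for (s in 1:5) {
    set.seed(s)
    y <- matrix(rnorm(15 * 4), 15, 4)
    dm <- diffusion_map(y)
    d <- as.matrix(dist(y))
    sig <- median(d[upper.tri(d)])
    K <- exp(-d^2 / (2 * sig^2))
    q <- rowSums(K)
    Kt <- K / outer(q, q)
    P <- Kt / rowSums(Kt)
    pi0 <- rowSums(Kt) / sum(Kt)
    v <- rnorm(15)
    for (i in 1:3000) {
      v <- as.numeric(P %*% v)
      v <- v - sum(pi0 * v)      # deflate the trivial component
      v <- v / sqrt(sum(v^2))
    }
    cosine <- abs(sum(v * dm$psi1)) /
      (sqrt(sum(v^2)) * sqrt(sum(dm$psi1^2)))
    expect_gte(cosine, 0.999)
  }
})

test_that("degenerate constant input is rejected", {
  expect_error(diffusion_map(matrix(1, 5, 3)), "degenerate")
})

test_that("BASICq spans [0,1], is sign-invariant and shift/permutation stable", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20 * 5), 20, 5), matrix(rnorm(15 * 5, 3), 15, 5))
  rownames(x) <- sprintf("S%02d", 1:35)
  labels <- setNames(rep(c(1, 2), c(20, 15)), rownames(x))
  dm <- diffusion_map(x)
  sc <- basicq_score(dm, labels)
  expect_equal(min(sc$basicq), 0)
  expect_equal(max(sc$basicq), 1)
  expect_gt(mean(sc$basicq[labels == 1]), mean(sc$basicq[labels == 2]))

  # negating the eigenvector leaves scores unchanged
  dm_neg <- dm
  dm_neg$psi1 <- -dm$psi1
  expect_equal(basicq_score(dm_neg, labels)$basicq, sc$basicq,
               tolerance = 1e-12)

  # adding a constant to all features is a rigid shift: identical scores
  dm_shift <- diffusion_map(x + 5)
  expect_equal(basicq_score(dm_shift, labels)$basicq, sc$basicq,
               tolerance = 1e-6)

  # permuting samples permutes scores
  perm <- sample(nrow(x))
  dm_p <- diffusion_map(x[perm, ])
  sc_p <- basicq_score(dm_p, labels[perm])
  expect_equal(sc_p$basicq[rownames(x)], sc$basicq, tolerance = 1e-6)

  expect_warning(basicq_score(dm, setNames(rep(1, 35), rownames(x))),
                 "single-endotype")
})

test_that("BASICq separates synthetic endotypes and tracks them continuously", {
  sim <- small_cohort(seed = 7)
  pp <- preprocess_pipeline(sim$expression)
  x <- t(unclass(pp$features))
  res <- assign_endotypes(x, seed = 7)
  sc <- basicq_score(diffusion_map(x), res$labels)
  z <- sim$truth$endotype
  expect_lt(wilcox.test(sc$basicq[z == 1], sc$basicq[z == 2])$p.value, 0.01)
  expect_gte(cor(sc$basicq, as.integer(z == 1)), 0.5)
})

test_that("VFD-30 falls with increasing BASICq on synthetic cohorts", {
  sim <- small_cohort(seed = 8)
  pp <- preprocess_pipeline(sim$expression)
  x <- t(unclass(pp$features))
  res <- assign_endotypes(x, seed = 8)
  sc <- basicq_score(diffusion_map(x), res$labels)
  fit <- fit_vfd_regression(sim$clinical, basicq = sc$basicq)
  expect_lt(fit$estimate[fit$term == "basicq"], 0)
})
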