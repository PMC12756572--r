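test_that("per-gene two-group fits match the least-squares oracle", {
  m <- expression_matrix(rbind(c(5, 5, 3, 3), c(4, 4, 4, 4)),
                         c("gA", "gB"), sprintf("s%d", 1:4))
  groups <- c(1, 1, 2, 2)
  fits <- fit_gene_models(m, groups)
  expect_equal(fits$log2fc[fits$gene == "gA"], 2)
  expect_equal(fits$s2[fits$gene == "gB"], 0)

  set.seed(1)
  mm <- expression_matrix(matrix(rnorm(30 * 12), 30, 12),
                          sprintf("g%02d", 1:30), sprintf("s%02d", 1:12))
  grp <- rep(c(1, 2), each = 6)
  ff <- fit_gene_models(mm, grp)
  for (i in c(1, 7, 30)) {
    ols <- lm(unclass(mm)[i, ] ~ factor(grp))
    expect_equal(ff$log2fc[i], -unname(coef(ols)[2]), tolerance = 1e-10)
    expect_equal(ff$s2[i], summary(ols)$sigma^2, tolerance = 1e-10)
  }
  expect_error(fit_gene_models(mm, rep(1, 12)), "two groups")
  expect_error(fit_gene_models(mm, c(1, rep(2, 11))), "at least 2")
})

test_that("variance moderation matches limma and shrinks in the right direction", {
  set.seed(2)
  G <- 2000; d0 <- 4; s0 <- 0.05; df <- 40
  s2 <- (s0 * d0 / rchisq(G, d0)) * rchisq(G, df) / df
  fits <- data.frame(gene = sprintf("g%04d", 1:G), log2fc = rnorm(G, 0, 0.1),
                     s2 = s2, df = df)
  attr(fits, "n1") <- 21; attr(fits, "n2") <- 21
  mod <- ebayes_moderate(fits)
  sq <- limma::squeezeVar(s2, df)
  expect_equal(attr(mod, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s0_sq"), sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-6)

  # posterior variance sits between the observed and the prior
  expect_true(all(mod$s2_post >= pmin(mod$s2, attr(mod, "s0_sq")) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(mod$s2, attr(mod, "s0_sq")) + 1e-12))
  # an outlier gene is shrunk downward
  worst <- which.max(mod$s2)
  expect_lt(mod$s2_post[worst], mod$s2[worst])
  expect_true(all(mod$adj_p >= mod$p - 1e-15))
})

test_that("equal observed variances collapse moderation to the common-variance t", {
  fits <- data.frame(gene = sprintf("g%02d", 1:20), log2fc = seq(-1, 1, length.out = 20),
                     s2 = 0.25, df = 10)
  attr(fits, "n1") <- 6; attr(fits, "n2") <- 6
  mod <- ebayes_moderate(fits)
  expect_identical(attr(mod, "d0"), Inf)
  t_common <- fits$log2fc / sqrt(0.25 * (1 / 6 + 1 / 6))
  expect_equal(mod$t_mod, t_common, tolerance = 1e-10)
  expect_error(ebayes_moderate(fits[1:5, ]), "at least 10")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    running <- Inf
    for (i in seq_along(o)) {
      k <- o[i]
      rank_k <- m - i + 1
      running <- min(running, p[k] * m / rank_k)
      adj[k] <- min(1, running)
    }
    adj
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("volcano flags obey the boundary semantics and recover markers", {
  st <- data.frame(gene = c("a", "b", "c"), log2fc = c(1.5, 1.49, -2),
                   adj_p = c(0.01, 0.01, 0.04))
  v <- volcano_table(st)
  expect_identical(v$flagged, c(TRUE, FALSE, TRUE))
  expect_identical(v$direction, c(1, 0, -1))
  expect_false(any(volcano_table(st, alpha = 0)$flagged))

  sim <- small_cohort(seed = 9)
  de <- ebayes_moderate(fit_gene_models(sim$expression, sim$truth$endotype))
  v <- volcano_table(de)
  mk <- sim$truth$marker_gene_ids
  expect_gte(mean(mk %in% v$gene[v$flagged]), 0.8)
  expect_lte(mean(v$flagged[!v$gene %in% mk]), 0.05)
})

test_that("moderated p-values are well calibrated under the null hierarchy", {
  sim <- simulate_cohort(cohort_spec(n_samples = 150, n_genes = 600,
                                     n_marker_genes = 10, seed = 10,
                                     marker_effect_log2 = c(0, 0),
                                     dirichlet_alpha = equal_alpha()))
  de <- ebayes_moderate(fit_gene_models(sim$expression, sim$truth$endotype))
  expect_gt(suppressWarnings(ks.test(de$p, "punif")$p.value), 0.01)
})
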