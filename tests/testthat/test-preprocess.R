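test_that("quantile normalization aligns column distributions", {
  # columns that are permutations of each other are a fixed point (up to order)
  set.seed(1)
  v <- rnorm(20)
  m <- expression_matrix(cbind(v, sample(v), sample(v)),
                         sprintf("G%02d", 1:20), c("a", "b", "c"))
  out <- quantile_normalize(m)
  for (j in 1:3)
    expect_equal(unname(sort(out[, j])), sort(v), tolerance = 1e-12)
  expect_equal(rank(out[, 2]), rank(m[, 2]))

  # hand computation: columns (1,3) and (2,4) -> both (1.5, 3.5) in rank order
  m2 <- expression_matrix(cbind(c(1, 3), c(2, 4)), c("g1", "g2"), c("s1", "s2"))
  out2 <- quantile_normalize(m2)
  expect_equal(matrix(as.numeric(out2), 2), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  m3 <- expression_matrix(matrix(5, 3, 2), c("a", "b", "c"), c("s1", "s2"))
  expect_equal(unclass(quantile_normalize(m3)), unclass(m3))

  m4 <- expression_matrix(matrix(1:3, 3, 1), c("a", "b", "c"), "s1")
  expect_warning(out4 <- quantile_normalize(m4), "single sample")
  expect_equal(unclass(out4), unclass(m4))
})

test_that("probe collapsing averages probes per gene and counts unmapped", {
  m <- expression_matrix(matrix(c(2, 4, 7, 1, 3, 9), 3, 2),
                         c("p1", "p2", "p3"), c("s1", "s2"), level = "probe")
  map <- c(p1 = "gA", p2 = "gA")
  out <- collapse_probes(m, map)
  expect_equal(out$n_unmapped, 1)
  expect_equal(unname(out$matrix["gA", ]), c(3, 2))
  expect_error(collapse_probes(m, setNames(character(0), character(0))), "empty")
  expect_error(collapse_probes(tiny_expression(), map), "probe-level")

  # random fixture vs brute-force group-by mean
  set.seed(2)
  G <- 40
  probes <- sprintf("p%02d", 1:G)
  genes <- sample(sprintf("g%02d", 1:12), G, TRUE)
  mm <- expression_matrix(matrix(rnorm(G * 5), G, 5), probes,
                          sprintf("s%d", 1:5), level = "probe")
  got <- collapse_probes(mm, setNames(genes, probes))$matrix
  for (g in unique(genes)) {
    manual <- colMeans(unclass(mm)[genes == g, , drop = FALSE])
    expect_equal(unname(got[g, ]), unname(manual), tolerance = 1e-12)
  }
})

test_that("expression filtering removes only all-at-floor rows", {
  vals <- rbind(c(0, 0, 0), c(0, 2, 0), c(5, 5, 5))
  m <- expression_matrix(vals, c("zero", "one_pos", "high"), c("a", "b", "c"))
  out <- filter_expressed(m)
  expect_identical(rownames(out$matrix), c("one_pos", "high"))
  expect_equal(out$report$n_zero_filtered, 1)

  # brute-force scan on a random mixed fixture
  set.seed(3)
  vv <- matrix(rexp(200) - 0.5, 50, 4)
  mm <- expression_matrix(vv, sprintf("g%02d", 1:50), letters[1:4])
  keep_manual <- rowSums(vv > 0) > 0
  expect_identical(rownames(filter_expressed(mm)$matrix),
                   sprintf("g%02d", 1:50)[keep_manual])

  expect_error(filter_expressed(expression_matrix(matrix(0, 2, 2),
                                                  c("a", "b"), c("x", "y"))),
               "all rows removed")
})

test_that("top-variance selection keeps ceil(q*G) rows with deterministic ties", {
  set.seed(4)
  m <- expression_matrix(matrix(rnorm(40), 10, 4), sprintf("g%02d", 1:10),
                         letters[1:4])
  expect_identical(unclass(top_variance_features(m, 1)), unclass(m))

  out <- top_variance_features(m, 0.2)
  expect_equal(nrow(out), 2)
  v <- apply(unclass(m), 1, var)
  expect_setequal(rownames(out), names(sort(v, decreasing = TRUE))[1:2])

  # equal variances at the cut: lexicographically smaller id survives
  tie <- expression_matrix(rbind(c(0, 10), c(10, 0), c(1, 1)),
                           c("gB", "gA", "gC"), c("s1", "s2"))
  expect_setequal(rownames(top_variance_features(tie, 1 / 3)), "gA")

  expect_error(top_variance_features(m, 0), "q must")

  # invariance to sample order
  perm <- expression_matrix(unclass(m)[, c(3, 1, 4, 2)],
                            rownames(m), colnames(m)[c(3, 1, 4, 2)])
  expect_identical(rownames(top_variance_features(perm, 0.3)),
                   rownames(top_variance_features(m, 0.3)))
})

test_that("pipeline order conserves counts at every step", {
  sim <- small_cohort(seed = 5)
  pp <- preprocess_pipeline(sim$expression, top_frac = 0.15)
  r <- pp$report
  expect_equal(r$n_genes_out + r$n_zero_filtered + r$n_unmapped, r$n_probes_in)
  expect_equal(r$n_features_selected, ceiling(0.15 * r$n_genes_out))
  expect_lte(r$n_features_selected, r$n_genes_out)
})
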