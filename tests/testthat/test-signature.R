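test_that("FS-PLS finds a planted gene first and stops on null responses", {
  firsts <- nulls <- logical(20)
  for (s in 1:20) {
    set.seed(s + 500)
    n <- 60
    y <- rbinom(n, 1, 0.4)
    x <- matrix(rnorm(n * 200), n, 200,
                dimnames = list(NULL, sprintf("g%03d", 1:200)))
    x[, 7] <- x[, 7] + 2 * y
    tr <- fspls_select(x, y)
    firsts[s] <- length(tr$selected_genes) > 0 && tr$selected_genes[1] == "g007"

    x0 <- matrix(rnorm(n * 200), n, 200,
                 dimnames = list(NULL, sprintf("g%03d", 1:200)))
    tr0 <- fspls_select(x0, rbinom(n, 1, 0.5))
    nulls[s] <- tr0$stop_reason == "no_significant" &&
      length(tr0$selected_genes) <= 1
  }
  expect_gte(mean(firsts), 0.95)
  expect_gte(mean(nulls), 0.9)
})

test_that("deflation removes collinear copies of a selected gene", {
  set.seed(3)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
  x[, 5] <- x[, 5] + 3 * y
  x[, 6] <- x[, 5]
  tr <- fspls_select(x, y)
  expect_equal(sum(c("g05", "g06") %in% tr$selected_genes), 1)
  expect_error(fspls_select(x, rep(1, n)), "constant response")
})

test_that("ROC thresholds sweep to the Mann-Whitney AUROC", {
  expect_equal(roc_curve(rep(1, 10), rep(c(0, 1), 5))$auroc, 0.5)

  set.seed(4)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5)
  rc <- roc_curve(scores, labels)
  u <- wilcox.test(scores[labels == 1], scores[labels == 0],
                   exact = FALSE)$statistic
  expect_equal(rc$auroc, unname(u) / (sum(labels == 1) * sum(labels == 0)),
               tolerance = 1e-12)
  expect_equal(as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               rc$auroc, tolerance = 1e-12)
  expect_equal(roc_curve(-scores, labels)$auroc, 1 - rc$auroc,
               tolerance = 1e-12)
})

test_that("the Youden threshold matches the hand-enumerated case", {
  yt <- endokit:::youden_threshold(1:8, c(0, 0, 0, 1, 0, 1, 1, 1))
  expect_gt(yt$threshold, 5)
  expect_lt(yt$threshold, 6)
  expect_equal(yt$sensitivity, 0.75)
  expect_equal(yt$specificity, 1.0)
  expect_equal(yt$youden_j, yt$sensitivity + yt$specificity - 1)
})

test_that("a perfectly separating gene yields a perfect panel", {
  set.seed(5)
  y <- rep(c(0, 1), each = 10)
  x <- cbind(sep = y * 10 + rnorm(20, sd = 0.1),
             noise = rnorm(20))
  pans <- best_combination(x, y, c("sep", "noise"), sizes = 1)
  p <- pans[["1"]]
  expect_identical(p$genes, "sep")
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  expect_equal(p$youden_j, 1)
})

test_that("the planted additive pair wins the 2-gene search", {
  wins <- logical(25)
  for (s in 1:25) {
    set.seed(s + 700)
    n <- 100
    y <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, sprintf("g%02d", 1:10)))
    x[, 3] <- x[, 3] + 1.2 * y
    x[, 8] <- x[, 8] + 1.2 * y
    pans <- best_combination(x, y, colnames(x), sizes = 2)
    wins[s] <- setequal(pans[["2"]]$genes, c("g03", "g08"))
  }
  expect_gte(mean(wins), 0.8)
})

test_that("candidate order does not change the selected panel", {
  set.seed(6)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("g%d", 1:6)))
  x[, 2] <- x[, 2] + 1.5 * y
  a <- best_combination(x, y, c("g1", "g2", "g3", "g4"), sizes = 2)
  b <- best_combination(x, y, c("g4", "g3", "g2", "g1"), sizes = 2)
  expect_identical(a[["2"]]$genes, b[["2"]]$genes)
  expect_error(best_combination(x, y, sprintf("x%d", 1:3)), "absent")
})
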