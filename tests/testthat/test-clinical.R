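test_that("VFD-30 handles death, short ventilation and the 30-day floor", {
  expect_equal(compute_vfd30(3, TRUE), 0L)
  expect_equal(compute_vfd30(4, FALSE), 26L)
  expect_equal(compute_vfd30(35, FALSE), 0L)
  expect_error(compute_vfd30(-1, FALSE), "non-negative")
  v <- compute_vfd30(sample(0:40, 50, TRUE), runif(50) < 0.2)
  expect_true(all(v >= 0 & v <= 30))
})

test_that("the composite event coincides with VFD-30 of zero", {
  cl <- validate_clinical(tiny_clinical(30, seed = 2))
  cl$ventilation_days[5] <- 31L
  oc <- outcome_records(cl)
  expect_identical(oc$event_composite, oc$vfd30 == 0)
  expect_true(all(oc$time_to_extubation <= 30))
})

test_that("proportion summaries reproduce printed cohort percentages", {
  counts <- matrix(c(98, 24, 124, 136), 2,
                   dimnames = list(c("yes", "no"), c("e1", "e2")))
  ps <- proportion_summary(counts)
  expect_equal(ps$percent["yes", "e1"], 80.3)
  expect_identical(ps$formatted["yes", "e1"], "98 (80.3%)")
  expect_equal(proportion_summary(matrix(c(8, 114), 2))$percent[1], 6.6)
  expect_equal(proportion_summary(matrix(c(0, 10), 2))$percent[1], 0.0)
})

test_that("rank-sum and Kruskal-Wallis wrappers match known cases", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1)
  expect_identical(rs$test_name, "rank_sum")
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  kw <- kruskal_test(rep(c(1, 2, 3), 3), rep(letters[1:3], each = 3))
  expect_identical(kw$test_name, "kruskal_wallis")
  expect_equal(kruskal_test(c(5, 5, 5, 5, 5, 5),
                            rep(letters[1:3], 2))$statistic, 0)
})

test_that("the VFD regression solves the normal equations and flags collinearity", {
  cl <- validate_clinical(tiny_clinical(60, seed = 3))
  lab <- rep(c(1, 2), 30)
  tab <- fit_vfd_regression(cl, endotype = lab)
  # independent closed-form oracle: (X'X)^{-1} X'y on the same design
  df <- endokit:::model_frame(cl, endotype = lab)
  df$vfd30 <- compute_vfd30(cl$ventilation_days, cl$died_by_day30)
  X <- model.matrix(vfd30 ~ ., data = df)
  beta <- solve(crossprod(X), crossprod(X, df$vfd30))
  expect_equal(tab$estimate, unname(beta[tab$term, 1]), tolerance = 1e-10)

  cl <- validate_clinical(tiny_clinical(40, seed = 4))
  lab <- rep(c(1, 2), 20)
  tab <- fit_vfd_regression(cl, endotype = lab)
  expect_true("endotype1" %in% tab$term)
  expect_true(all(tab$ci_lo <= tab$estimate & tab$estimate <= tab$ci_hi))

  # a column identical to the endotype indicator breaks full rank
  cl2 <- cl
  cl2$pim2 <- plogis(lab)  # pim2_logit becomes an affine copy of endotype1
  expect_error(fit_vfd_regression(cl2, endotype = lab), "collinear")
})

test_that("the planted endotype effect is recovered across seeds", {
  est <- vapply(1:12, function(s) {
    sim <- simulate_cohort(cohort_spec(seed = s, n_genes = 20,
                                       n_marker_genes = 2))
    tab <- fit_vfd_regression(sim$clinical, endotype = sim$truth$endotype)
    tab$estimate[tab$term == "endotype1"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-3.7)), 1.0)
})

test_that("null endotype effects are covered by the confidence interval", {
  covered <- vapply(1:40, function(s) {
    set.seed(s)
    cl <- validate_clinical(tiny_clinical(120, seed = s))
    lab <- sample(rep(c(1, 2), 60))
    tab <- fit_vfd_regression(cl, endotype = lab)
    row <- tab[tab$term == "endotype1", ]
    row$ci_lo <= 0 && 0 <= row$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("Cox fits recover a known hazard ratio and match a grid oracle", {
  hrs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = 0.1 * 2^g)
    cens <- t > 20
    tab <- fit_cox_model(pmin(t, 20), !cens, endotype = 2 - g)
    tab$hr[tab$term == "endotype1"]
  }, numeric(1))
  expect_gt(mean(hrs), 1.7)
  expect_lt(mean(hrs), 2.3)

  # 1-D partial-likelihood grid oracle, single binary covariate, no ties
  set.seed(21)
  n <- 40
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.2 * ifelse(g == 1, 2, 1))
  loglik <- function(b) {
    ord <- order(t)
    ll <- 0
    for (i in seq_len(n)) {
      k <- ord[i]
      risk <- t >= t[k]
      ll <- ll + b * g[k] - log(sum(exp(b * g[risk])))
    }
    ll
  }
  grid <- seq(-2, 2, by = 0.001)
  b_grid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  tab <- fit_cox_model(t, rep(1, n), endotype = 2 - g)
  expect_lt(abs(log(tab$hr[tab$term == "endotype1"]) - b_grid), 0.002)

  expect_error(fit_cox_model(t, rep(0, n), endotype = 2 - g), "no events")
})

test_that("the descriptive table summarizes both variable kinds by endotype", {
  sim <- small_cohort(seed = 13)
  t1 <- endotype_table1(sim$clinical, sim$truth$endotype)
  expect_named(t1$proportions, c("sex", "age_group", "admission_reason",
                                 "comorbidity", "infection_status"))
  expect_true(all(grepl("%\\)$", t1$proportions$sex)))
  expect_identical(t1$continuous$variable,
                   c("pim2", "ventilation_days", "vfd30"))
  expect_true(all(t1$continuous$p >= 0 & t1$continuous$p <= 1))
})
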