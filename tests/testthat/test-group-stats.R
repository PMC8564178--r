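test_that("cognition z-scores standardize and flip timed tests", {
  raw <- data.frame(mmse = c(10, 20, 30), tmt_a = c(30, 60, 90))
  z <- zscore_cognition(raw, timed = "tmt_a")
  expect_equal(z$mmse, c(-1, 0, 1))
  # fastest subject gets the highest z on a time-scored test
  expect_equal(which.max(z$tmt_a), which.min(raw$tmt_a))
  expect_equal(z$tmt_a, c(1, 0, -1))
  # per-column mean 0, SD 1 after transform
  set.seed(1)
  raw2 <- data.frame(a = rnorm(50, 10, 3), b = runif(50, 40, 200))
  z2 <- zscore_cognition(raw2, timed = "b")
  expect_lt(max(abs(colMeans(z2))), 1e-12)
  expect_equal(unname(apply(z2, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_cognition(data.frame(a = rep(1, 5))),
               class = "nc_validation_error")
})

test_that("chi-square test reproduces hand expansion and analytic identities", {
  # identical proportions: statistic 0, p 1
  same <- matrix(c(10, 20, 5, 10, 8, 16), nrow = 3, byrow = TRUE)
  res0 <- chi_square_test(same)
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
  # 2x2 hand expansion
  tab <- matrix(c(12, 8, 5, 15), 2, byrow = TRUE)
  res <- chi_square_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chisq, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_identical(res$df, 1L)
  # for df = 2 the survival function collapses to exp(-X2/2)
  tab3 <- matrix(c(3, 29, 4, 20, 8, 22), nrow = 3, byrow = TRUE)
  res3 <- chi_square_test(tab3)
  expect_identical(res3$df, 2L)
  expect_equal(res3$p, exp(-res3$chisq / 2), tolerance = 1e-12)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)),
               class = "nc_validation_error")
})

test_that("one-way ANOVA from raw data and from summaries agree", {
  set.seed(4)
  g <- rep(letters[1:3], c(12, 9, 14))
  x <- rnorm(35, ave(seq_along(g), g), 2)
  raw <- oneway_anova(x, g)
  ns <- tapply(x, g, length); ms <- tapply(x, g, mean); ss <- tapply(x, g, sd)
  summ <- oneway_anova_summary(ns, ms, ss)
  expect_equal(raw$F, summ$F, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  # equal group means: F = 0, p = 1
  eq <- oneway_anova_summary(c(10, 10), c(5, 5), c(1, 2))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
})

test_that("Kruskal-Wallis matches hand ranking and is order-invariant", {
  res <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  # hand computation: ranks 1,2 vs 3,4, no ties
  H <- 12 / (4 * 5) * (2 * (1.5 - 2.5)^2 + 2 * (3.5 - 2.5)^2)
  expect_equal(res$H, H, tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(40); g <- rep(1:3, length.out = 40)
  perm <- sample(40)
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(x[perm], g[perm])$H,
               tolerance = 1e-12)
  # calibration: under identical distributions p is roughly uniform
  ps <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    kruskal_wallis(rnorm(45), rep(1:3, each = 15))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("permutation ANCOVA reduces to plain ANOVA without covariates", {
  set.seed(10)
  g <- rep(c("mild", "moderate", "severe"), c(12, 10, 11))
  y <- rnorm(33) + (g == "severe")
  fit <- ancova_permutation(y, g, NULL, n_perm = 200, seed = 3,
                            scheme = "labels")
  expect_equal(fit$F_obs, oneway_anova(y, g)$F, tolerance = 1e-10)
  # p-values respect the add-one convention and the seed
  expect_gte(fit$p_perm, 1 / 201)
  fit2 <- ancova_permutation(y, g, NULL, n_perm = 200, seed = 3,
                             scheme = "labels")
  expect_identical(fit$p_perm, fit2$p_perm)
})

test_that("Freedman-Lane ANCOVA detects group effects net of covariates", {
  set.seed(11)
  n <- 86
  g <- rep(c("mild", "moderate", "severe"), c(32, 24, 30))
  age <- rnorm(n, 65, 5); sex <- rbinom(n, 1, 0.5)
  covs <- data.frame(age = age, sex = sex)
  # outcome driven only by covariates: omnibus should not reject
  y0 <- 0.1 * age + 0.5 * sex + rnorm(n)
  fit0 <- ancova_permutation(y0, g, covs, n_perm = 500, seed = 5)
  expect_gt(fit0$p_perm, 0.01)
  # strong group effect: rejected, post-hoc contrasts carry direction
  y1 <- y0 - 1.2 * (g == "severe")
  fit1 <- ancova_permutation(y1, g, covs, n_perm = 500, seed = 5)
  expect_lt(fit1$p_perm, 0.01)
  expect_false(is.null(fit1$posthoc))
  ms <- fit1$posthoc[fit1$posthoc$pair == "mild-severe", ]
  expect_lt(ms$t, 0)
  expect_match(ms$direction, "severe < mild")
  expect_error(ancova_permutation(y1, g, cbind(covs, covs$age),
                                  n_perm = 200, seed = 1),
               class = "nc_rank_error")
})

test_that("region-wise analysis returns one row per region, none dropped", {
  set.seed(13)
  n <- 30; K <- 7
  g <- rep(c("mild", "moderate", "severe"), each = 10)
  M <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("r", 1:K)))
  M[, 4] <- 0  # degenerate region
  st <- region_stats(M, g, NULL, n_perm = 100, seed = 2)
  expect_identical(nrow(st), 7L)
  expect_identical(st$region, paste0("r", 1:K))
  expect_true(is.na(st$p_perm[4]))
  expect_true(all(st$p_perm >= 1 / 101, na.rm = TRUE))
  st_fdr <- region_stats(M, g, NULL, n_perm = 100, seed = 2, fdr = TRUE)
  expect_true(all(st_fdr$p_fdr >= st_fdr$p_perm, na.rm = TRUE))
})

test_that("partial correlation matches the closed-form recursion", {
  set.seed(14)
  n <- 60
  c1 <- rnorm(n)
  x <- 0.5 * c1 + rnorm(n)
  y <- -0.3 * c1 + 0.4 * x + rnorm(n)
  pc <- partial_correlation(x, y, data.frame(c1))
  rxy <- cor(x, y); rxc <- cor(x, c1); ryc <- cor(y, c1)
  r_oracle <- (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  expect_equal(pc$r, r_oracle, tolerance = 1e-10)
  expect_equal(pc$df, n - 3)
  # y = x exactly
  expect_equal(partial_correlation(x, x, data.frame(c1))$r, 1, tolerance = 1e-12)
  # y driven only by the covariate: true partial correlation is zero
  pc0 <- partial_correlation(x, 3 * c1 + rnorm(n), data.frame(c1))
  expect_lt(abs(pc0$r), 0.3)
})

test_that("demographics table picks the right test per variable", {
  df <- generate_tables(tiny_spec(seed = 3))
  tab <- demographics_table(df)
  expect_identical(tab$test[tab$variable == "age"], "kruskal-wallis")
  expect_identical(tab$test[tab$variable == "sex"], "chi-square")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  tab2 <- demographics_table(df, continuous = c(age = "anova"))
  expect_identical(tab2$test[tab2$variable == "age"], "anova")
})
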