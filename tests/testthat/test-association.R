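test_that("AICc matches the closed form and ranks duplicate models equally", {
  set.seed(101)
  d <- tibble::tibble(y = rnorm(30), x = rnorm(30))
  mc <- fit_model_set(d, list(null = y ~ 1, x1 = y ~ x, x2 = y ~ x))
  res <- tidy(mc)
  expect_equal(res$delta_aicc[res$model == "x1"],
               res$delta_aicc[res$model == "x2"], tolerance = 1e-12)
  expect_equal(min(res$delta_aicc), 0)
  expect_equal(sum(res$weight), 1, tolerance = 1e-12)

  # hand formula: n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1), k counting sigma^2
  fit <- lm(y ~ x, data = dplyr::mutate(d, x = as.numeric(scale(x))))
  rss <- sum(residuals(fit)^2); n <- 30; k <- 3
  expect_equal(res$aicc[res$model == "x1"],
               n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-10)
})

test_that("a strong predictor lands in the best set; the null drops out", {
  wins <- vapply(1:30, function(s) {
    set.seed(s)
    d <- tibble::tibble(x = rnorm(40))
    d$y <- 1.5 * d$x + rnorm(40)
    res <- tidy(fit_model_set(d, list(null = y ~ 1, x = y ~ x)))
    res$in_best_set[res$model == "x"] && !res$in_best_set[res$model == "null"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("covariate standardization leaves ranks and deltas unchanged", {
  set.seed(102)
  d <- tibble::tibble(x = rnorm(25, 100, 20), z = rnorm(25, 5, 2))
  d$y <- 0.05 * d$x + rnorm(25)
  fl <- list(null = y ~ 1, x = y ~ x, xz = y ~ x + z)
  r1 <- tidy(fit_model_set(d, fl, scale_numeric = TRUE))
  r2 <- tidy(fit_model_set(d, fl, scale_numeric = FALSE))
  expect_equal(r1$model, r2$model)
  expect_equal(r1$delta_aicc, r2$delta_aicc, tolerance = 1e-9)
})

test_that("welch test matches the textbook oracle and handles degeneracy", {
  set.seed(103)
  x <- rnorm(14, 1); y <- rnorm(9, 0.2, 2)
  res <- welch_t(x, y)
  ref <- welch_oracle(x, y)
  expect_equal(res$statistic, ref$t, tolerance = 1e-12)
  expect_equal(res$df, ref$df, tolerance = 1e-12)
  expect_equal(res$p_value, ref$p, tolerance = 1e-12)

  z <- rnorm(6)
  same <- welch_t(z, z)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  flat <- welch_t(rep(2, 4), rep(2, 5))
  expect_equal(flat$p_value, 1)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("Scheirer-Ray-Hare reduces to Kruskal-Wallis when one factor collapses", {
  set.seed(104)
  y <- rnorm(24)
  a <- factor(rep(c("p", "q", "r"), each = 8))
  b <- factor(rep("only", 24))
  res <- scheirer_ray_hare(y, a, b)
  kw <- kruskal.test(y, a)
  expect_equal(res$H[res$term == "A"], unname(kw$statistic), tolerance = 1e-10)
  expect_equal(res$p_value[res$term == "A"], kw$p.value, tolerance = 1e-10)

  # constant response: H = 0 throughout
  cons <- scheirer_ray_hare(rep(3, 16), rep(c("a", "b"), 8),
                            rep(c("x", "x", "y", "y"), 4))
  expect_true(all(cons$H == 0))
  expect_error(scheirer_ray_hare(y, a, factor(c(rep("u", 8), rep("v", 16)))),
               "empty cell")
})

test_that("Scheirer-Ray-Hare finds a planted main effect but not ghosts", {
  set.seed(105)
  p_a <- p_b <- numeric(30)
  for (s in 1:30) {
    a <- factor(rep(c("f", "m"), each = 12))
    b <- factor(rep(c("j", "ad"), 12))
    y <- rnorm(24) + 3 * (a == "m")
    res <- scheirer_ray_hare(y, a, b)
    p_a[s] <- res$p_value[res$term == "A"]
    p_b[s] <- res$p_value[res$term == "B"]
  }
  expect_gte(mean(p_a < 0.05), 0.9)
  expect_lte(mean(p_b < 0.05), 0.2)
})

test_that("chi-square and correlation match their brute-force formulas", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p_value, 1)
  set.seed(106)
  tab <- matrix(c(12, 5, 7, 16), 2)
  res <- chi_square_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")

  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  res2 <- pearson_cor(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$estimate, r, tolerance = 1e-12)
  expect_equal(res2$statistic, r * sqrt(18 / (1 - r^2)), tolerance = 1e-12)
  expect_equal(pearson_cor(x, 2 * x + 1)$estimate, 1, tolerance = 1e-12)
})

test_that("family adjustment records membership and applies BH", {
  tests <- tibble::tibble(test = c("t1", "t2"), p_value = c(0.01, 0.04))
  out <- adjust_family(tests, family = "demo")
  expect_equal(out$p_adj, c(0.02, 0.04))
  expect_true(all(out$family == "demo"))
  single <- adjust_family(tests[1, ])
  expect_equal(single$p_adj, single$p_value)
  same <- adjust_family(tibble::tibble(p_value = rep(0.3, 4)))
  expect_equal(same$p_adj, rep(0.3, 4))
})

test_that("alpha associations warn on missing transforms and handle nulls", {
  vals <- c(2.1, 2.5, 1.9, 2.3, 2.2, 2.4, 2.6, 1.8)
  expect_warning(alpha_association(vals, rnorm(8), metric = "shannon"),
                 "untransformed")
  flat <- alpha_association(rep(1, 8), rnorm(8))
  expect_equal(flat$estimate, 0)
  # permuted covariate: CI covers zero at the nominal rate
  set.seed(107)
  covered <- vapply(1:50, function(s) {
    v <- rnorm(20); cov <- rnorm(20)
    fit <- lm(v ~ cov)
    ci <- confint(fit)["cov", ]
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
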