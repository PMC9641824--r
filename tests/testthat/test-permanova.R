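all_perms <- function(n) {
  idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  idx <- idx[apply(idx, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  idx[rowSums(sweep(idx, 2, seq_len(n), "!=")) > 0, , drop = FALSE]
}

sep_groups_dist <- function() {
  set.seed(81)
  pts <- rbind(matrix(rnorm(9, 0, 0.1), 3), matrix(rnorm(9, 10, 0.1), 3))
  dist(pts)
}

test_that("exhaustive permutations reproduce the enumeration oracle", {
  d <- sep_groups_dist()
  design <- tibble::tibble(grp = factor(rep(c("a", "b"), each = 3)))
  fit <- permanova(d, design, ~ grp, permutations = all_perms(6))
  # 2 of the 20 distinct 3|3 splits reach the observed F
  expect_equal(tidy(fit)$p_value[1], 2 / 20)
})

test_that("pseudo-F and R2 agree with vegan and partition totals", {
  tc <- tiny_community(82, n_taxa = 30)
  d <- beta_diversity(tc$com$counts, "bray")
  design <- tibble::tibble(sex = factor(tc$md$sex), age = tc$md$age_class)
  ref <- vegan::adonis2(d ~ sex + age, data = design, by = "margin",
                        permutations = 99)
  fit <- permanova(d, design, ~ sex + age, n_perm = 99, by = "margin")
  res <- tidy(fit)
  expect_equal(res$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(res$sum_sq[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  # sequential terms + residual account for the total (conservation)
  fit_seq <- permanova(d, design, ~ sex + age, n_perm = 19, by = "terms")
  rs <- tidy(fit_seq)
  expect_equal(sum(rs$r_squared[rs$term != "Total"]), 1, tolerance = 1e-10)
})

test_that("a single-term model gives identical marginal and sequential fits", {
  tc <- tiny_community(83, n_taxa = 20)
  d <- beta_diversity(tc$com$counts, "jaccard")
  design <- tibble::tibble(sex = factor(tc$md$sex))
  m1 <- permanova(d, design, ~ sex, n_perm = 199, by = "margin", seed = 5)
  m2 <- permanova(d, design, ~ sex, n_perm = 199, by = "terms", seed = 5)
  expect_equal(tidy(m1), tidy(m2))
  # and the permutation p is reproducible under a fixed seed
  m3 <- permanova(d, design, ~ sex, n_perm = 199, by = "margin", seed = 5)
  expect_identical(tidy(m1)$p_value, tidy(m3)$p_value)
})

test_that("confounded designs are rejected with the aliased term named", {
  d <- sep_groups_dist()
  design <- tibble::tibble(grp = factor(rep(c("a", "b"), each = 3)),
                           twin = factor(rep(c("x", "y"), each = 3)))
  expect_error(permanova(d, design, ~ grp + twin, n_perm = 9), "twin")
})

test_that("dispersion test matches vegan betadisper distances", {
  tc <- tiny_community(84, n_taxa = 25)
  d <- beta_diversity(tc$com$counts, "bray")
  grp <- factor(tc$md$sex)
  mine <- dispersion_test(d, grp, n_perm = 99, seed = 2)
  ref <- vegan::betadisper(d, grp, type = "median")
  expect_equal(sort(mine$distances$distance), sort(unname(ref$distances)),
               tolerance = 1e-4)
  expect_equal(mine$f, anova(ref)$`F value`[1], tolerance = 1e-3)
})

test_that("dispersion extremes behave as expected", {
  # identical groups: F ~ 0
  set.seed(85)
  pts <- matrix(rnorm(12), 6, 2)
  pts2 <- rbind(pts, pts)
  d <- dist(pts2)
  grp <- factor(rep(c("a", "b"), each = 6))
  res <- dispersion_test(d, grp, n_perm = 49, seed = 1)
  expect_lt(res$f, 1e-10)
  # a zero-spread group against a dispersed one: small p
  tight <- matrix(rep(c(0, 0), each = 8), 8, 2) + rnorm(16, 0, 1e-6)
  loose <- matrix(rnorm(16, 0, 3), 8, 2)
  d2 <- dist(rbind(tight, loose))
  res2 <- dispersion_test(d2, factor(rep(c("t", "l"), each = 8)),
                          n_perm = 199, seed = 1)
  expect_lt(res2$p_value, 0.05)
  expect_error(dispersion_test(d2, factor(rep("a", 16))), "two groups")
  expect_error(dispersion_test(d2, factor(c("a", rep("b", 15)))), "at least two samples")
})
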