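test_that("alpha indices match hand-computed toy values", {
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4), tolerance = 1e-10)
  # S_obs = 6, F1 = 3, F2 = 2 -> 6 + 3*2/(2*3) = 7
  expect_equal(chao1_index(c(1, 1, 1, 2, 2, 5)), 7)
  expect_equal(chao1_index(c(3, 4, 5)), 3)  # no singletons
  tree <- toy_tree()
  # sample {A, C}: edges A(1) + C(1) + both internal (1 + 1) = 4
  expect_equal(faith_pd(c(A = 2, B = 0, C = 1, D = 0), tree), 4)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("alpha transforms follow the conventional normalization", {
  expect_equal(transform_alpha(1, "shannon"), 0, ignore_attr = TRUE)
  expect_equal(transform_alpha(4, "faith_pd"), 0.25, ignore_attr = TRUE)
  expect_equal(transform_alpha(7, "chao1"), 7, ignore_attr = TRUE)
  expect_error(transform_alpha(c(1, -2), "shannon"), "nonpositive")
})

test_that("beta diversity matches toy constructions", {
  tree <- toy_tree()
  mat <- rbind(s1 = c(A = 1, B = 1, C = 1, D = 0),
               s2 = c(A = 0, B = 1, C = 1, D = 1))
  tbl <- counts_tbl(mat)
  expect_equal(as.numeric(beta_diversity(tbl, "jaccard")), 0.5)  # 1 - 2/4
  # disjoint single-tip samples on separate clades share no branches
  m2 <- rbind(s1 = c(A = 3, B = 0, C = 0, D = 0),
              s2 = c(A = 0, B = 0, C = 3, D = 0))
  expect_equal(as.numeric(beta_diversity(counts_tbl(m2), "unifrac",
                                         tree = tree)), 1)
  # weighted UniFrac by hand: |p_e - q_e| over edges x lengths
  # sample s1 all in A, s2 all in C: edges A, C and both internals differ by 1
  expect_equal(as.numeric(beta_diversity(counts_tbl(m2), "wunifrac",
                                         tree = tree)), 4)
  # identical samples: zero under every metric
  m3 <- rbind(s1 = c(A = 2, B = 1, C = 4, D = 0),
              s2 = c(A = 2, B = 1, C = 4, D = 0))
  for (metric in c("bray", "jaccard", "unifrac", "wunifrac")) {
    expect_equal(as.numeric(beta_diversity(counts_tbl(m3), metric,
                                           tree = tree)), 0,
                 info = metric)
  }
})

test_that("distances stay in range and ignore unobserved tree taxa", {
  set.seed(71)
  tc <- tiny_community(71, n_taxa = 25)
  tbl <- tc$com$counts
  for (metric in c("bray", "jaccard", "unifrac")) {
    d <- beta_diversity(tbl, metric, tree = tc$com$tree)
    expect_true(all(d >= 0 & d <= 1 + 1e-12), info = metric)
  }
  expect_true(all(beta_diversity(tbl, "wunifrac", tree = tc$com$tree) >= 0))
  # grafting an extra never-observed tip changes nothing (unweighted)
  tree2 <- ape::bind.tree(tc$com$tree,
                          ape::read.tree(text = "(ghost:0.7);"),
                          where = length(tc$com$tree$tip.label) + 1)
  d1 <- beta_diversity(tbl, "unifrac", tree = tc$com$tree)
  d2 <- beta_diversity(tbl, "unifrac", tree = tree2)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("implementation agrees with phyloseq/vegan/picante oracles", {
  tc <- tiny_community(72, n_taxa = 30)
  tbl <- tc$com$counts; tree <- tc$com$tree
  mat <- as.matrix(tbl[, -(1:2)]); rownames(mat) <- tbl$sample_id
  ps <- phyloseq::phyloseq(phyloseq::otu_table(mat, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree))
  for (w in c(FALSE, TRUE)) {
    mine <- as.matrix(beta_diversity(tbl, if (w) "wunifrac" else "unifrac",
                                     tree = tree))
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = w, normalized = FALSE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
  }
  expect_equal(as.numeric(beta_diversity(tbl, "bray")),
               as.numeric(vegan::vegdist(mat, "bray")), tolerance = 1e-12)
  expect_equal(as.numeric(beta_diversity(tbl, "jaccard")),
               as.numeric(vegan::vegdist(mat > 0, "jaccard")),
               tolerance = 1e-12)
  pd_ref <- picante::pd(mat, tree, include.root = TRUE)$PD
  expect_equal(alpha_diversity(tbl, tree, "faith_pd")$faith_pd, pd_ref,
               tolerance = 1e-10)
  expect_equal(alpha_diversity(tbl, metrics = "shannon")$shannon,
               unname(vegan::diversity(mat, "shannon")), tolerance = 1e-12)
})

test_that("principal coordinates reproduce Euclidean configurations", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ord <- pcoa_ordination(d3, k = 2)
  ev <- ord$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_gt(ev[1], 0)

  set.seed(73)
  pts <- matrix(rnorm(20), 10, 2)
  ord2 <- pcoa_ordination(dist(pts), k = 2)
  coords <- as.matrix(ord2$points[, c("axis1", "axis2")])
  expect_equal(as.numeric(dist(coords)), as.numeric(dist(pts)),
               tolerance = 1e-8)

  # duplicated samples land on identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  ord3 <- pcoa_ordination(dist(pts2), k = 2)
  c3 <- as.matrix(ord3$points[, c("axis1", "axis2")])
  expect_equal(c3[11, ], c3[1, ], tolerance = 1e-8)
  expect_warning(pcoa_ordination(d3, k = 5), "truncated")
})
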