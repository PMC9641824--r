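test_that("contaminant flagging is directional and thresholded", {
  n_true <- 47
  mat <- matrix(0, 3 + n_true, 3)
  colnames(mat) <- c("in_all_controls", "never_in_controls", "ambiguous")
  mat[1:3, 1] <- 10; mat[4, 1] <- 5                 # 3/3 controls, 1/47
  mat[4:20, 2] <- 8                                 # 0/3 controls
  mat[1:2, 3] <- 4; mat[4:8, 3] <- 4                # 2/3 controls, 5/47
  tbl <- counts_tbl(mat, is_control = c(rep(TRUE, 3), rep(FALSE, n_true)))
  flags <- flag_contaminants(tbl)
  expect_true(flags$contaminant[flags$taxon_id == "in_all_controls"])
  expect_false(flags$contaminant[flags$taxon_id == "never_in_controls"])
  # the 2x2 score equals the exhaustive hypergeometric (Fisher) oracle
  sc <- flags$score[flags$taxon_id == "ambiguous"]
  expect_equal(sc, fisher_oracle(2, 3, 5, n_true), tolerance = 1e-12)
})

test_that("taxon filter removes each off-target class and logs it", {
  mat <- matrix(5, 4, 10)
  colnames(mat) <- sprintf("t%02d", 1:10)
  tbl <- counts_tbl(mat)
  tax <- tibble::tibble(
    taxon_id = colnames(mat),
    Kingdom = c("Eukaryota", rep("Bacteria", 9)),
    Phylum = c("X", NA, rep("Firmicutes", 8)),
    Class = "c", Order = c(rep("o", 2), "Chloroplast", rep("o", 7)),
    Family = c(rep("f", 3), "Mitochondria", rep("f", 6)),
    Genus = "g"
  )
  out <- taxon_filter(tbl, tax)
  expect_equal(length(setdiff(names(out), c("sample_id", "is_control"))), 6)
  log <- attr(out, "removal_log")
  expect_equal(log$n_removed[log$rule == "not_bacteria"], 1L)
  expect_equal(log$n_removed[log$rule == "chloroplast"], 1L)
  expect_equal(log$n_removed[log$rule == "mitochondria"], 1L)
  expect_equal(log$n_removed[log$rule == "unresolved_phylum"], 1L)
  # a clean bacterial taxon with resolved phylum survives
  expect_true("t05" %in% names(out))
})

test_that("depth filter drops below 10,000 and keeps the boundary", {
  mk <- function(depths) {
    mat <- vapply(depths, function(d) {
      x <- rep(0, 5); x[1:2] <- c(d - 100, 100); x
    }, numeric(5))
    counts_tbl(t(mat))
  }
  out <- depth_filter(mk(c(9999, 10000, 50000)))
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "dropped_samples"), "s1")
  # the observed study-like range loses exactly its sub-floor sample
  out2 <- depth_filter(mk(c(6825, 14523, 50000)))
  expect_equal(nrow(out2), 2)
  expect_error(depth_filter(mk(c(100, 200))), "no sample")
})

test_that("rarefaction conserves depth, never inflates, and is seeded", {
  set.seed(52)
  mat <- matrix(rpois(8 * 30, 20), nrow = 8)
  tbl <- counts_tbl(mat)
  depth <- min(rowSums(mat))
  r1 <- rarefy(tbl, depth, seed = 999)
  m1 <- as.matrix(r1[, -(1:2)])
  expect_true(all(rowSums(m1) == depth))
  common <- intersect(colnames(m1), colnames(mat))
  expect_true(all(m1[, common] <= mat[, common]))
  expect_identical(r1, rarefy(tbl, depth, seed = 999))
  # a sample already at the target depth is untouched
  at_depth <- which(rowSums(mat) == depth)[1]
  expect_equal(unname(m1[at_depth, common]), unname(mat[at_depth, common]))
  expect_error(rarefy(tbl, max(rowSums(mat)) + 1), "at least")
})

test_that("rarefied counts have the hypergeometric mean", {
  x <- c(60, 30, 10)
  tbl <- counts_tbl(matrix(x, 1))
  depth <- 50
  draws <- vapply(1:400, function(s) {
    as.numeric(as.matrix(rarefy(tbl, depth, seed = s)[, -(1:2)])[1, 1])
  }, numeric(1))
  expected <- depth * x[1] / sum(x)
  se <- sqrt(depth * (x[1] / sum(x)) * (1 - x[1] / sum(x)) *
               (sum(x) - depth) / (sum(x) - 1)) / sqrt(400)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("the full ladder runs in order and is idempotent downstream", {
  md <- add_condition(simulate_metadata(10, 10, seed = 61))
  com <- simulate_community(community_scenario(
    seed = 62, n_taxa = 60, depth_range = c(11000, 15000),
    n_low_depth = 1, n_pcr_failed = 0), md)
  prep <- suppressWarnings(prep_community(com$counts, com$taxonomy,
                                          min_depth = 10000))
  expect_false(any(prep$is_control))
  flags <- attr(prep, "contaminants")
  expect_true(all(flags$taxon_id[grepl("CONTAM", flags$taxon_id)] %in%
                    flags$taxon_id[flags$contaminant]))
  expect_false(any(grepl("OFFTARGET", names(prep))))
  depths <- rowSums(as.matrix(prep[, -(1:2)]))
  expect_true(all(depths == attr(prep, "rarefied_depth")))
  # re-applying the downstream filters is a no-op
  again <- depth_filter(taxon_filter(prep, com$taxonomy),
                        min_depth = attr(prep, "rarefied_depth"))
  expect_equal(as.matrix(again[, -(1:2)]), as.matrix(prep[, -(1:2)]))
  again2 <- rarefy(prep, attr(prep, "rarefied_depth"), seed = 999)
  expect_equal(as.matrix(again2[, -(1:2)]), as.matrix(prep[, -(1:2)]))
})
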