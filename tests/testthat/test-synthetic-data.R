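test_that("track construction matches the scenario plan", {
  sc <- track_scenario(seed = 2, n_migratory_days = 5,
                       stopover_run_lengths = integer(),
                       daily_step_km = 200, heading_deg = 0,
                       endpoint = "arrival")
  tr <- simulate_track(sc)
  lab <- tr$truth$labels
  expect_equal(lab$day_class[1:5], rep("migratory", 5))
  expect_equal(tr$truth$endpoint_date, lab$date[6])
  expect_equal(tr$truth$endpoint, "arrival")

  # one 3-day stopover run after migratory day 2: days 3-5 are stopover
  sc2 <- track_scenario(seed = 3, n_migratory_days = 5,
                        stopover_run_lengths = c(3), stopover_after = 2)
  tr2 <- simulate_track(sc2)
  expect_equal(tr2$truth$labels$day_class[3:5], rep("stopover", 3))
  segs <- daily_metrics(subsample_daylight(tr2$fixes))
  expect_true(all(segs$beeline_km[3:5] < 19))
})

test_that("scenario invariants are enforced", {
  expect_error(track_scenario(heading_deg = 180, endpoint = "arrival"),
               "northern")
  expect_error(track_scenario(daily_step_km = 30), "40-km")
  expect_error(track_scenario(stopover_run_lengths = c(6)), "lookahead")
  expect_error(track_scenario(n_predeath_stopover_days = 3,
                              n_migratory_days = 5), "die before")
})

test_that("fixed seeds reproduce tracks and communities byte-identically", {
  sc <- track_scenario(seed = 9, n_migratory_days = 4)
  expect_identical(simulate_track(sc), simulate_track(sc))
  md <- simulate_metadata(6, 6, seed = 5)
  expect_identical(md, simulate_metadata(6, 6, seed = 5))
  cs <- community_scenario(seed = 5, n_taxa = 30, n_pcr_failed = 0)
  expect_identical(simulate_community(cs, md), simulate_community(cs, md))
})

test_that("metadata emulates the dimorphic cohort", {
  md <- simulate_metadata(36, 18, seed = 1, condition_date_slope = 0)
  fem <- md$mass_g[md$sex == "female"]
  # sample mean within 3 s.e. of the 629 g population mean
  expect_lt(abs(mean(fem) - 629), 3 * 77 / sqrt(36))
  mal <- md$mass_g[md$sex == "male"]
  expect_lt(abs(mean(mal) - 518), 3 * 60 / sqrt(18))
  expect_true(all(md$euring_age >= 5))
  expect_identical(levels(md$age_class), c("juvenile", "adult"))
  expect_equal(nrow(simulate_metadata(0, 0)), 0)
})

test_that("null condition-date slope is covered by the regression CI", {
  covered <- vapply(1:100, function(s) {
    md <- add_condition(simulate_metadata(20, 0, seed = s,
                                          condition_date_slope = 0))
    fit <- lm(smi_g ~ capture_julian, data = md)
    ci <- confint(fit)["capture_julian", ]
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("community counts respect depths, controls and planted structure", {
  md <- add_condition(simulate_metadata(10, 10, seed = 2))
  cs <- community_scenario(seed = 7, n_taxa = 50, depth_range = c(3000, 5000),
                           n_low_depth = 0, n_pcr_failed = 0)
  com <- simulate_community(cs, md)
  mat <- as.matrix(com$counts[, -(1:2)])
  # conservation: depths recorded match the table
  expect_equal(unname(rowSums(mat)), com$sample_info$depth)
  expect_equal(sum(com$counts$is_control), 3)
  # contaminants present in every control
  contam <- com$truth$taxa$taxon_id[com$truth$taxa$contaminant]
  ctrl <- mat[com$counts$is_control, contam, drop = FALSE]
  expect_true(all(ctrl > 0))
  # ... and rare in true samples
  true_prev <- colMeans(mat[!com$counts$is_control, contam, drop = FALSE] > 0)
  expect_true(all(true_prev < 0.5))

  expect_error(
    simulate_community(community_scenario(seed = 1, n_taxa = 10,
                                          sex_effect_taxa = "ASV_099"), md),
    "not in taxon set")
})

test_that("a single-taxon community puts every read in that taxon", {
  md <- simulate_metadata(3, 3, seed = 4)
  cs <- community_scenario(seed = 4, n_taxa = 1, n_controls = 0,
                           n_contaminants = 0, n_offtarget = 0,
                           n_pcr_failed = 0, n_low_depth = 0,
                           depth_range = c(500, 600))
  com <- simulate_community(cs, md)
  mat <- as.matrix(com$counts[, -(1:2)])
  expect_true(all(mat[, 1] == com$sample_info$depth))
  expect_equal(unname(apply(mat, 1, shannon_index)), rep(0, 6))
})

test_that("zero planted effects give an exchangeable null community", {
  # sex labels carry no signal: PERMANOVA p is not systematically small
  ps <- vapply(1:25, function(s) {
    tc <- tiny_community(700 + s, n_f = 6, n_m = 6, n_taxa = 30,
                         sex_lfc = 0, condition_taxon_slope = 0,
                         date_evenness_slope = 0)
    d <- beta_diversity(tc$com$counts, "bray")
    fit <- permanova(d, tibble::tibble(sex = factor(tc$md$sex)), ~ sex,
                     n_perm = 99)
    tidy(fit)$p_value[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.25)   # uniform null has mean ~0.5
  expect_lte(mean(ps < 0.05), 0.2)
})
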