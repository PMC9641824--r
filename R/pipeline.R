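#' Default pipeline configuration
#'
#' One nested list holding every stage's parameters and seeds. The cohort
#' and tracking defaults reproduce the study conditions the pipeline
#' emulates: 36 females and 18 males trapped in April; 38 GPS-tagged birds
#' of which 19 arrive, 15 die (11 of them at the stopover without ever
#' departing) and 4 lose connection, so that survivors among tracked birds
#' excluding losses are 19 of 34; adults plan longer migrations than
#' juveniles and later-trapped birds plan shorter ones.
#'
#' @param seed Master integer seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  base <- as.integer(abs(seed) %% 1000000L)
  list(
    seed = as.integer(seed),
    stage_seeds = list(
      metadata = base * 100L + 1L,
      tracks = base * 100L + 2L,
      community = base * 100L + 3L,
      permanova = base * 100L + 4L,
      dispersion = base * 100L + 5L
    ),
    cohort = list(n_females = 36, n_males = 18, condition_date_slope = -2,
                  date_range = c(95, 115), p_juvenile = 0.43),
    tracking = list(
      n_arrival_f = 16, n_death_f = 11, n_loss_f = 3,
      n_arrival_m = 3, n_death_m = 4, n_loss_m = 1,
      n_death_at_stopover = 11,
      daily_step_km = 150,
      mig_days_juvenile = 15, mig_days_adult = 29, mig_days_sd = 4,
      mig_days_date_slope = -0.6,
      n_winter_known = 13
    ),
    community = list(n_taxa = 150, dispersion = 50, sex_lfc = 1.5,
                     date_evenness_slope = -0.02,
                     condition_taxon_slope = -0.8,
                     depth_range = c(14523, 76393), n_low_depth = 1,
                     n_pcr_failed = 6, n_controls = 3,
                     n_contaminants = 5, n_offtarget = 4),
    prep = list(decontam_threshold = 0.5, min_depth = 10000,
                rarefaction_seed = 999),
    permanova = list(n_perm = 9999, by = "margin",
                     metrics = c("unifrac", "wunifrac", "jaccard", "bray")),
    dispersion = list(n_perm = 999),
    da = list(prevalence_min = 0.10, q_threshold = 0.01,
              w_percentile = 0.85, rank = "Genus"),
    analyses = list(h1_sex = TRUE, h2_date = TRUE, h3_condition = TRUE,
                    sex_stratified = TRUE)
  )
}

#' Validate (and fill) a pipeline configuration
#'
#' Checks a configuration list (or JSON file) against the schema of
#' [default_run_config()]: unknown keys are an error, missing keys are
#' filled with defaults, and thresholds are range-checked.
#'
#' @param config A configuration list, or path to a JSON file written by
#'   [write_run_config()].
#' @return The validated, fully populated `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_run_config(config$seed %||% 1)
  check_keys <- function(given, def, path = "") {
    unknown <- setdiff(names(given), names(def))
    if (length(unknown)) {
      abort(paste0("unknown config key(s): ",
                   paste0(path, unknown, collapse = ", ")))
    }
    for (nm in names(given)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        check_keys(as.list(given[[nm]]), def[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check_keys(config, defaults)
  cfg <- modify_defaults(defaults, config)
  with(cfg$prep, {
    if (decontam_threshold <= 0 || decontam_threshold >= 1) {
      abort("prep.decontam_threshold must lie in (0, 1)")
    }
    if (min_depth <= 0) abort("prep.min_depth must be positive")
  })
  if (cfg$permanova$n_perm < 1) abort("permanova.n_perm must be >= 1")
  if (any(unlist(cfg$cohort[c("n_females", "n_males")]) < 0)) {
    abort("cohort sizes must be nonnegative")
  }
  with(cfg$da, {
    if (q_threshold <= 0 || q_threshold >= 1 ||
        prevalence_min <= 0 || prevalence_min >= 1 ||
        w_percentile <= 0 || w_percentile >= 1) {
      abort("da thresholds must lie in (0, 1)")
    }
  })
  structure(cfg, class = "run_config")
}

modify_defaults <- function(def, given) {
  for (nm in names(given)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]])) &&
        (is.list(given[[nm]]))) {
      def[[nm]] <- modify_defaults(def[[nm]], given[[nm]])
    } else if (!is.null(given[[nm]])) {
      value <- given[[nm]]
      # JSON round-trips simplify scalars; preserve default types
      if (is.numeric(def[[nm]]) && is.numeric(value)) value <- as.numeric(value)
      def[[nm]] <- value
    }
  }
  def
}

#' @rdname validate_run_config
#' @param path Output JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full simulation-to-association pipeline
#'
#' Executes the stages in order — simulate, segment, prep, community
#' metrics, differential abundance, associations — with every intermediate
#' product written to `out_dir` as plain text, and a manifest recording
#' seeds, configuration and per-stage row counts. Stages communicate only
#' through those files, and the whole run is deterministic for a fixed
#' configuration.
#'
#' @param config A `run_config` (validated if not already).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and the paths written.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("migrobiome")),
                   config = unclass(cfg), stages = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- res
    res
  }
  run_stage("simulate", function() stage_simulate(cfg, out_dir))
  run_stage("segment", function() stage_segment(cfg, out_dir))
  run_stage("prep", function() stage_prep(cfg, out_dir))
  run_stage("community", function() stage_community(cfg, out_dir))
  run_stage("da", function() stage_da(cfg, out_dir))
  run_stage("associate", function() stage_associate(cfg, out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, out_dir = out_dir))
}

# ---- stages ---------------------------------------------------------------

stage_simulate <- function(cfg, out_dir) {
  md <- simulate_metadata(cfg$cohort$n_females, cfg$cohort$n_males,
                          seed = cfg$stage_seeds$metadata,
                          condition_date_slope = cfg$cohort$condition_date_slope,
                          date_range = cfg$cohort$date_range,
                          p_juvenile = cfg$cohort$p_juvenile)
  md <- add_condition(md)

  # assign tagged birds and their true endpoints within each sex
  tk <- cfg$tracking
  set.seed(cfg$stage_seeds$tracks)
  plan <- dplyr::bind_rows(
    assign_endpoints(md[md$sex == "female", ], tk$n_arrival_f, tk$n_death_f,
                     tk$n_loss_f),
    assign_endpoints(md[md$sex == "male", ], tk$n_arrival_m, tk$n_death_m,
                     tk$n_loss_m)
  )
  death_ids <- plan$id[!is.na(plan$endpoint) & plan$endpoint == "death"]
  n_stop_death <- min(tk$n_death_at_stopover, length(death_ids))
  stopover_death <- death_ids[seq_len(n_stop_death)]

  md <- dplyr::left_join(md, plan, by = "id")
  tracks <- purrr::pmap(
    list(md$id, md$sex, md$age_class, md$capture_julian, md$endpoint,
         seq_len(nrow(md))),
    function(id, sex, age, jday, endpoint, i) {
      if (is.na(endpoint)) return(NULL)
      base_days <- if (age == "juvenile") tk$mig_days_juvenile else tk$mig_days_adult
      n_mig <- max(5, round(base_days +
        tk$mig_days_date_slope * (jday - mean(cfg$cohort$date_range)) +
        rnorm(1, 0, tk$mig_days_sd)))
      at_stopover <- endpoint == "death" && id %in% stopover_death
      # en-route deaths strike early in the journey; stopover deaths follow a
      # right-skewed few-day wait (most birds die within the first week)
      if (endpoint == "death" && !at_stopover) n_mig <- sample(2:10, 1)
      sc <- track_scenario(
        seed = cfg$stage_seeds$tracks + i,
        start_date = as.Date("2018-12-31") + jday,
        n_migratory_days = if (at_stopover) 0 else n_mig,
        stopover_run_lengths = if (at_stopover || endpoint == "death") {
          integer()
        } else {
          sample(1:3, sample(1:3, 1), replace = TRUE)
        },
        daily_step_km = tk$daily_step_km,
        endpoint = endpoint,
        n_predeath_stopover_days = if (at_stopover) {
          min(stats::rgeom(1, 0.2), 22)
        } else 0,
        stopover_spread_km = if (at_stopover) 0.5 else 5
      )
      simulate_track(sc, individual_id = id)
    }
  )
  tracks <- purrr::compact(tracks)
  fixes <- dplyr::bind_rows(purrr::map(tracks, "fixes"))
  truth_tracks <- purrr::map(tracks, function(t) {
    list(individual_id = t$fixes$individual_id[1],
         endpoint = t$truth$endpoint,
         endpoint_date = as.character(t$truth$endpoint_date),
         labels = t$truth$labels)
  })

  com_cfg <- cfg$community
  scenario <- community_scenario(
    seed = cfg$stage_seeds$community,
    n_taxa = com_cfg$n_taxa, dispersion = com_cfg$dispersion,
    sex_lfc = com_cfg$sex_lfc,
    date_evenness_slope = com_cfg$date_evenness_slope,
    condition_taxon_slope = com_cfg$condition_taxon_slope,
    depth_range = com_cfg$depth_range, n_low_depth = com_cfg$n_low_depth,
    n_pcr_failed = com_cfg$n_pcr_failed, n_controls = com_cfg$n_controls,
    n_contaminants = com_cfg$n_contaminants,
    n_offtarget = com_cfg$n_offtarget
  )
  com <- simulate_community(scenario, md)

  readr::write_csv(fixes, file.path(out_dir, "gps_fixes.csv"))
  readr::write_csv(md, file.path(out_dir, "metadata.csv"))
  readr::write_tsv(com$counts, file.path(out_dir, "asv_counts.tsv"))
  readr::write_tsv(com$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  ape::write.tree(com$tree, file.path(out_dir, "tree.nwk"))
  readr::write_tsv(com$sample_info, file.path(out_dir, "sample_info.tsv"))
  jsonlite::write_json(
    list(tracks = truth_tracks, taxa = com$truth$taxa,
         planted = list(sex_lfc = com$truth$sex_lfc,
                        date_evenness_slope = com$truth$date_evenness_slope,
                        condition_taxon_slope = com$truth$condition_taxon_slope)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  list(n_individuals = nrow(md), n_tracked = length(tracks),
       n_fixes = nrow(fixes), n_taxa = length(taxon_cols(com$counts)))
}

assign_endpoints <- function(md_sex, n_arr, n_death, n_loss) {
  n_tag <- n_arr + n_death + n_loss
  if (n_tag > nrow(md_sex)) abort("more tagged birds than individuals")
  tagged <- sample(md_sex$id, n_tag)
  tibble::tibble(
    id = md_sex$id,
    endpoint_true = NA_character_
  ) |>
    dplyr::mutate(endpoint_true = replace(
      .data$endpoint_true, match(tagged, .data$id),
      sample(rep(c("arrival", "death", "loss"), c(n_arr, n_death, n_loss)))
    )) |>
    dplyr::rename(endpoint = "endpoint_true")
}

stage_segment <- function(cfg, out_dir) {
  fixes <- read_gps_fixes(file.path(out_dir, "gps_fixes.csv"))
  md <- readr::read_csv(file.path(out_dir, "metadata.csv"),
                        show_col_types = FALSE)
  seg <- segment_track(fixes)
  set.seed(cfg$stage_seeds$tracks + 10000L)
  winter_ids <- with(seg$outcomes, sample(
    individual_id[endpoint == "arrival"],
    min(cfg$tracking$n_winter_known, sum(endpoint == "arrival"))
  ))
  summaries <- seg$segments |>
    dplyr::group_split(.data$individual_id) |>
    purrr::map(function(s) {
      id <- s$individual_id[1]
      out <- seg$outcomes[seg$outcomes$individual_id == id, ]
      capture <- c(s$roost_start_lat[1], s$roost_start_lon[1])
      winter <- if (id %in% winter_ids) {
        c(runif(1, -30, -15), runif(1, 20, 35))
      } else NULL
      breeding <- if (out$endpoint == "arrival" && !is.null(winter)) {
        c(out$endpoint_lat, out$endpoint_lon)
      } else NULL
      migration_summary(s, out, capture, winter, breeding)
    }) |>
    dplyr::bind_rows()
  readr::write_tsv(seg$segments, file.path(out_dir, "segments.tsv"))
  readr::write_tsv(seg$outcomes, file.path(out_dir, "outcomes.tsv"))
  readr::write_tsv(summaries, file.path(out_dir, "migration.tsv"))
  list(n_segments = nrow(seg$segments), n_outcomes = nrow(seg$outcomes))
}

stage_prep <- function(cfg, out_dir) {
  counts <- readr::read_tsv(file.path(out_dir, "asv_counts.tsv"),
                            show_col_types = FALSE)
  taxonomy <- readr::read_tsv(file.path(out_dir, "taxonomy.tsv"),
                              show_col_types = FALSE)
  info <- readr::read_tsv(file.path(out_dir, "sample_info.tsv"),
                          show_col_types = FALSE)
  # amplification failures never reach the sequencing ladder
  failed <- info$sample_id[info$pcr_failed]
  counts <- dplyr::filter(counts, !.data$sample_id %in% failed)
  prepared <- prep_community(
    counts, taxonomy,
    decontam_threshold = cfg$prep$decontam_threshold,
    min_depth = cfg$prep$min_depth,
    seed = cfg$prep$rarefaction_seed
  )
  readr::write_tsv(prepared, file.path(out_dir, "prepared_counts.tsv"))
  readr::write_tsv(attr(prepared, "contaminants"),
                   file.path(out_dir, "contaminant_flags.tsv"))
  log <- attr(prepared, "removal_log")
  readr::write_tsv(log, file.path(out_dir, "taxon_removal_log.tsv"))
  list(n_samples = nrow(prepared),
       n_taxa = length(taxon_cols(prepared)),
       n_contaminants = sum(attr(prepared, "contaminants")$contaminant),
       n_dropped_depth = length(attr(prepared, "dropped_samples")),
       rarefied_depth = attr(prepared, "rarefied_depth"))
}

stage_community <- function(cfg, out_dir) {
  prepared <- readr::read_tsv(file.path(out_dir, "prepared_counts.tsv"),
                              show_col_types = FALSE)
  tree <- ape::read.tree(file.path(out_dir, "tree.nwk"))
  md <- readr::read_csv(file.path(out_dir, "metadata.csv"),
                        show_col_types = FALSE)
  md <- md[match(prepared$sample_id, md$id), ]

  alpha <- alpha_diversity(prepared, tree)
  alpha$shannon_log10 <- transform_alpha(alpha$shannon, "shannon")
  alpha$faith_pd_inv <- transform_alpha(alpha$faith_pd, "faith_pd")
  readr::write_tsv(alpha, file.path(out_dir, "alpha.tsv"))

  perm_rows <- list()
  disp_rows <- list()
  ord_rows <- list()
  design <- tibble::tibble(sex = factor(md$sex), age = md$age_class)
  for (metric in cfg$permanova$metrics) {
    d <- beta_diversity(prepared, metric, tree = tree)
    dm <- as.matrix(d)
    readr::write_tsv(tibble::as_tibble(dm, rownames = "sample_id"),
                     file.path(out_dir, paste0("beta_", metric, ".tsv")))
    fit <- permanova(d, design, ~ sex + age,
                     n_perm = cfg$permanova$n_perm, by = cfg$permanova$by,
                     seed = cfg$stage_seeds$permanova)
    perm_rows[[metric]] <- dplyr::mutate(tidy(fit), metric = metric,
                                         model = "sex+age", .before = 1)
    dt <- dispersion_test(d, design$sex, n_perm = cfg$dispersion$n_perm,
                          seed = cfg$stage_seeds$dispersion)
    disp_rows[[metric]] <- tibble::tibble(metric = metric, grouping = "sex",
                                          f = dt$f, p_value = dt$p_value)
    ord <- pcoa_ordination(d, k = 2)
    ord_rows[[metric]] <- dplyr::mutate(ord$points, metric = metric,
                                        .before = 1)
  }

  # female-only models for condition and capture date
  fem <- md$sex == "female"
  if (cfg$analyses$sex_stratified && sum(fem) >= 8) {
    fem_counts <- prepared[fem, ]
    fem_design <- tibble::tibble(condition = md$smi_g[fem],
                                 date = md$capture_julian[fem])
    for (metric in cfg$permanova$metrics) {
      d <- beta_diversity(fem_counts, metric, tree = tree)
      for (term in c("condition", "date")) {
        fit <- permanova(d, fem_design, stats::as.formula(paste("~", term)),
                         n_perm = cfg$permanova$n_perm,
                         seed = cfg$stage_seeds$permanova)
        perm_rows[[paste(metric, term)]] <-
          dplyr::mutate(tidy(fit), metric = metric,
                        model = paste0("female:", term), .before = 1)
      }
    }
  }
  readr::write_tsv(dplyr::bind_rows(perm_rows),
                   file.path(out_dir, "permanova.tsv"))
  readr::write_tsv(dplyr::bind_rows(disp_rows),
                   file.path(out_dir, "dispersion.tsv"))
  readr::write_tsv(dplyr::bind_rows(ord_rows),
                   file.path(out_dir, "ordination.tsv"))
  list(n_alpha = nrow(alpha), n_permanova = length(perm_rows))
}

stage_da <- function(cfg, out_dir) {
  prepared <- readr::read_tsv(file.path(out_dir, "prepared_counts.tsv"),
                              show_col_types = FALSE)
  taxonomy <- readr::read_tsv(file.path(out_dir, "taxonomy.tsv"),
                              show_col_types = FALSE)
  md <- readr::read_csv(file.path(out_dir, "metadata.csv"),
                        show_col_types = FALSE)
  md <- md[match(prepared$sample_id, md$id), ]
  config <- da_config(prevalence_min = cfg$da$prevalence_min,
                      q_threshold = cfg$da$q_threshold,
                      w_percentile = cfg$da$w_percentile)
  agg <- aggregate_rank(prepared, taxonomy, cfg$da$rank)

  fits <- list()
  if (cfg$analyses$h1_sex) {
    fits$sex <- ancombc_fit(agg, factor(md$sex), config)
  }
  fem <- md$sex == "female"
  if (cfg$analyses$h3_condition && sum(fem) >= 8) {
    fits$condition_female <- ancombc_fit(agg[fem, ], md$smi_g[fem], config)
  }
  if (cfg$analyses$h2_date && sum(fem) >= 8) {
    fits$date_female <- ancombc_fit(agg[fem, ], md$capture_julian[fem], config)
  }
  res <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(tidy(f), analysis = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
  readr::write_tsv(res, file.path(out_dir, "da_results.tsv"))
  list(n_tests = nrow(res),
       n_selected = sum(res$selected))
}

stage_associate <- function(cfg, out_dir) {
  md <- readr::read_csv(file.path(out_dir, "metadata.csv"),
                        show_col_types = FALSE)
  mig <- readr::read_tsv(file.path(out_dir, "migration.tsv"),
                         show_col_types = FALSE)
  alpha <- readr::read_tsv(file.path(out_dir, "alpha.tsv"),
                           show_col_types = FALSE)
  if ("endpoint" %in% names(md)) {
    md <- dplyr::rename(md, endpoint_true = "endpoint")
  }
  md <- dplyr::left_join(md, mig, by = c(id = "individual_id")) |>
    dplyr::mutate(survived = dplyr::case_when(
      .data$endpoint == "arrival" ~ "survivor",
      .data$endpoint == "death" ~ "non-survivor",
      TRUE ~ NA_character_
    ))

  tests <- list()
  for (s in c("female", "male")) {
    sub <- md[md$sex == s, ]
    tests[[paste0("smi_age_", s)]] <- dplyr::mutate(
      welch_t(sub$smi_g[sub$age_class == "juvenile"],
              sub$smi_g[sub$age_class == "adult"]),
      test = paste0("smi~age (", s, ")"), .before = 1)
    surv <- sub[!is.na(sub$survived), ]
    if (min(table(surv$survived)) >= 2) {
      tests[[paste0("smi_surv_", s)]] <- dplyr::mutate(
        welch_t(surv$smi_g[surv$survived == "survivor"],
                surv$smi_g[surv$survived == "non-survivor"]),
        test = paste0("smi~survival (", s, ")"), .before = 1)
    }
  }
  srh <- scheirer_ray_hare(md$capture_julian, md$sex, md$age_class)
  tests$srh <- srh |>
    dplyr::transmute(test = paste0("capture_date~", .data$term, " (SRH)"),
                     statistic = .data$H, df = as.numeric(.data$df),
                     p_value = .data$p_value, effect = NA_real_)
  tagged <- md[!is.na(md$survived), ]
  surv_tab <- table(tagged$sex, tagged$survived)
  if (all(dim(surv_tab) == 2) && all(rowSums(surv_tab) > 0)) {
    tests$chi_surv_sex <- dplyr::mutate(chi_square_2x2(surv_tab),
                                        test = "survival~sex (chi-square)",
                                        effect = NA_real_, .before = 1)
  }
  demo <- adjust_family(dplyr::bind_rows(tests), family = "demographic")

  # correlations among migration measures
  surv_mig <- md[md$endpoint %in% "arrival", ]
  cors <- dplyr::bind_rows(
    dplyr::mutate(pearson_cor(surv_mig$capture_julian,
                              surv_mig$post_eilat_distance_km),
                  test = "capture_date~post_stopover_distance", .before = 1),
    if (sum(!is.na(surv_mig$total_migration_distance_km)) >= 3) {
      dplyr::mutate(pearson_cor(surv_mig$total_migration_distance_km,
                                surv_mig$post_eilat_distance_km),
                    test = "total~post_stopover_distance", .before = 1)
    }
  )

  # AICc model sets: capture date ~ condition/age, per sex
  model_rows <- list()
  for (s in c("female", "male")) {
    sub <- md[md$sex == s, ]
    mc <- fit_model_set(sub, list(
      null = capture_julian ~ 1,
      condition = capture_julian ~ smi_g,
      additive = capture_julian ~ smi_g + age_class,
      interaction = capture_julian ~ smi_g * age_class
    ))
    model_rows[[s]] <- dplyr::mutate(tidy(mc), sex = s,
                                     response = "capture_julian", .before = 1)
  }
  fem_surv <- md[md$sex == "female" & md$endpoint %in% "arrival", ]
  if (nrow(fem_surv) >= 10) {
    mc <- fit_model_set(fem_surv, list(
      null = post_eilat_distance_km ~ 1,
      condition = post_eilat_distance_km ~ smi_g,
      additive = post_eilat_distance_km ~ smi_g + age_class,
      interaction = post_eilat_distance_km ~ smi_g * age_class
    ))
    model_rows$post_eilat <- dplyr::mutate(tidy(mc), sex = "female",
                                           response = "post_eilat_distance_km",
                                           .before = 1)
  }

  # alpha diversity vs condition, date and survival (females)
  fem <- md[md$sex == "female", ]
  fem_alpha <- dplyr::inner_join(alpha, fem, by = c(sample_id = "id"))
  alpha_rows <- list()
  for (metric in c("shannon_log10", "chao1", "faith_pd_inv")) {
    vals <- fem_alpha[[metric]]
    attr(vals, "transformed") <- TRUE
    for (cov in c("smi_g", "capture_julian")) {
      alpha_rows[[paste(metric, cov)]] <- dplyr::mutate(
        alpha_association(vals, fem_alpha[[cov]], "regression"),
        test = paste0(metric, "~", cov), .before = 1)
    }
    surv <- fem_alpha[!is.na(fem_alpha$survived), ]
    if (min(table(surv$survived)) >= 2) {
      vals_s <- surv[[metric]]
      attr(vals_s, "transformed") <- TRUE
      alpha_rows[[paste(metric, "surv")]] <- dplyr::mutate(
        alpha_association(vals_s, surv$survived, "welch"),
        test = paste0(metric, "~survival"), .before = 1)
    }
  }

  readr::write_tsv(demo, file.path(out_dir, "demographic_tests.tsv"))
  readr::write_tsv(cors, file.path(out_dir, "correlations.tsv"))
  readr::write_tsv(dplyr::bind_rows(model_rows),
                   file.path(out_dir, "model_selection.tsv"))
  readr::write_tsv(dplyr::bind_rows(alpha_rows),
                   file.path(out_dir, "alpha_associations.tsv"))
  list(n_demographic = nrow(demo), n_correlations = nrow(cors),
       n_models = nrow(dplyr::bind_rows(model_rows)),
       n_alpha_tests = length(alpha_rows))
}
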