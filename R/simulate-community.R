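#' Community simulation scenario
#'
#' Parameters of the Dirichlet-multinomial generator for cloacal ASV count
#' tables with planted, recoverable effects: a compositional shift between
#' the sexes on a designated taxon set, a capture-date effect on community
#' evenness, and a body-condition-linked shift of one pathogen-like taxon
#' (an *Escherichia-Shigella* genus analogue). Negative-control samples
#' carry a fixed set of laboratory-contaminant taxa.
#'
#' @param seed Integer RNG seed.
#' @param n_taxa Number of true community taxa (ASVs).
#' @param base_log_abundance Optional numeric vector (length `n_taxa`) of
#'   baseline log relative abundances; drawn `N(0, 1.5)` when `NULL`.
#' @param dispersion Dirichlet concentration; lower values give more
#'   sample-to-sample overdispersion.
#' @param sex_effect_taxa Character vector of taxa shifted between sexes
#'   (`NULL` picks the first 8 when `n_taxa >= 20`, otherwise none).
#' @param sex_lfc Log-fold shift applied to `sex_effect_taxa` in males.
#' @param date_evenness_slope Per-day multiplier on the spread of log
#'   abundances: negative values make later-captured samples less even
#'   (lower Shannon diversity); `0` removes the effect.
#' @param condition_taxon Taxon whose log abundance tracks body condition
#'   (`NULL` picks one when `n_taxa >= 20`).
#' @param condition_taxon_slope Log-abundance change of `condition_taxon`
#'   per standard deviation of body condition (negative: leaner birds carry
#'   more).
#' @param depth_range Read-depth range (uniform) for ordinary samples.
#' @param n_low_depth Number of samples drawn instead from the 6825-9999
#'   range, below the 10,000-read retention floor.
#' @param n_pcr_failed Number of samples flagged as amplification failures
#'   (excluded from analysis upstream of the read-depth ladder).
#' @param n_controls Number of negative-control samples.
#' @param n_contaminants Number of contaminant taxa planted in every
#'   control.
#' @param n_offtarget Number of off-target taxa (non-bacterial, chloroplast,
#'   mitochondrial, unresolved-phylum) added to exercise the taxonomy
#'   filter.
#' @return A list of class `community_scenario`.
#' @export
community_scenario <- function(seed = 1,
                               n_taxa = 150,
                               base_log_abundance = NULL,
                               dispersion = 50,
                               sex_effect_taxa = NULL,
                               sex_lfc = 1.5,
                               date_evenness_slope = -0.02,
                               condition_taxon = NULL,
                               condition_taxon_slope = -0.8,
                               depth_range = c(14523, 76393),
                               n_low_depth = 1,
                               n_pcr_failed = 6,
                               n_controls = 3,
                               n_contaminants = 5,
                               n_offtarget = 4) {
  if (any(depth_range < 1)) abort("read depths must be >= 1")
  if (n_taxa < 1) abort("need at least one taxon")
  structure(list(
    seed = as.integer(seed), n_taxa = n_taxa,
    base_log_abundance = base_log_abundance,
    dispersion = dispersion,
    sex_effect_taxa = sex_effect_taxa, sex_lfc = sex_lfc,
    date_evenness_slope = date_evenness_slope,
    condition_taxon = condition_taxon,
    condition_taxon_slope = condition_taxon_slope,
    depth_range = depth_range, n_low_depth = n_low_depth,
    n_pcr_failed = n_pcr_failed,
    n_controls = n_controls, n_contaminants = n_contaminants,
    n_offtarget = n_offtarget
  ), class = "community_scenario")
}

#' Simulate an ASV count table with taxonomy, phylogeny and ground truth
#'
#' Per sample, log relative abundances are the baseline plus the planted
#' sex, condition and date-evenness effects; counts are then drawn
#' Dirichlet-multinomial at a depth from `depth_range`. Negative controls
#' are dominated by the contaminant taxa, each of which is planted
#' deterministically in every control and appears in true samples only at
#' trace probability. A random bifurcating tree with positive branch
#' lengths covers all taxa.
#'
#' @param scenario A [community_scenario()].
#' @param metadata Tibble from [simulate_metadata()] (one sample per row);
#'   body condition is taken from an `smi_g` column if present, otherwise
#'   computed internally per sex.
#' @return A list: `counts` (wide tibble: `sample_id`, `is_control`, one
#'   column per taxon), `taxonomy` (tibble `taxon_id`, `Kingdom` ...
#'   `Genus`), `tree` (`phylo`, `NULL` when fewer than 2 taxa),
#'   `sample_info` (depths, control/PCR flags) and `truth` (per-taxon
#'   differential flags and the planted slopes).
#' @export
simulate_community <- function(scenario, metadata) {
  stopifnot(inherits(scenario, "community_scenario"))
  sc <- scenario
  n_samples <- nrow(metadata)
  if (n_samples == 0) abort("metadata must contain at least one sample")
  set.seed(sc$seed)

  taxa <- sprintf("ASV_%03d", seq_len(sc$n_taxa))
  base <- sc$base_log_abundance %||% rnorm(sc$n_taxa, 0, 1.5)
  if (length(base) != sc$n_taxa) {
    abort("base_log_abundance must have length n_taxa")
  }

  rich <- sc$n_taxa >= 20
  sex_taxa <- sc$sex_effect_taxa %||% (if (rich) taxa[1:8] else character())
  cond_taxon <- sc$condition_taxon %||% (if (rich) taxa[10] else NULL)
  bad <- setdiff(c(sex_taxa, cond_taxon), taxa)
  if (length(bad)) {
    abort(paste0("effect taxa not in taxon set: ", paste(bad, collapse = ", ")))
  }

  contam_taxa <- if (sc$n_contaminants > 0) {
    sprintf("CONTAM_%02d", seq_len(sc$n_contaminants))
  } else character()
  off_taxa <- if (sc$n_offtarget > 0) {
    sprintf("OFFTARGET_%02d", seq_len(sc$n_offtarget))
  } else character()
  all_taxa <- c(taxa, contam_taxa, off_taxa)

  # trace-level baseline keeps contaminants nearly absent from true samples;
  # off-target taxa are ordinary community members taxonomically out of scope
  eta0 <- c(base, rep(-8, length(contam_taxa)),
            rnorm(length(off_taxa), -1.5, 0.3))

  # covariates
  male <- as.numeric(metadata$sex == "male")
  date_c <- if ("capture_julian" %in% names(metadata) && n_samples > 1) {
    metadata$capture_julian - mean(metadata$capture_julian)
  } else rep(0, n_samples)
  cond <- community_condition(metadata)

  pcr_failed <- rep(FALSE, n_samples)
  if (sc$n_pcr_failed > 0) {
    pcr_failed[sample(n_samples, min(sc$n_pcr_failed, n_samples))] <- TRUE
  }
  depths <- sample_depths(sc, n_samples, exclude_low = pcr_failed)
  counts <- matrix(0L, n_samples, length(all_taxa),
                   dimnames = list(metadata$id, all_taxa))
  for (j in seq_len(n_samples)) {
    eta <- eta0
    eta[match(sex_taxa, all_taxa)] <- eta[match(sex_taxa, all_taxa)] +
      sc$sex_lfc * male[j]
    if (!is.null(cond_taxon)) {
      i <- match(cond_taxon, all_taxa)
      eta[i] <- eta[i] + sc$condition_taxon_slope * cond[j]
    }
    spread <- exp(-sc$date_evenness_slope * date_c[j])
    eta <- spread * (eta - mean(eta))
    counts[j, ] <- draw_dirichlet_multinomial(eta, sc$dispersion, depths[j])
  }

  # negative controls: contaminant-dominated, contaminants planted in all
  control_ids <- character(0)
  control_counts <- NULL
  if (sc$n_controls > 0) {
    control_ids <- sprintf("control_%02d", seq_len(sc$n_controls))
    eta_ctrl <- rep(-6, length(all_taxa))
    eta_ctrl[match(contam_taxa, all_taxa)] <- runif(length(contam_taxa), 1, 2)
    control_counts <- matrix(0L, sc$n_controls, length(all_taxa),
                             dimnames = list(control_ids, all_taxa))
    plant <- 5L
    for (j in seq_len(sc$n_controls)) {
      depth <- round(runif(1, 2000, 6000))
      drawn <- draw_dirichlet_multinomial(eta_ctrl, sc$dispersion,
                                          depth - plant * length(contam_taxa))
      drawn[match(contam_taxa, all_taxa)] <-
        drawn[match(contam_taxa, all_taxa)] + plant
      control_counts[j, ] <- drawn
    }
  }

  all_counts <- rbind(counts, control_counts)
  counts_tbl <- tibble::as_tibble(all_counts, rownames = "sample_id") |>
    dplyr::mutate(is_control = .data$sample_id %in% control_ids,
                  .after = "sample_id")

  sample_info <- tibble::tibble(
    sample_id = rownames(all_counts),
    is_control = rownames(all_counts) %in% control_ids,
    pcr_failed = c(pcr_failed, rep(FALSE, length(control_ids))),
    depth = unname(rowSums(all_counts))
  )

  taxonomy <- simulate_taxonomy(taxa, contam_taxa, off_taxa, cond_taxon)
  tree <- if (length(all_taxa) >= 2) {
    tr <- ape::rtree(length(all_taxa), tip.label = sample(all_taxa))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    tr
  } else NULL

  truth <- list(
    taxa = tibble::tibble(
      taxon_id = all_taxa,
      sex_effect = all_taxa %in% sex_taxa,
      condition_taxon = !is.null(cond_taxon) & all_taxa %in% cond_taxon,
      contaminant = all_taxa %in% contam_taxa,
      offtarget = all_taxa %in% off_taxa
    ),
    sex_lfc = sc$sex_lfc,
    date_evenness_slope = sc$date_evenness_slope,
    condition_taxon_slope = sc$condition_taxon_slope,
    condition = cond
  )
  list(counts = counts_tbl, taxonomy = taxonomy, tree = tree,
       sample_info = sample_info, truth = truth)
}

community_condition <- function(metadata) {
  if (nrow(metadata) < 2) return(rep(0, nrow(metadata)))
  md <- metadata
  if (!"smi_g" %in% names(md)) {
    ok <- all(c("sex", "mass_g", "wing_mm") %in% names(md)) &&
      all(table(md$sex) >= 3)
    if (!ok) return(rep(0, nrow(md)))
    md <- add_condition(md)
  }
  stat <- md |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(cond = as.numeric(scale(.data$smi_g))) |>
    dplyr::ungroup()
  cond <- stat$cond[match(metadata$id, stat$id)]
  ifelse(is.na(cond), 0, cond)
}

# the sub-floor depths are planted among samples that pass amplification,
# so the depth filter and the PCR exclusion remove disjoint samples
sample_depths <- function(sc, n, exclude_low = rep(FALSE, n)) {
  depths <- round(runif(n, sc$depth_range[1], sc$depth_range[2]))
  ok <- which(!exclude_low)
  n_low <- min(sc$n_low_depth, length(ok))
  if (n_low > 0) {
    depths[ok[sample.int(length(ok), n_low)]] <- round(runif(n_low, 6825, 9999))
  }
  depths
}

draw_dirichlet_multinomial <- function(eta, dispersion, depth) {
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  w <- rgamma(length(p), shape = dispersion * p, rate = 1)
  if (sum(w) == 0) w[which.max(p)] <- 1
  as.integer(rmultinom(1, max(depth, 1), w / sum(w)))
}

simulate_taxonomy <- function(taxa, contam_taxa, off_taxa, cond_taxon) {
  phyla <- c("Firmicutes", "Actinobacteriota", "Proteobacteria",
             "Bacteroidota", "Fusobacteriota", "Synergistota")
  p_phy <- c(0.42, 0.35, 0.11, 0.06, 0.04, 0.02)
  phy <- sample(phyla, length(taxa), replace = TRUE, prob = p_phy)
  genus <- paste0("Genus_", sprintf("%03d", ceiling(seq_along(taxa) / 3)))
  tax <- tibble::tibble(
    taxon_id = taxa, Kingdom = "Bacteria", Phylum = phy,
    Class = paste0(phy, "_class"), Order = paste0(phy, "_order"),
    Family = paste0(phy, "_family"), Genus = genus
  )
  if (!is.null(cond_taxon)) {
    i <- match(cond_taxon, tax$taxon_id)
    tax$Phylum[i] <- "Proteobacteria"
    tax$Class[i] <- "Gammaproteobacteria"
    tax$Order[i] <- "Enterobacterales"
    tax$Family[i] <- "Enterobacteriaceae"
    tax$Genus[i] <- "Escherichia-Shigella"
  }
  if (length(contam_taxa)) {
    lab_genera <- c("Ralstonia", "Sphingomonas", "Methylobacterium",
                    "Bradyrhizobium", "Pseudomonas", "Acinetobacter")
    tax <- dplyr::bind_rows(tax, tibble::tibble(
      taxon_id = contam_taxa, Kingdom = "Bacteria", Phylum = "Proteobacteria",
      Class = "Proteobacteria_class", Order = "Proteobacteria_order",
      Family = "Proteobacteria_family",
      Genus = rep_len(lab_genera, length(contam_taxa))
    ))
  }
  if (length(off_taxa)) {
    templates <- list(
      list(Kingdom = "Eukaryota", Phylum = "Ochrophyta", Class = "Diatomea",
           Order = "Bacillariales", Family = "Bacillariaceae",
           Genus = "Nitzschia"),
      list(Kingdom = "Bacteria", Phylum = "Cyanobacteria",
           Class = "Cyanobacteriia", Order = "Chloroplast",
           Family = "Chloroplast_family", Genus = NA_character_),
      list(Kingdom = "Bacteria", Phylum = "Proteobacteria",
           Class = "Alphaproteobacteria", Order = "Rickettsiales",
           Family = "Mitochondria", Genus = NA_character_),
      list(Kingdom = "Bacteria", Phylum = NA_character_,
           Class = NA_character_, Order = NA_character_,
           Family = NA_character_, Genus = NA_character_)
    )
    extra <- purrr::map2(off_taxa, rep_len(templates, length(off_taxa)),
                         function(id, tmp) {
                           tibble::as_tibble(c(list(taxon_id = id), tmp))
                         }) |>
      dplyr::bind_rows()
    tax <- dplyr::bind_rows(tax, extra)
  }
  tax
}

`%||%` <- function(a, b) if (is.null(a)) b else a
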