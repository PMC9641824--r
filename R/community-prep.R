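#' Flag laboratory contaminants by prevalence in negative controls
#'
#' Prevalence-based contaminant identification: for each taxon a 2x2
#' presence/absence table (controls vs true samples) is scored with a
#' chi-square test, falling back to Fisher's exact test whenever any
#' expected cell is below 5. The score is directional — only taxa whose
#' presence fraction is higher in controls than in true samples can be
#' flagged — and a taxon is called a contaminant when its score falls below
#' `threshold` (default 0.5).
#'
#' @param counts Wide count tibble (`sample_id`, `is_control`, one numeric
#'   column per taxon).
#' @param threshold Score threshold in (0, 1).
#' @return A tibble with one row per taxon: presence counts in each sample
#'   class, the directional `score` and the `contaminant` flag.
#' @export
flag_contaminants <- function(counts, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  mat <- counts_matrix(counts)
  ctrl <- counts$is_control
  if (!any(ctrl) || !any(!ctrl)) {
    abort("need at least one control and one true sample")
  }
  pres <- mat > 0
  n_ctrl <- sum(ctrl)
  n_true <- sum(!ctrl)
  in_ctrl <- colSums(pres[ctrl, , drop = FALSE])
  in_true <- colSums(pres[!ctrl, , drop = FALSE])

  score <- purrr::map2_dbl(in_ctrl, in_true, function(a, b) {
    if (a + b == 0) return(NA_real_)
    if (a / n_ctrl <= b / n_true) return(1)  # not control-enriched
    tab <- matrix(c(a, n_ctrl - a, b, n_true - b), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      fisher.test(tab, alternative = "greater")$p.value
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
  })
  if (any(is.na(score))) {
    warn("taxa absent from every sample were left unflagged")
  }
  tibble::tibble(
    taxon_id = colnames(mat),
    prevalence_control = unname(in_ctrl) / n_ctrl,
    prevalence_sample = unname(in_true) / n_true,
    score = unname(score),
    contaminant = !is.na(score) & score < threshold
  )
}

#' Remove off-target taxa by taxonomy
#'
#' Drops taxa not assigned to the kingdom Bacteria, identified as
#' mitochondria (family) or chloroplasts (order), or unresolved at the
#' phylum level.
#'
#' @param counts Wide count tibble.
#' @param taxonomy Tibble with `taxon_id` and the ranks `Kingdom` ...
#'   `Genus`; must cover every taxon in `counts`.
#' @return The filtered count tibble, with a `removal_log` attribute (tibble
#'   of rule names and counts removed).
#' @export
taxon_filter <- function(counts, taxonomy) {
  taxa <- taxon_cols(counts)
  missing_tax <- setdiff(taxa, taxonomy$taxon_id)
  if (length(missing_tax)) {
    abort(paste0("taxonomy does not cover: ", paste(head(missing_tax, 5), collapse = ", ")))
  }
  tax <- taxonomy[match(taxa, taxonomy$taxon_id), ]
  rules <- list(
    not_bacteria = is.na(tax$Kingdom) | tax$Kingdom != "Bacteria",
    mitochondria = !is.na(tax$Family) & tax$Family == "Mitochondria",
    chloroplast = !is.na(tax$Order) & tax$Order == "Chloroplast",
    unresolved_phylum = is.na(tax$Phylum) | tax$Phylum == ""
  )
  drop <- Reduce(`|`, rules)
  log <- tibble::tibble(
    rule = names(rules),
    n_removed = unname(vapply(rules, sum, integer(1)))
  )
  out <- dplyr::select(counts, -dplyr::all_of(taxa[drop]))
  attr(out, "removal_log") <- log
  out
}

#' Drop samples below a minimum read depth
#'
#' Samples whose total read count is below `min_depth` are removed;
#' samples exactly at the floor are retained.
#'
#' @param counts Wide count tibble.
#' @param min_depth Retention floor in reads.
#' @return The filtered tibble, with a `dropped_samples` attribute.
#' @export
depth_filter <- function(counts, min_depth = 10000) {
  depths <- rowSums(counts_matrix(counts))
  keep <- depths >= min_depth
  if (!any(keep)) abort("no sample reaches the minimum read depth")
  out <- counts[keep, ]
  attr(out, "dropped_samples") <- counts$sample_id[!keep]
  out
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (hypergeometric subsampling), then removes taxa left with zero total.
#' Deterministic for a fixed seed.
#'
#' @param counts Wide count tibble; every sample must have at least `depth`
#'   reads.
#' @param depth Target depth; defaults to the table's minimum sample depth.
#' @param seed RNG seed (the conventional analysis uses 999).
#' @return The rarefied count tibble.
#' @export
rarefy <- function(counts, depth = NULL, seed = 999) {
  mat <- counts_matrix(counts)
  depths <- rowSums(mat)
  depth <- depth %||% min(depths)
  if (any(depths < depth)) {
    abort("every sample must have at least `depth` reads before rarefying")
  }
  set.seed(seed)
  rare <- t(apply(mat, 1, function(x) {
    if (sum(x) == depth) return(x)
    reads <- rep.int(seq_along(x), x)
    kept <- sample(reads, depth)
    tabulate(kept, nbins = length(x))
  }))
  colnames(rare) <- colnames(mat)
  keep_taxa <- colSums(rare) > 0
  out <- dplyr::bind_cols(
    counts[setdiff(names(counts), colnames(mat))],
    tibble::as_tibble(rare[, keep_taxa, drop = FALSE])
  )
  out
}

#' Run the full pre-processing ladder
#'
#' Contaminant flagging and removal (using the negative controls, which are
#' then discarded), taxonomy-based off-target removal, read-depth
#' filtering, and rarefaction — in that order.
#'
#' @param counts Wide count tibble including control samples.
#' @param taxonomy Taxonomy tibble covering the counts.
#' @param decontam_threshold Contaminant score threshold.
#' @param min_depth Read-depth retention floor.
#' @param rarefy_depth Rarefaction target; `NULL` uses the post-filter
#'   minimum depth.
#' @param seed Rarefaction seed.
#' @return The prepared count tibble with attributes `contaminants` (the
#'   flag table), `removal_log`, `dropped_samples` and `rarefied_depth`.
#' @export
prep_community <- function(counts, taxonomy,
                           decontam_threshold = 0.5,
                           min_depth = 10000,
                           rarefy_depth = NULL,
                           seed = 999) {
  flags <- flag_contaminants(counts, decontam_threshold)
  contam <- flags$taxon_id[flags$contaminant]
  out <- counts |>
    dplyr::filter(!.data$is_control) |>
    dplyr::select(-dplyr::all_of(contam))
  out <- taxon_filter(out, taxonomy)
  removal_log <- attr(out, "removal_log")
  out <- depth_filter(out, min_depth)
  dropped <- attr(out, "dropped_samples")
  target <- rarefy_depth %||% min(rowSums(counts_matrix(out)))
  out <- rarefy(out, depth = target, seed = seed)
  attr(out, "contaminants") <- flags
  attr(out, "removal_log") <- removal_log
  attr(out, "dropped_samples") <- dropped
  attr(out, "rarefied_depth") <- target
  out
}

# ---- wide-table helpers ---------------------------------------------------

# columns of `counts` that hold per-taxon counts
taxon_cols <- function(counts) {
  setdiff(names(counts), c("sample_id", "is_control"))
}

# samples x taxa integer matrix from the wide tibble
counts_matrix <- function(counts) {
  taxa <- taxon_cols(counts)
  if (!"sample_id" %in% names(counts)) abort("counts need a sample_id column")
  mat <- as.matrix(counts[taxa])
  if (!is.numeric(mat)) abort("taxon columns must be numeric")
  if (any(mat < 0)) abort("counts must be nonnegative")
  rownames(mat) <- counts$sample_id
  mat
}
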