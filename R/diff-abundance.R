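#' Aggregate an ASV table to a taxonomic rank
#'
#' Sums counts within each phylum or genus; taxa unresolved at the rank are
#' dropped (and logged in the `dropped_taxa` attribute). A table whose
#' taxon columns already equal the rank labels passes through unchanged.
#'
#' @param counts Wide count tibble.
#' @param taxonomy Taxonomy tibble covering the counts.
#' @param rank `"Phylum"` or `"Genus"`.
#' @return Aggregated wide tibble (one column per rank value).
#' @export
aggregate_rank <- function(counts, taxonomy, rank = c("Genus", "Phylum")) {
  rank <- match.arg(rank)
  if (!rank %in% names(taxonomy)) abort(paste0("taxonomy lacks a ", rank, " column"))
  taxa <- taxon_cols(counts)
  if (all(taxa %in% taxonomy[[rank]])) return(counts)  # already aggregated
  lab <- taxonomy[[rank]][match(taxa, taxonomy$taxon_id)]
  resolved <- !is.na(lab) & lab != ""
  mat <- counts_matrix(counts)[, resolved, drop = FALSE]
  agg <- t(rowsum(t(mat), lab[resolved]))
  out <- dplyr::bind_cols(
    counts[intersect(c("sample_id", "is_control"), names(counts))],
    tibble::as_tibble(agg)
  )
  attr(out, "dropped_taxa") <- taxa[!resolved]
  out
}

#' Differential-abundance configuration
#'
#' @param prevalence_min Minimum fraction of samples a taxon must appear in
#'   to be tested (strictly greater than).
#' @param q_threshold BH-adjusted p-value ceiling for selection.
#' @param w_percentile Quantile of `|W|` a taxon must exceed for selection,
#'   computed within the tested taxon set.
#' @param pseudocount Added to counts before logging.
#' @param max_iter,tol Offset-iteration controls.
#' @return List of class `da_config`.
#' @export
da_config <- function(prevalence_min = 0.10, q_threshold = 0.01,
                      w_percentile = 0.85, pseudocount = 1,
                      max_iter = 100, tol = 1e-6) {
  if (prevalence_min <= 0 || prevalence_min >= 1 ||
      q_threshold <= 0 || q_threshold >= 1 ||
      w_percentile <= 0 || w_percentile >= 1) {
    abort("thresholds must lie in (0, 1)")
  }
  structure(list(prevalence_min = prevalence_min, q_threshold = q_threshold,
                 w_percentile = w_percentile, pseudocount = pseudocount,
                 max_iter = max_iter, tol = tol), class = "da_config")
}

#' Bias-corrected differential-abundance test
#'
#' Models `log(count + pseudocount)` as a per-sample offset (the unknown
#' sampling fraction) plus a taxon intercept and a taxon-specific
#' coefficient on the covariate. Offsets and coefficients are estimated by
#' alternating (i) per-taxon least squares given the offsets and (ii) an
#' offset update equal to each sample's median residual across taxa, until
#' the largest offset change falls below `tol`; offsets are pinned to mean
#' zero. `W = coefficient / se`, p-values from the standard normal, q by
#' Benjamini-Hochberg. A taxon is *selected* when `q < q_threshold` and
#' `|W|` exceeds the `w_percentile` quantile of `|W|` over the tested taxa.
#'
#' @param counts Wide count tibble (taxa filtered to the analysis rank).
#' @param covariate Numeric vector or two-level factor/character, one value
#'   per sample (positive coefficients mean higher abundance at higher
#'   covariate values / in the second factor level).
#' @param config A [da_config()].
#' @return Object of class `da_fit`; `tidy()` gives per-taxon `lfc`, `se`,
#'   `W`, `p_value`, `q_value`, `selected`.
#' @export
ancombc_fit <- function(counts, covariate, config = da_config()) {
  mat <- counts_matrix(counts)
  n <- nrow(mat)
  if (n < 8) abort("need at least 8 samples")
  if (length(covariate) != n) abort("one covariate value per sample required")
  x <- encode_covariate(covariate)
  if (sd(x) == 0) abort("constant covariate: W undefined for every taxon")

  keep <- colMeans(mat > 0) > config$prevalence_min
  if (!any(keep)) abort("no taxon passes the prevalence filter")
  Y <- log(mat[, keep, drop = FALSE] + config$pseudocount)
  taxa <- colnames(Y)
  X <- cbind(1, x)

  d <- rep(0, n)
  XtXinv <- solve(crossprod(X))
  proj <- XtXinv %*% t(X)
  delta <- Inf
  damp <- 1
  for (it in seq_len(config$max_iter)) {
    B <- proj %*% (Y - d)          # 2 x p coefficients
    R <- Y - X %*% B               # residuals incl. offsets
    target <- apply(R, 1, median)
    target <- target - mean(target)
    # the raw median update can cycle between tie configurations; damp the
    # step whenever the offset change stops shrinking
    d_new <- d + damp * (target - d)
    delta_new <- max(abs(d_new - d))
    if (is.finite(delta) && delta_new >= delta) damp <- damp / 2
    delta <- delta_new
    d <- d_new
    if (delta < config$tol) break
  }
  if (delta >= config$tol) {
    abort(sprintf("offset iteration did not converge (last delta %.3g)", delta))
  }

  Ystar <- Y - d
  B <- proj %*% Ystar
  resid <- Ystar - X %*% B
  sigma2 <- colSums(resid^2) / (n - 2)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  lfc <- B[2, ]
  W <- lfc / se
  p <- 2 * pnorm(-abs(W))
  q <- bh_adjust(p)
  w_cut <- quantile(abs(W), config$w_percentile, names = FALSE)
  res <- tibble::tibble(
    taxon = taxa,
    lfc = unname(lfc), se = unname(se), W = unname(W),
    p_value = unname(p), q_value = unname(q),
    selected = q < config$q_threshold & abs(W) > w_cut
  )
  structure(list(results = res, offsets = d, config = config,
                 w_cut = w_cut, n_iter = it, covariate = covariate),
            class = "da_fit")
}

encode_covariate <- function(covariate) {
  if (is.numeric(covariate)) return(covariate)
  f <- as.factor(covariate)
  if (nlevels(droplevels(f)) != 2) {
    abort("categorical covariates must have exactly two levels")
  }
  as.numeric(f == levels(f)[2])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
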