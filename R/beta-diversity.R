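#' Beta-diversity distance matrices
#'
#' Pairwise community dissimilarities on a (rarefied) count table:
#'
#' * **bray** — Bray-Curtis, `sum |x - y| / sum (x + y)`;
#' * **jaccard** — by default on presence/absence,
#'   `1 - |A n B| / |A u B|`; set `binary = FALSE` for the quantitative
#'   (Ruzicka) variant;
#' * **unifrac** — unweighted UniFrac: branch length unique to one sample
#'   over the branch length covered by either;
#' * **wunifrac** — weighted UniFrac, non-normalized:
#'   `sum_e b_e |p_e - q_e|` with `p_e` the relative abundance of taxa below
#'   edge `e`.
#'
#' @param counts Wide count tibble.
#' @param metric One of `"bray"`, `"jaccard"`, `"unifrac"`, `"wunifrac"`.
#' @param tree Rooted `phylo` covering the taxa (UniFrac metrics only; tips
#'   absent from the table are ignored).
#' @param binary Use presence/absence for Jaccard.
#' @return A `dist` object with attribute `metric`.
#' @export
beta_diversity <- function(counts, metric = c("bray", "jaccard", "unifrac", "wunifrac"),
                           tree = NULL, binary = TRUE) {
  metric <- match.arg(metric)
  mat <- counts_matrix(counts)
  n <- nrow(mat)
  if (metric %in% c("unifrac", "wunifrac")) {
    if (is.null(tree)) abort("UniFrac metrics require a phylogeny")
    missing_tips <- setdiff(colnames(mat), tree$tip.label)
    if (length(missing_tips)) {
      abort(paste0("tree lacks tips: ", paste(head(missing_tips, 5), collapse = ", ")))
    }
    # taxa on the tree but absent from the table contribute nothing
    inc <- edge_tip_incidence(tree)[, colnames(mat), drop = FALSE]
    blen <- tree$edge.length
    if (metric == "unifrac") {
      covered <- (inc %*% t(mat > 0)) > 0             # edges x samples
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          either <- covered[, i] | covered[, j]
          shared <- covered[, i] & covered[, j]
          tot <- sum(blen[either])
          d[i, j] <- d[j, i] <- if (tot > 0) sum(blen[either & !shared]) / tot else 0
        }
      }
    } else {
      rel <- mat / rowSums(mat)
      p_edge <- inc %*% t(rel)                         # edges x samples
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d[i, j] <- d[j, i] <- sum(blen * abs(p_edge[, i] - p_edge[, j]))
        }
      }
    }
  } else if (metric == "bray") {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(abs(mat[i, ] - mat[j, ])) /
          sum(mat[i, ] + mat[j, ])
      }
    }
  } else {
    x <- if (binary) (mat > 0) * 1 else mat
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (binary) {
          inter <- sum(x[i, ] > 0 & x[j, ] > 0)
          uni <- sum(x[i, ] > 0 | x[j, ] > 0)
          d[i, j] <- d[j, i] <- if (uni > 0) 1 - inter / uni else 0
        } else {
          d[i, j] <- d[j, i] <- 1 - sum(pmin(x[i, ], x[j, ])) /
            sum(pmax(x[i, ], x[j, ]))
        }
      }
    }
  }
  rownames(d) <- colnames(d) <- rownames(mat)
  out <- stats::as.dist(d)
  attr(out, "metric") <- metric
  out
}

#' Principal-coordinate ordination (classical MDS)
#'
#' Eigendecomposition of the Gower double-centred matrix of squared
#' distances; coordinates are ordered by eigenvalue. Negative eigenvalues
#' (from non-Euclidean dissimilarities) are reported as-is.
#'
#' @param dist A `dist` object.
#' @param k Number of dimensions to return.
#' @return An object of class `pcoa_ord`: list with `points` (tibble:
#'   `sample_id`, `axis1` ... `axisk`), `eigenvalues` and the proportion of
#'   (positive) variance explained.
#' @export
pcoa_ordination <- function(dist, k = 2) {
  G <- gower_center(dist)
  e <- eigen(G, symmetric = TRUE)
  pos <- sum(e$values > 1e-8)
  if (k > pos) {
    warn(sprintf("only %d positive axes available; k truncated", pos))
    k <- pos
  }
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k, k)
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(
    points = dplyr::bind_cols(
      tibble::tibble(sample_id = attr(dist, "Labels") %||%
                       as.character(seq_len(attr(dist, "Size")))),
      tibble::as_tibble(pts)
    ),
    eigenvalues = e$values,
    prop_explained = e$values[seq_len(k)] / sum(pmax(e$values, 0))
  ), class = "pcoa_ord")
}

# Gower-centred inner-product matrix from a dist
gower_center <- function(dist) {
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}
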