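#' Alpha-diversity indices
#'
#' Computes per-sample Shannon diversity (natural log), bias-corrected
#' Chao1 richness `S_obs + F1(F1-1) / (2(F2+1))`, and Faith's phylogenetic
#' diversity (total branch length of the subtree spanning the observed taxa
#' and the root).
#'
#' @param counts Wide count tibble (`sample_id` plus taxon columns).
#' @param tree Rooted `phylo` whose tips include every taxon in `counts`;
#'   required for Faith's PD.
#' @param metrics Any of `"shannon"`, `"chao1"`, `"faith_pd"`.
#' @return Tibble with `sample_id` and one column per metric.
#' @export
alpha_diversity <- function(counts, tree = NULL,
                            metrics = c("shannon", "chao1", "faith_pd")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  mat <- counts_matrix(counts)
  if (any(rowSums(mat) == 0)) abort("all-zero samples have undefined diversity")
  out <- tibble::tibble(sample_id = rownames(mat))
  if ("shannon" %in% metrics) {
    out$shannon <- unname(apply(mat, 1, shannon_index))
  }
  if ("chao1" %in% metrics) {
    out$chao1 <- unname(apply(mat, 1, chao1_index))
  }
  if ("faith_pd" %in% metrics) {
    if (is.null(tree)) abort("Faith's PD requires a phylogeny")
    out$faith_pd <- faith_pd(mat, tree)
  }
  out
}

#' @rdname alpha_diversity
#' @param x Nonnegative count vector for one sample.
#' @export
shannon_index <- function(x) {
  if (all(x == 0)) abort("all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' @rdname alpha_diversity
#' @export
chao1_index <- function(x) {
  if (all(x == 0)) abort("all-zero sample")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Faith's phylogenetic diversity
#'
#' @param mat Samples x taxa matrix (or a single named count vector).
#' @param tree Rooted `phylo` covering the taxa.
#' @return Numeric vector of PD values (one per sample/row).
#' @export
faith_pd <- function(mat, tree) {
  if (is.null(dim(mat))) mat <- matrix(mat, 1, dimnames = list("s", names(mat)))
  missing_tips <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing_tips)) {
    abort(paste0("tree lacks tips: ", paste(head(missing_tips, 5), collapse = ", ")))
  }
  inc <- edge_tip_incidence(tree)                    # edges x tips
  # tips x samples presence; tree tips absent from the table stay absent
  pres <- matrix(0, length(tree$tip.label), nrow(mat),
                 dimnames = list(tree$tip.label, rownames(mat)))
  pres[colnames(mat), ] <- t(mat > 0)
  covered <- (inc %*% pres) > 0                      # edges x samples
  as.numeric(t(covered) %*% tree$edge.length)
}

# logical edges x tips matrix: does tip t descend from edge e
edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  inc <- matrix(FALSE, nrow(tree$edge), n_tip,
                dimnames = list(NULL, tree$tip.label))
  # postorder: fill each edge with the tips below its child node
  tip_sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) tip_sets[[i]] <- i
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    if (child > n_tip) {
      kids <- children[[as.character(child)]]
      tip_sets[[child]] <- unlist(lapply(tree$edge[kids, 2],
                                         function(k) tip_sets[[k]]))
    }
    inc[e, tip_sets[[child]]] <- TRUE
  }
  inc
}

#' Normalizing transforms for alpha-diversity values
#'
#' Applies the transform conventionally used to bring each index close to
#' normality before linear modelling: `log10` for Shannon, the reciprocal
#' for Faith's PD, identity for Chao1.
#'
#' @param values Positive numeric vector.
#' @param metric One of `"shannon"`, `"faith_pd"`, `"chao1"`.
#' @return Transformed values, with attribute `transformed = TRUE`.
#' @export
transform_alpha <- function(values, metric = c("shannon", "faith_pd", "chao1")) {
  metric <- match.arg(metric)
  if (metric %in% c("shannon", "faith_pd") && any(values <= 0)) {
    abort("nonpositive values cannot be log/inverse transformed")
  }
  out <- switch(metric,
    shannon = log10(values),
    faith_pd = 1 / values,
    chao1 = values
  )
  attr(out, "transformed") <- TRUE
  out
}
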