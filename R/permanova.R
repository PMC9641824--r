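#' Permutational multivariate analysis of variance
#'
#' Partitions a dissimilarity matrix by the terms of a model formula using
#' the Gower-centred inner-product matrix: for each term the pseudo-F
#' compares the explained sum of squares (marginal mode: full model minus
#' the model with that term dropped; sequential mode: terms added in order)
#' to the full-model residual. Significance comes from permuting sample
#' labels, with the unbiased estimator `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param dist A `dist` object over the samples.
#' @param data Data frame of covariates, rows aligned with the samples of
#'   `dist`.
#' @param formula Right-hand-side formula of terms, e.g. `~ sex + age`.
#' @param n_perm Number of permutations (9999 by convention).
#' @param by `"margin"` (marginal effects) or `"terms"` (sequential).
#' @param seed Optional RNG seed for the permutations.
#' @param permutations Optional integer matrix of row indices (one
#'   permutation per row) overriding random permutation generation — e.g.
#'   an exhaustive enumeration for small designs.
#' @return Object of class `permanova_fit`; `tidy()` gives one row per term
#'   (`df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`) plus residual and
#'   total rows.
#' @export
permanova <- function(dist, data, formula, n_perm = 9999,
                      by = c("margin", "terms"), seed = NULL,
                      permutations = NULL) {
  by <- match.arg(by)
  n <- attr(dist, "Size")
  if (nrow(data) != n) abort("design rows must match the distance matrix")
  if (!is.null(seed)) set.seed(seed)

  mf <- model.frame(formula, data, na.action = stats::na.fail)
  trm <- attr(mf, "terms")
  term_labels <- attr(trm, "term.labels")
  if (length(term_labels) == 0) abort("formula has no terms")
  X <- model.matrix(trm, mf)
  assign <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    bad_terms <- unique(term_labels[assign[match(aliased, colnames(X))]])
    abort(paste0("confounded (aliased) term(s): ", paste(bad_terms, collapse = ", ")))
  }

  G <- gower_center(dist)
  ss_total <- sum(diag(G))
  hat_full <- hat_matrix(X)
  df_res <- n - qrX$rank
  # reduced-model hats, one per term
  hats_red <- purrr::map(seq_along(term_labels), function(t) {
    keep <- assign == 0 | assign != t
    if (by == "terms") keep <- assign == 0 | assign < t
    hat_matrix(X[, keep, drop = FALSE])
  })
  hats_upto <- purrr::map(seq_along(term_labels), function(t) {
    hat_matrix(X[, assign == 0 | assign <= t, drop = FALSE])
  })

  df_terms <- purrr::map_int(seq_along(term_labels), function(t) {
    as.integer(sum(assign == t))
  })
  # traces as inner products with vectorized hat matrices; the trace of the
  # permuted G equals tr(G), so only the model traces need recomputing
  v_full <- as.vector(hat_full)
  v_red <- purrr::map(hats_red, as.vector)
  v_upto <- purrr::map(hats_upto, as.vector)
  n_terms <- length(term_labels)
  f_from_traces <- function(tr_full, tr_red, tr_upto) {
    ss_res <- ss_total - tr_full
    ss_terms <- if (by == "margin") tr_full - tr_red else tr_upto - tr_red
    (ss_terms / df_terms) / (ss_res / df_res)
  }
  vg <- as.vector(G)
  obs_full <- sum(v_full * vg)
  obs_red <- purrr::map_dbl(v_red, function(v) sum(v * vg))
  obs_upto <- purrr::map_dbl(v_upto, function(v) sum(v * vg))
  f_obs <- f_from_traces(obs_full, obs_red, obs_upto)
  ss_obs <- if (by == "margin") obs_full - obs_red else obs_upto - obs_red

  if (is.null(permutations)) {
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_used <- nrow(permutations)
  exceed <- numeric(n_terms)
  chunk <- 256L
  for (start in seq(1, n_used, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_used)
    M <- vapply(idx, function(r) {
      p <- permutations[r, ]
      as.vector(G[p, p])
    }, numeric(n * n))
    tr_full <- as.numeric(crossprod(v_full, M))
    tr_red <- do.call(rbind, purrr::map(v_red, function(v) {
      as.numeric(crossprod(v, M))
    }))
    tr_upto <- do.call(rbind, purrr::map(v_upto, function(v) {
      as.numeric(crossprod(v, M))
    }))
    ss_res_p <- ss_total - tr_full
    ss_terms_p <- if (by == "margin") {
      sweep(-tr_red, 2, tr_full, `+`)
    } else {
      tr_upto - tr_red
    }
    f_perm <- (ss_terms_p / df_terms) / rep(ss_res_p / df_res,
                                            each = n_terms)
    tol <- 1e-8 * pmax(1, abs(f_obs))  # ties count as exceedances
    exceed <- exceed + rowSums(f_perm >= f_obs - tol)
  }
  p_val <- (1 + exceed) / (1 + n_used)
  obs <- list(ss = ss_obs, ss_res = ss_total - obs_full)

  res <- tibble::tibble(
    term = c(term_labels, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, ss_total),
    r_squared = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(f_obs, NA, NA),
    p_value = c(p_val, NA, NA)
  )
  structure(list(results = res, by = by, n_perm = n_used,
                 formula = formula),
            class = "permanova_fit")
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Homogeneity of multivariate dispersion
#'
#' A betadisper-style test: samples are embedded by principal coordinates
#' (keeping negative-eigenvalue axes as imaginary parts), each sample's
#' distance to its group's spatial median is computed with the
#' `d^2 = d_real^2 - d_imag^2` correction, and group differences in those
#' distances are tested with a one-way F whose p-value comes from
#' permuting group labels.
#'
#' @param dist A `dist` object.
#' @param groups Factor of group labels (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @return List of class `dispersion_test`: per-sample distances, per-group
#'   mean dispersions, the F statistic and permutation p-value.
#' @export
dispersion_test <- function(dist, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("need at least two groups")
  if (any(table(groups) < 2)) abort("every group needs at least two samples")
  if (!is.null(seed)) set.seed(seed)

  G <- gower_center(dist)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > 1e-8
  neg <- e$values < -1e-8
  real <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos), sum(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg), sum(neg))

  dist_to_median <- function(g) {
    d <- numeric(length(g))
    for (lev in levels(g)) {
      idx <- which(g == lev)
      mr <- spatial_median(real[idx, , drop = FALSE])
      d_r2 <- rowSums(sweep(real[idx, , drop = FALSE], 2, mr)^2)
      d_i2 <- 0
      if (ncol(imag) > 0) {
        mi <- spatial_median(imag[idx, , drop = FALSE])
        d_i2 <- rowSums(sweep(imag[idx, , drop = FALSE], 2, mi)^2)
      }
      d[idx] <- sqrt(pmax(d_r2 - d_i2, 0))
    }
    d
  }
  f_stat <- function(d, g) {
    fit <- stats::aov(d ~ g)
    s <- summary(fit)[[1]]
    s$`F value`[1]
  }

  d_obs <- dist_to_median(groups)
  f_obs <- f_stat(d_obs, groups)
  exceed <- 0
  for (r in seq_len(n_perm)) {
    gp <- sample(groups)
    fp <- f_stat(dist_to_median(gp), gp)
    if (!is.na(fp) && fp >= f_obs - 1e-12) exceed <- exceed + 1
  }
  structure(list(
    distances = tibble::tibble(
      sample_id = attr(dist, "Labels") %||% as.character(seq_along(groups)),
      group = groups, distance = d_obs
    ),
    group_dispersion = tibble::tibble(
      group = levels(groups),
      mean_distance = as.numeric(tapply(d_obs, groups, mean))
    ),
    f = f_obs,
    p_value = (1 + exceed) / (1 + n_perm),
    n_perm = n_perm
  ), class = "dispersion_test")
}

# geometric (spatial) median by Weiszfeld iteration
spatial_median <- function(X, tol = 1e-9, max_iter = 200) {
  if (nrow(X) == 1) return(X[1, ])
  m <- colMeans(X)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    if (any(d < 1e-12)) {
      d <- pmax(d, 1e-12)
    }
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}
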