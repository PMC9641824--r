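#' Fit and rank a set of linear models by AICc
#'
#' Ordinary least-squares fits of each candidate formula, ranked by
#' small-sample-corrected AIC computed from the closed form
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k` counting the
#' residual variance as a parameter (additive normal-likelihood constants
#' are dropped; differences and Akaike weights are unaffected). Numeric
#' covariates are centred and scaled before fitting. The best set holds
#' every model within 2 AICc units of the minimum.
#'
#' @param data Data frame holding response and covariates.
#' @param formulas Named list (or character vector) of model formulas, all
#'   sharing one response.
#' @param scale_numeric Centre and scale numeric covariates first.
#' @return Object of class `model_comparison`; `tidy()` gives one row per
#'   model (`model`, `k`, `aicc`, `delta_aicc`, `weight`, `in_best_set`),
#'   minimum delta 0, weights summing to 1.
#' @export
fit_model_set <- function(data, formulas, scale_numeric = TRUE) {
  if (is.character(formulas)) formulas <- lapply(formulas, stats::as.formula)
  if (is.null(names(formulas)) || any(names(formulas) == "")) {
    names(formulas) <- vapply(formulas, function(f) deparse1(f), character(1))
  }
  vars <- unique(unlist(lapply(formulas, all.vars)))
  data <- data[complete.cases(data[vars]), , drop = FALSE]
  response <- all.vars(formulas[[1]])[1]
  if (scale_numeric) {
    covs <- setdiff(vars, response)
    for (v in covs) {
      if (is.numeric(data[[v]])) data[[v]] <- as.numeric(scale(data[[v]]))
    }
  }
  n <- nrow(data)
  rows <- purrr::imap(formulas, function(f, label) {
    fit <- lm(f, data = data)
    k <- length(coef(fit)) + 1  # + residual variance
    if (n <= k + 1) {
      warn(sprintf("model '%s' dropped: AICc undefined for n = %d, k = %d",
                   label, n, k))
      return(NULL)
    }
    rss <- sum(stats::residuals(fit)^2)
    aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    tibble::tibble(model = label, k = k, aicc = aicc)
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) abort("no model could be fitted")
  res <- res |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc),
                  weight = exp(-.data$delta_aicc / 2) /
                    sum(exp(-.data$delta_aicc / 2)),
                  in_best_set = .data$delta_aicc < 2) |>
    dplyr::arrange(.data$delta_aicc)
  structure(list(results = res, n = n, formulas = formulas),
            class = "model_comparison")
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) form with Satterthwaite degrees of freedom —
#' the form implied whenever fractional df are reported. Two groups with
#' zero variance and equal means return `t = 0, p = 1` rather than an
#' error.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `effect`
#'   (`mean(x) - mean(y)`).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            effect = 0))
    }
    abort("both groups have zero variance but unequal means; t undefined")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, effect = mean(x) - mean(y))
}

#' Scheirer-Ray-Hare test
#'
#' Non-parametric two-way factorial test: the response is replaced by
#' midranks (ties handled automatically), a two-way ANOVA decomposition is
#' computed on the ranks, and each term's H statistic is the term sum of
#' squares divided by the total mean square of the ranks, referred to a
#' chi-square distribution on the term's df.
#'
#' @param response Numeric vector.
#' @param factor_a,factor_b Crossed factors (>= 2 levels each, no empty
#'   cell).
#' @return Tibble with one row per term (`A`, `B`, `A:B`): `df`, `H`,
#'   `p_value`.
#' @export
scheirer_ray_hare <- function(response, factor_a, factor_b) {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  if (any(table(a, b) == 0)) abort("empty cell in the two-way design")
  r <- rank(response)
  ms_total <- sum((r - mean(r))^2) / (length(r) - 1)
  if (ms_total == 0) {
    return(tibble::tibble(term = c("A", "B", "A:B"),
                          df = c(nlevels(a) - 1, nlevels(b) - 1,
                                 (nlevels(a) - 1) * (nlevels(b) - 1)),
                          H = 0, p_value = 1))
  }
  # factors collapsed to one level drop out (Kruskal-Wallis limit)
  fit <- if (nlevels(a) > 1 && nlevels(b) > 1) {
    lm(r ~ a * b)
  } else if (nlevels(a) > 1) {
    lm(r ~ a)
  } else if (nlevels(b) > 1) {
    lm(r ~ b)
  } else {
    abort("both factors have a single level")
  }
  tab <- anova(fit)
  term_names <- rownames(tab)
  pick <- function(nm) if (nm %in% term_names) tab[nm, ] else NULL
  rows <- list(A = pick("a"), B = pick("b"), `A:B` = pick("a:b"))
  out <- purrr::imap(rows, function(row, nm) {
    if (is.null(row)) return(NULL)
    h <- row$`Sum Sq` / ms_total
    tibble::tibble(term = nm, df = row$Df, H = h,
                   p_value = pchisq(h, row$Df, lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 nonnegative count matrix with positive margins.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) abort("expected a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: chi-square undefined")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Pearson correlation test
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return One-row tibble: `estimate` (r), `statistic` (t on n-2 df), `df`,
#'   `p_value`.
#' @export
pearson_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) abort("need at least 3 complete pairs")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Adjust a family of test results for multiple comparisons
#'
#' Benjamini-Hochberg adjustment across the declared family; the family
#' label is recorded in the output so reported adjusted p-values are
#' traceable to their family definition.
#'
#' @param tests Tibble with a `p_value` column (one test per row).
#' @param method Adjustment method (default `"BH"`).
#' @param family Family label recorded in the output.
#' @return `tests` with `p_adj` and `family` columns appended.
#' @export
adjust_family <- function(tests, method = "BH", family = "family_1") {
  if (nrow(tests) == 0) abort("empty test family")
  dplyr::mutate(tests, p_adj = p.adjust(.data$p_value, method = method),
                family = family)
}

#' Association between alpha diversity and a covariate
#'
#' For numeric covariates, a simple linear regression of the (transformed)
#' diversity values with slope and F-test; for two-level covariates (e.g.
#' survival), a Welch t-test.
#'
#' @param values Alpha-diversity values, normally transformed via
#'   [transform_alpha()] (a warning is raised otherwise for metrics that
#'   need it).
#' @param covariate Numeric vector or two-level factor.
#' @param kind `"regression"` or `"welch"`.
#' @param metric Optional metric name used only to warn about missing
#'   transforms.
#' @return One-row tibble: `kind`, `estimate` (slope or mean difference),
#'   `statistic`, `df`, `p_value`.
#' @export
alpha_association <- function(values, covariate,
                              kind = c("regression", "welch"),
                              metric = NULL) {
  kind <- match.arg(kind)
  if (!is.null(metric) && metric %in% c("shannon", "faith_pd") &&
      !isTRUE(attr(values, "transformed"))) {
    warn(sprintf("'%s' values look untransformed; see transform_alpha()", metric))
  }
  values <- as.numeric(values)
  if (kind == "regression") {
    if (sd(values) == 0) {
      return(tibble::tibble(kind = kind, estimate = 0, statistic = NA_real_,
                            df = NA_real_, p_value = 1))
    }
    fit <- lm(values ~ covariate)
    s <- summary(fit)
    tibble::tibble(kind = kind,
                   estimate = coef(fit)[2],
                   statistic = s$fstatistic[1],
                   df = s$fstatistic[3],
                   p_value = pf(s$fstatistic[1], s$fstatistic[2],
                                s$fstatistic[3], lower.tail = FALSE))
  } else {
    f <- as.factor(covariate)
    if (nlevels(droplevels(f)) != 2) abort("welch kind needs two groups")
    res <- welch_t(values[f == levels(f)[1]], values[f == levels(f)[2]])
    tibble::tibble(kind = kind, estimate = res$effect,
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value)
  }
}
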