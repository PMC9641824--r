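#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-unit result table of a
#' fitted object (per day, per term, per taxon, per model), `glance()` a
#' one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @name migrobiome-tidiers
NULL

#' @rdname migrobiome-tidiers
#' @export
tidy.track_segmentation <- function(x, ...) x$segments

#' @rdname migrobiome-tidiers
#' @export
glance.track_segmentation <- function(x, ...) {
  x$segments |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(n_days = dplyr::n(),
                     n_migratory = sum(.data$day_class == "migratory"),
                     n_stopover = sum(.data$day_class == "stopover"),
                     .groups = "drop") |>
    dplyr::left_join(x$outcomes, by = "individual_id")
}

#' @rdname migrobiome-tidiers
#' @export
tidy.permanova_fit <- function(x, ...) x$results

#' @rdname migrobiome-tidiers
#' @export
glance.permanova_fit <- function(x, ...) {
  terms_only <- dplyr::filter(x$results, !.data$term %in% c("Residual", "Total"))
  tibble::tibble(by = x$by, n_perm = x$n_perm,
                 r_squared_model = sum(terms_only$r_squared),
                 min_p = min(terms_only$p_value))
}

#' @rdname migrobiome-tidiers
#' @export
tidy.da_fit <- function(x, ...) x$results

#' @rdname migrobiome-tidiers
#' @export
glance.da_fit <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$results),
                 n_selected = sum(x$results$selected),
                 w_cut = x$w_cut, n_iter = x$n_iter)
}

#' @rdname migrobiome-tidiers
#' @export
tidy.model_comparison <- function(x, ...) x$results

#' @rdname migrobiome-tidiers
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$results), n = x$n,
                 best = x$results$model[1],
                 n_best_set = sum(x$results$in_best_set))
}

#' @rdname migrobiome-tidiers
#' @export
tidy.dispersion_test <- function(x, ...) x$distances

#' @rdname migrobiome-tidiers
#' @export
glance.dispersion_test <- function(x, ...) {
  tibble::tibble(f = x$f, p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname migrobiome-tidiers
#' @export
tidy.pcoa_ord <- function(x, ...) x$points

#' @export
print.track_segmentation <- function(x, ...) {
  cat("<track_segmentation> ", nrow(x$outcomes), " individual(s), ",
      nrow(x$segments), " day segments\n", sep = "")
  print(x$outcomes)
  invisible(x)
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("PERMANOVA (", x$by, " mode, ", x$n_perm, " permutations)\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @export
print.da_fit <- function(x, ...) {
  cat("Bias-corrected differential abundance: ", nrow(x$results),
      " taxa tested, ", sum(x$results$selected), " selected\n", sep = "")
  print(dplyr::arrange(x$results, .data$q_value))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("AICc model comparison (n = ", x$n, ")\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate dispersion: F = ", signif(x$f, 4),
      ", permutation p = ", signif(x$p_value, 4), "\n", sep = "")
  print(x$group_dispersion)
  invisible(x)
}
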