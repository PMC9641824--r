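#' Scaled mass index of body condition
#'
#' Standardizes body mass to the cohort's arithmetic mean wing length via the
#' allometric scaling `SMI_i = M_i * (L0 / L_i)^b`, with `L0` the mean wing
#' length and `b` the standardized major axis (SMA) slope of `ln(mass)` on
#' `ln(wing)` — the ordinary least-squares slope divided by the Pearson
#' correlation of the logged variables. Because sexual size dimorphism in
#' raptors distorts the mass-size relationship across sexes, the index must
#' be computed within one sex at a time; mixed-sex input is refused.
#'
#' @param data Tibble with one row per individual including `sex`, a mass
#'   column and a wing-length column.
#' @param mass Column name for body mass (g). Default `mass_g`.
#' @param wing Column name for wing length (mm). Default `wing_mm`.
#' @return `data` with an appended `smi_g` column.
#' @examples
#' birds <- tibble::tibble(sex = "female",
#'                         mass_g = c(600, 650, 700),
#'                         wing_mm = c(380, 390, 400))
#' smi(birds)
#' @export
smi <- function(data, mass = "mass_g", wing = "wing_mm") {
  if (!"sex" %in% names(data)) abort("data needs a `sex` column")
  if (length(unique(data$sex)) > 1) {
    abort("smi() must be run on one sex at a time (strong sexual dimorphism)")
  }
  if (nrow(data) < 3) abort("need at least 3 records to fit the SMA slope")
  m <- data[[mass]]
  l <- data[[wing]]
  if (any(m <= 0) || any(l <= 0)) abort("mass and wing length must be positive")
  if (sd(l) == 0) {
    # degenerate allometry: all wings equal the mean, so mass is its own index
    return(dplyr::mutate(data, smi_g = m))
  }
  b <- sma_slope(log(m), log(l))
  dplyr::mutate(data, smi_g = m * (mean(l) / l)^b)
}

#' Standardized major axis slope
#'
#' SMA slope of `y` on `x`: the OLS slope divided by the Pearson correlation,
#' equivalently `sign(r) * sd(y) / sd(x)`.
#'
#' @param y,x Numeric vectors (already on the scale to be regressed, e.g.
#'   logged).
#' @return The SMA slope.
#' @export
sma_slope <- function(y, x) {
  if (sd(x) == 0) abort("SMA slope undefined: zero variance in x")
  r <- stats::cor(x, y)
  if (is.na(r) || r == 0) abort("SMA slope undefined: zero correlation")
  sign(r) * sd(y) / sd(x)
}

#' EURING age code to age class
#'
#' Ringing-scheme code 5 denotes a first-year (juvenile) bird; codes of 6
#' and above denote second-year-and-older (adult) birds.
#'
#' @param euring_age Integer codes, all `>= 5`.
#' @return Factor with levels `juvenile`, `adult`.
#' @examples
#' assign_age(c(5, 6, 9))
#' @export
assign_age <- function(euring_age) {
  if (any(is.na(euring_age)) || any(euring_age < 5)) {
    abort("EURING age codes below 5 are not used in this scheme")
  }
  factor(ifelse(euring_age == 5, "juvenile", "adult"),
         levels = c("juvenile", "adult"))
}

#' Add the scaled mass index to a mixed-sex metadata table
#'
#' Splits by sex, computes [smi()] within each sex, and recombines.
#'
#' @inheritParams smi
#' @return `data` with `smi_g` and `age_class` columns appended.
#' @export
add_condition <- function(data, mass = "mass_g", wing = "wing_mm") {
  out <- data |>
    dplyr::group_split(.data$sex) |>
    purrr::map(smi, mass = mass, wing = wing) |>
    dplyr::bind_rows()
  if ("euring_age" %in% names(out) && !"age_class" %in% names(out)) {
    out <- dplyr::mutate(out, age_class = assign_age(.data$euring_age))
  }
  if ("id" %in% names(out)) {
    out <- dplyr::arrange(out, match(.data$id, data$id))
  }
  out
}
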