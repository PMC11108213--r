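#' Fit a linear standard curve
#'
#' Ordinary least-squares calibration line (absorbance or band area versus
#' known concentration), as used for BSA protein standards, glucose
#' standards and densitometry lanes. At least three distinct concentrations
#' are required.
#'
#' @param standards Data frame with columns `concentration` and
#'   `absorbance` (an `area` column is accepted as a synonym).
#' @return An object of class `standard_curve`: slope, intercept, R^2,
#'   valid range, and the underlying `lm` fit for diagnostics.
#' @export
#' @examples
#' std <- tibble::tibble(concentration = c(0.25, 0.5, 1), absorbance = c(0.17, 0.3, 0.55))
#' fit_standard_curve(std)
fit_standard_curve <- function(standards) {
  if (!"absorbance" %in% names(standards) && "area" %in% names(standards))
    standards$absorbance <- standards$area
  stopifnot(all(c("concentration", "absorbance") %in% names(standards)))
  conc <- standards$concentration
  if (length(unique(conc)) < 3)
    stop("calibration needs at least 3 distinct concentrations", call. = FALSE)
  if (sd(conc) == 0) stop("zero concentration variance", call. = FALSE)
  fit <- lm(absorbance ~ concentration, data = standards)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    range = range(conc), n = length(conc), fit = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> A =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "* conc;  R^2 =", signif(x$r_squared, 4),
      "; valid range [", x$range[1], ",", x$range[2], "]\n")
  invisible(x)
}

#' @method tidy standard_curve
#' @export
#' @importFrom generics tidy
tidy.standard_curve <- function(x, ...) {
  out <- tibble::as_tibble(summary(x$fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out
}

#' @method glance standard_curve
#' @export
#' @importFrom generics glance
glance.standard_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n = x$n,
                 range_lo = x$range[1], range_hi = x$range[2])
}

#' Invert absorbances through a standard curve
#'
#' Computes `concentration = (A - background - intercept) / slope`. The
#' background is the non-recombinant-strain absorbance in excess of the
#' curve intercept (per-arm scalar), subtracted before inversion. Negative
#' results are clipped to zero and flagged; results outside the calibrated
#' range are flagged as extrapolated.
#'
#' @param samples Numeric absorbances (or a data frame with a `value`
#'   column).
#' @param curve A [fit_standard_curve()] result.
#' @param background Background absorbance to subtract (default 0).
#' @return A tibble with `absorbance`, `concentration`, `clipped`,
#'   `extrapolated`.
#' @export
quantify <- function(samples, curve, background = 0) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve has zero slope", call. = FALSE)
  A <- if (is.data.frame(samples)) samples$value else samples
  conc <- (A - background - curve$intercept) / curve$slope
  clipped <- conc < 0
  tibble::tibble(
    absorbance = A,
    concentration = pmax(conc, 0),
    clipped = clipped,
    extrapolated = conc > curve$range[2] | (conc < curve$range[1] & !clipped)
  )
}

#' Enzyme activity from DNS absorbance
#'
#' Converts A540 readings to reducing-sugar (glucose) concentration via the
#' glucose standard curve, then to activity with 1 U = 1 umol glucose
#' released per minute, reported per mL of enzyme sample:
#' `U/mL = glucose_mM * reaction_volume_mL / (incubation_min * volume_mL)`.
#'
#' @param A540 Numeric absorbances at 540 nm (or data frame with `value`).
#' @param glucose_curve Standard curve in AU per mM glucose.
#' @param incubation_min Hydrolysis time, minutes (default 30).
#' @param volume_mL Enzyme (supernatant) volume in the reaction, mL.
#' @param reaction_volume_mL Total reaction volume, mL.
#' @param background Background absorbance (default 0).
#' @return A tibble with `absorbance`, `glucose_mM`, `activity_U_ml` and
#'   the flags from [quantify()].
#' @export
enzyme_activity <- function(A540, glucose_curve, incubation_min = 30,
                            volume_mL = 0.5, reaction_volume_mL = 1,
                            background = 0) {
  stopifnot(incubation_min > 0, volume_mL > 0, reaction_volume_mL > 0)
  q <- quantify(A540, glucose_curve, background)
  tibble::tibble(
    absorbance = q$absorbance,
    glucose_mM = q$concentration,
    activity_U_ml = q$concentration * reaction_volume_mL /
      (incubation_min * volume_mL),
    clipped = q$clipped, extrapolated = q$extrapolated
  )
}

#' Group statistics, percent increases and fold changes
#'
#' Per arm and assay: group mean, SD and n; for each treated group, the
#' percent increase and fold change of its mean over the control mean, a
#' delta-method standard error of the percent increase, and a descriptive
#' Welch two-sample p-value for the treated-vs-control contrast (no
#' multiplicity adjustment; the study reports descriptive error bars only).
#'
#' @param table An AssayTable: data frame with columns `arm`, `group`,
#'   `replicate`, `value` (an `assay` column is carried through if present).
#'   Values may be raw absorbances or derived concentrations/activities.
#' @param control Label of the control group (default `"control"`).
#' @return An object of class `treatment_result` (a tibble).
#' @export
#' @examples
#' tabs <- make_assay_tables(assay_spec(seed = 1))
#' compare_groups(tabs$bradford)
compare_groups <- function(table, control = "control") {
  stopifnot(all(c("arm", "group", "value") %in% names(table)))
  if (!"assay" %in% names(table)) table$assay <- "value"
  if (!control %in% table$group)
    stop("control group '", control, "' missing", call. = FALSE)
  res <- table |>
    dplyr::group_by(.data$arm, .data$assay, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), values = list(.data$value),
                     .groups = "drop_last") |>
    dplyr::mutate(
      ctrl_mean = .data$mean[.data$group == control],
      ctrl_sd   = .data$sd[.data$group == control],
      ctrl_n    = .data$n[.data$group == control],
      ctrl_values = list(.data$values[[which(.data$group == control)]])
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fold = .data$mean / .data$ctrl_mean,
      percent_increase = 100 * (.data$fold - 1),
      se_percent = 100 * sqrt(
        (.data$sd^2 / .data$n) / .data$ctrl_mean^2 +
          .data$mean^2 * (.data$ctrl_sd^2 / .data$ctrl_n) / .data$ctrl_mean^4),
      p_welch = purrr::pmap_dbl(
        list(.data$values, .data$ctrl_values, .data$group),
        function(v, cv, grp) {
          if (grp == control) return(NA_real_)
          tryCatch(t.test(v, cv)$p.value, error = function(e) NA_real_)
        })
    ) |>
    dplyr::select(-"values", -"ctrl_values") |>
    dplyr::mutate(percent_increase = ifelse(.data$group == control, 0,
                                            .data$percent_increase),
                  fold = ifelse(.data$group == control, 1, .data$fold))
  class(res) <- c("treatment_result", class(res))
  res
}

#' @method glance treatment_result
#' @export
#' @importFrom generics glance
glance.treatment_result <- function(x, ...) {
  x |>
    dplyr::filter(.data$group != "control") |>
    dplyr::group_by(.data$arm, .data$assay) |>
    dplyr::slice_max(.data$fold, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("arm", "assay", max_group = "group",
                  max_percent_increase = "percent_increase",
                  max_fold = "fold")
}

#' Densitometry band areas to concentration estimates
#'
#' Linear calibration of integrated SDS-PAGE band areas against BSA
#' standard lanes, then inversion of sample lane areas; the gel-image ROI
#' extraction itself is upstream of this function (band areas are the
#' quantitative input).
#'
#' @param band_areas Numeric sample lane areas (or data frame with `value`).
#' @param bsa_standards Data frame with `concentration` and `area` (or
#'   `absorbance`) for at least 3 BSA lanes.
#' @param background Background area to subtract (default 0).
#' @return A tibble as from [quantify()].
#' @export
densitometry_concentrations <- function(band_areas, bsa_standards,
                                        background = 0) {
  curve <- fit_standard_curve(bsa_standards)
  quantify(band_areas, curve, background)
}
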