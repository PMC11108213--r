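#' Diagnostic emission-line catalog
#'
#' Atomic/molecular transition constants for the four diagnostic lines: the
#' He I Boltzmann pair used for electron temperature (706.5 nm triplet,
#' 728.1 nm singlet) and the molecular-nitrogen Saha-Boltzmann pair used
#' for electron density (N2 second positive system 357.6 nm, N2+ first
#' negative system 391.1 nm). Energies are upper-level energies (eV), `g`
#' upper-level statistical weights, `A` Einstein coefficients (1/s).
#' Values are fixed as catalogued for the study's arithmetic; no database
#' lookup is performed at run time.
#'
#' @return A tibble with columns `species`, `wavelength_nm`, `E_upper_eV`,
#'   `g`, `A`, `role`.
#' @export
#' @examples
#' he_n2_lines()
he_n2_lines <- function() {
  tibble::tibble(
    species       = c("He I", "He I", "N2", "N2+"),
    wavelength_nm = c(706.5, 728.1, 357.6, 391.1),
    E_upper_eV    = c(22.7185, 22.9203, 11.05, 3.16),
    g             = c(3, 1, 1, 1),
    A             = c(1.5474e7, 1.8299e7, 8.84e6, 1.14e7),
    role          = c("Te_triplet", "Te_singlet", "ne_neutral", "ne_ion")
  )
}

# Ionization energy of molecular nitrogen used in the Saha-Boltzmann step.
.E_ion_N2 <- 15.58

.line <- function(lines, role) {
  i <- match(role, lines$role)
  if (is.na(i)) stop("line catalog lacks role ", role, call. = FALSE)
  lines[i, ]
}

#' Construct a spectrum trace
#'
#' @param wavelength_nm Strictly increasing wavelengths, nm.
#' @param intensity Intensities (arbitrary units), same length, finite.
#' @param meta Optional named list of acquisition metadata.
#' @return A tibble of class `spectrum_trace`.
#' @export
spectrum_trace <- function(wavelength_nm, intensity, meta = list()) {
  stopifnot(length(wavelength_nm) == length(intensity),
            length(wavelength_nm) >= 2,
            all(is.finite(wavelength_nm)), all(is.finite(intensity)))
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(wavelength_nm = wavelength_nm, intensity = intensity)
  class(out) <- c("spectrum_trace", class(out))
  attr(out, "meta") <- meta
  out
}

#' Baseline-subtracted line intensity
#'
#' Integrates a spectral window `[center - half_window, center + half_window]`
#' after subtracting a straight baseline anchored on the averaged outer
#' points of the window (trapezoidal rule), or returns the
#' baseline-subtracted peak height when `mode = "height"`. For a window of pure baseline the result is ~0 (and
#' may be slightly negative under noise).
#'
#' @param trace A `spectrum_trace` (or data frame with `wavelength_nm`,
#'   `intensity`).
#' @param center Line center, nm.
#' @param half_window Half-width of the integration window, nm (default 0.5).
#' @param mode `"area"` (default) or `"height"`.
#' @return Integrated intensity (units: intensity x nm) or peak height.
#' @export
integrate_line <- function(trace, center, half_window = 0.5,
                           mode = c("area", "height")) {
  mode <- match.arg(mode)
  wl <- trace$wavelength_nm; it <- trace$intensity
  lo <- center - half_window; hi <- center + half_window
  if (lo < min(wl) || hi > max(wl))
    stop("integration window [", lo, ", ", hi, "] nm outside trace range",
         call. = FALSE)
  sel <- wl >= lo & wl <= hi
  w <- wl[sel]; y <- it[sel]
  if (length(w) < 3) stop("too few samples in window", call. = FALSE)
  # robust baseline: average the outer points on each side of the window
  # (single-point anchors would propagate their full noise into the area)
  k <- max(1L, min(round(0.08 * length(w)), (length(w) - 1L) %/% 2L))
  xL <- mean(w[seq_len(k)]); yL <- mean(y[seq_len(k)])
  xR <- mean(w[seq(length(w) - k + 1L, length(w))])
  yR <- mean(y[seq(length(w) - k + 1L, length(w))])
  base <- yL + (yR - yL) * (w - xL) / (xR - xL)
  yc <- y - base
  if (mode == "height") return(max(yc))
  sum(diff(w) * (head(yc, -1) + tail(yc, -1)) / 2)
}

#' Electron temperature from the He I 728.1/706.5 nm line ratio
#'
#' Boltzmann line-ratio estimate assuming a Boltzmann population of the
#' n = 3 upper levels:
#' `Te = (E_728 - E_706) / ln(A_728 g_728 I_706 lambda_706 /
#'  (A_706 g_706 I_728 lambda_728))` with `Te` in eV. The singlet 728.1 nm
#' line carries the higher upper-level energy, so the estimate depends only
#' on the intensity ratio and is scale invariant.
#'
#' @param I_706,I_728 Measured (integrated) intensities of the two He I
#'   lines; both must be > 0.
#' @param lines Line catalog (default [he_n2_lines()]).
#' @return Electron temperature, eV.
#' @export
#' @examples
#' estimate_Te(I_706 = 2.995, I_728 = 1)  # ~1.485 eV
estimate_Te <- function(I_706, I_728, lines = he_n2_lines()) {
  if (any(c(I_706, I_728) <= 0) || any(!is.finite(c(I_706, I_728))))
    stop("line intensities must be positive", call. = FALSE)
  s <- .line(lines, "Te_singlet"); t3 <- .line(lines, "Te_triplet")
  arg <- (s$A * s$g * I_706 * t3$wavelength_nm) /
         (t3$A * t3$g * I_728 * s$wavelength_nm)
  if (arg < 1)
    stop("non-physical ratio: I_706/I_728 = ", signif(I_706 / I_728, 4),
         " gives Boltzmann argument ", signif(arg, 4), " < 1", call. = FALSE)
  if (arg == 1)
    stop("degenerate ratio: Boltzmann argument is exactly 1 (infinite Te)",
         call. = FALSE)
  (s$E_upper_eV - t3$E_upper_eV) / log(arg)
}

#' Electron density from the N2 357.6 / N2+ 391.1 nm line ratio
#'
#' Saha-Boltzmann estimate using a neutral/ion line pair:
#' `ne = 2 (2 pi me kB Te)^{3/2} / h^3 * (I_357 A_391 g_391 lambda_357) /
#'  (I_391 A_357 g_357 lambda_391) * exp(-(E_ion - E_391 + E_357)/Te)`
#' with the molecular-nitrogen ionization energy 15.58 eV and Te in eV.
#' The estimate is linear in `I_357/I_391` at fixed Te.
#'
#' @param I_357,I_391 Measured (integrated) intensities; both > 0.
#' @param Te Electron temperature, eV (> 0), typically from [estimate_Te()].
#' @param lines Line catalog (default [he_n2_lines()]).
#' @return Electron density, m^-3 (divide by 1e6 for cm^-3).
#' @export
#' @examples
#' estimate_ne(I_357 = 0.0567, I_391 = 1, Te = 1.4851) / 1e6  # ~1e14 cm^-3
estimate_ne <- function(I_357, I_391, Te, lines = he_n2_lines()) {
  if (!is.finite(Te) || Te <= 0) stop("Te must be positive", call. = FALSE)
  if (any(c(I_357, I_391) <= 0) || any(!is.finite(c(I_357, I_391))))
    stop("line intensities must be positive", call. = FALSE)
  n2 <- .line(lines, "ne_neutral"); n2p <- .line(lines, "ne_ion")
  saha <- 2 * (2 * pi * .const$me * Te * .const$e)^1.5 / .const$h^3
  ratio <- (I_357 * n2p$A * n2p$g * n2$wavelength_nm) /
           (I_391 * n2$A * n2$g * n2p$wavelength_nm)
  dE <- .E_ion_N2 - n2p$E_upper_eV + n2$E_upper_eV
  saha * ratio * exp(-dE / Te)
}

#' Line-ratio diagnosis of a full spectrum
#'
#' Integrates the four diagnostic lines (baseline-subtracted windows),
#' estimates Te from the He I pair and then ne from the nitrogen pair at
#' that Te. If the nitrogen windows fall outside the trace, a partial
#' result with Te only is returned (`ne` is `NA` and flagged missing);
#' missing He windows are an error since nothing can be estimated.
#'
#' @param trace A `spectrum_trace`.
#' @param lines Line catalog (default [he_n2_lines()]).
#' @param half_window Integration half-window, nm (default 0.5).
#' @param mode Intensity mode passed to [integrate_line()].
#' @return An object of class `line_ratio_result`: list with `Te_eV`,
#'   `ne_m3`, `ne_cm3`, `intensities` (tibble of the four integrals),
#'   `ratios`, `ne_missing`, and the constants used.
#' @export
diagnose_spectrum <- function(trace, lines = he_n2_lines(),
                              half_window = 0.5, mode = c("area", "height")) {
  mode <- match.arg(mode)
  wl_ok <- function(l) (l - half_window) >= min(trace$wavelength_nm) &&
                       (l + half_window) <= max(trace$wavelength_nm)
  he <- c(.line(lines, "Te_triplet")$wavelength_nm,
          .line(lines, "Te_singlet")$wavelength_nm)
  nn <- c(.line(lines, "ne_neutral")$wavelength_nm,
          .line(lines, "ne_ion")$wavelength_nm)
  if (!all(vapply(he, wl_ok, logical(1))))
    stop("trace does not cover the He I diagnostic lines", call. = FALSE)
  I <- vapply(c(he, nn), function(l) {
    if (wl_ok(l)) integrate_line(trace, l, half_window, mode) else NA_real_
  }, numeric(1))
  names(I) <- c("I_706", "I_728", "I_357", "I_391")
  Te <- estimate_Te(I[["I_706"]], I[["I_728"]], lines)
  ne_missing <- anyNA(I[c("I_357", "I_391")])
  ne <- if (ne_missing) NA_real_ else
    estimate_ne(I[["I_357"]], I[["I_391"]], Te, lines)
  structure(list(
    Te_eV = Te, ne_m3 = ne, ne_cm3 = ne / 1e6,
    intensities = tibble::tibble(line = names(I), intensity = unname(I)),
    ratios = c(r_706_728 = unname(I["I_706"] / I["I_728"]),
               r_357_391 = unname(I["I_357"] / I["I_391"])),
    ne_missing = ne_missing,
    constants = list(kB_eVK = .const$kB_eVK, me = .const$me, h = .const$h,
                     E_ion_N2_eV = .E_ion_N2)
  ), class = "line_ratio_result")
}

#' @export
print.line_ratio_result <- function(x, ...) {
  cat("<line_ratio_result>\n")
  cat("  Te =", signif(x$Te_eV, 5), "eV  (I706/I728 =",
      signif(x$ratios[["r_706_728"]], 4), ")\n")
  if (isTRUE(x$ne_missing)) {
    cat("  ne = <missing: nitrogen lines not covered>\n")
  } else {
    cat("  ne =", signif(x$ne_m3, 3), "m^-3 =", signif(x$ne_cm3, 3),
        "cm^-3  (I357/I391 =", signif(x$ratios[["r_357_391"]], 4), ")\n")
  }
  invisible(x)
}

#' @method tidy line_ratio_result
#' @export
#' @importFrom generics tidy
tidy.line_ratio_result <- function(x, ...) {
  tibble::tibble(
    quantity = c("Te", "ne"),
    estimate = c(x$Te_eV, x$ne_cm3),
    unit = c("eV", "cm^-3")
  )
}
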