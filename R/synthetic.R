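# Run code under a local RNG state so generators are pure functions of
# their spec (seed included) and never disturb the caller's RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic emission spectrum
#'
#' Defines the ground truth and instrument model for [make_spectrum()]. The
#' defaults are the study conditions of the AC-driven plume diagnosis:
#' true Te 1.4851 eV and true ne 1e14 cm^-3. Decoy lines at other plausible
#' plasma wavelengths (OH, N2 bands, other He I lines, O I) are included by
#' default to exercise window robustness.
#'
#' @param Te_eV True electron temperature, eV (> 0).
#' @param ne_cm3 True electron density, cm^-3 (>= 0).
#' @param lines Diagnostic line catalog (default [he_n2_lines()]).
#' @param width_nm Gaussian instrumental line width (sd), nm; the default
#'   0.2 nm corresponds to a ~0.5 nm FWHM compact CCD spectrometer.
#' @param baseline_level,baseline_slope Additive baseline: level at the grid
#'   start and slope per nm.
#' @param noise_sd Multiplicative Gaussian noise sd (fraction of intensity).
#' @param wl_min,wl_max,wl_step Wavelength grid, nm; must cover every
#'   catalog line by at least 5 widths.
#' @param decoys Include the 6 decoy lines (logical).
#' @param seed Integer seed for the noise realization (NULL = no noise
#'   seeding control; generation is then only deterministic if noise_sd = 0).
#' @return A list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(Te_eV = 1.4851, ne_cm3 = 1e14,
                          lines = he_n2_lines(), width_nm = 0.2,
                          baseline_level = 20, baseline_slope = 0.01,
                          noise_sd = 0.05,
                          wl_min = 300, wl_max = 800, wl_step = 0.005,
                          decoys = TRUE, seed = 1L) {
  stopifnot(Te_eV > 0, ne_cm3 >= 0, width_nm > 0, wl_step > 0,
            noise_sd >= 0)
  all_wl <- c(lines$wavelength_nm,
              if (decoys) c(308.9, 315.9, 337.1, 380.5, 587.6, 777.3))
  if (any(all_wl - 5 * width_nm < wl_min) || any(all_wl + 5 * width_nm > wl_max))
    stop("wavelength grid does not cover all lines by 5 widths", call. = FALSE)
  structure(list(Te_eV = Te_eV, ne_cm3 = ne_cm3, lines = lines,
                 width_nm = width_nm, baseline_level = baseline_level,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 wl_min = wl_min, wl_max = wl_max, wl_step = wl_step,
                 decoys = decoys, seed = seed),
            class = "spectrum_spec")
}

# Noise-free line areas consistent with (Te, ne): the He pair ratio comes
# from inverting the Boltzmann relation, the nitrogen pair ratio from
# inverting the Saha-Boltzmann relation at the same Te.
.spectrum_truth_areas <- function(spec) {
  l <- spec$lines
  s <- .line(l, "Te_singlet"); t3 <- .line(l, "Te_triplet")
  C1 <- (s$A * s$g * t3$wavelength_nm) / (t3$A * t3$g * s$wavelength_nm)
  r_he <- exp((s$E_upper_eV - t3$E_upper_eV) / spec$Te_eV) / C1
  A_728 <- 1000
  A_706 <- r_he * A_728
  A_391 <- 800
  r_n2 <- spec$ne_cm3 * 1e6 /
    estimate_ne(I_357 = 1, I_391 = 1, Te = spec$Te_eV, lines = l)
  A_357 <- r_n2 * A_391
  c(`706.5` = A_706, `728.1` = A_728, `357.6` = A_357, `391.1` = A_391)
}

#' Generate a synthetic emission spectrum with known ground truth
#'
#' Builds Gaussian line profiles whose integrated-intensity ratios invert
#' the two line-ratio relations exactly at the true (Te, ne), adds optional
#' decoy lines, a linear baseline, and seeded multiplicative noise. With
#' zero noise and baseline, [diagnose_spectrum()] recovers the truth to
#' numerical tolerance (round trip by construction).
#'
#' @param spec A [spectrum_spec()].
#' @return A `spectrum_trace` whose `meta` attribute records the truth.
#' @export
#' @examples
#' tr <- make_spectrum(spectrum_spec(noise_sd = 0))
#' diagnose_spectrum(tr)
make_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  wl <- seq(spec$wl_min, spec$wl_max, by = spec$wl_step)
  areas <- .spectrum_truth_areas(spec)
  centers <- as.numeric(names(areas))
  if (spec$decoys) {
    centers <- c(centers, 308.9, 315.9, 337.1, 380.5, 587.6, 777.3)
    areas <- c(areas, 450, 180, 1500, 350, 600, 250)
  }
  s <- spec$width_nm
  y <- numeric(length(wl))
  for (i in seq_along(centers)) {
    sel <- which(abs(wl - centers[i]) < 8 * s)   # windowed evaluation
    y[sel] <- y[sel] + areas[i] / (s * sqrt(2 * pi)) *
      exp(-(wl[sel] - centers[i])^2 / (2 * s^2))
  }
  y <- y + spec$baseline_level + spec$baseline_slope * (wl - spec$wl_min)
  if (spec$noise_sd > 0) {
    y <- .with_seed(spec$seed, y * (1 + rnorm(length(y), 0, spec$noise_sd)))
  }
  spectrum_trace(wl, y, meta = list(
    truth = list(Te_eV = spec$Te_eV, ne_cm3 = spec$ne_cm3, areas = areas),
    spec = spec
  ))
}

#' Specification for synthetic assay tables
#'
#' Ground truth for [make_assay_tables()]. Defaults emulate the study's
#' reported outcomes: dose-dependent protein increase reaching +45% (AC) and
#' +33% (DC) at 240 s by Bradford, 1.25-fold (AC) and 1.19-fold (DC) enzyme
#' activity, densitometry increases of 47% (AC) and 39% (DC), and null
#' effects on OD600 growth and MTT viability. Group means are pushed through
#' the true standard curves and replicate noise is additive Gaussian on the
#' measured absorbance (default 0.01 AU).
#'
#' @param arms Treatment arms (default AC and DC).
#' @param groups Exposure groups; `control` plus treatment durations (s).
#' @param n_replicates Replicates per group (>= 3; default 4).
#' @param multipliers Named list per assay of per-arm effect multipliers
#'   (control first, must be 1).
#' @param curves True standard-curve parameters for Bradford (AU per mg/mL),
#'   DNS (AU per mM) and densitometry (area per mg/mL).
#' @param control_levels True control-group analyte levels.
#' @param noise_sd Named additive noise sds on the measured values.
#' @param background_conc Non-recombinant background protein, mg/mL
#'   (adds absorbance to every Bradford/densitometry measurement).
#' @param seed Integer seed.
#' @return A list of class `assay_spec`.
#' @export
assay_spec <- function(arms = c("AC", "DC"),
                       groups = c("control", "120", "180", "240"),
                       n_replicates = 4,
                       multipliers = list(
                         bradford  = list(AC = c(1, 1.15, 1.30, 1.45),
                                          DC = c(1, 1.11, 1.22, 1.33)),
                         activity  = list(AC = c(1, 1.08, 1.16, 1.25),
                                          DC = c(1, 1.06, 1.13, 1.19)),
                         band_area = list(AC = c(1, 1.16, 1.31, 1.47),
                                          DC = c(1, 1.13, 1.26, 1.39)),
                         od600     = list(AC = c(1, 1, 1, 1), DC = c(1, 1, 1, 1)),
                         mtt       = list(AC = c(1, 1, 1, 1), DC = c(1, 1, 1, 1))
                       ),
                       curves = list(
                         bradford = c(slope = 0.5, intercept = 0.05),
                         dns = c(slope = 0.35, intercept = 0.02),
                         densitometry = c(slope = 10000, intercept = 0)
                       ),
                       control_levels = list(protein_mg_ml = 0.4,
                                             glucose_mM = 2,
                                             od600 = 8, mtt_A = 0.6),
                       noise_sd = c(bradford = 0.01, dns = 0.01, mtt = 0.02,
                                    od600 = 0.15, band_area = 150),
                       background_conc = 0.15, seed = 1L) {
  stopifnot(n_replicates >= 3, groups[1] == "control")
  for (a in names(multipliers)) for (arm in names(multipliers[[a]])) {
    m <- multipliers[[a]][[arm]]
    if (length(m) != length(groups) || m[1] != 1)
      stop("multipliers$", a, "$", arm,
           ": need one value per group with control = 1", call. = FALSE)
  }
  structure(list(arms = arms, groups = groups, n_replicates = n_replicates,
                 multipliers = multipliers, curves = curves,
                 control_levels = control_levels, noise_sd = noise_sd,
                 background_conc = background_conc, seed = seed),
            class = "assay_spec")
}

#' Generate synthetic assay tables with a truth record
#'
#' Produces tidy AssayTables (columns `arm`, `group`, `replicate`, `assay`,
#' `value`) for the Bradford, DNS, OD600, MTT and densitometry readouts,
#' plus the standards needed to calibrate (BSA concentration/absorbance
#' pairs, glucose standards, BSA lane areas) and a `truth` record holding
#' every programmed parameter so downstream estimates can be scored.
#'
#' @param spec An [assay_spec()].
#' @return A list of class `assay_tables` with elements `bradford`, `dns`,
#'   `od600`, `mtt`, `band_area` (AssayTable tibbles), `bsa_standards`,
#'   `glucose_standards`, `bsa_lanes`, `background_A595`, and `truth`.
#' @export
#' @examples
#' tabs <- make_assay_tables(assay_spec(seed = 7))
#' compare_groups(tabs$bradford)
make_assay_tables <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  g <- expand.grid(arm = spec$arms, group = spec$groups,
                   replicate = seq_len(spec$n_replicates),
                   stringsAsFactors = FALSE)
  mult <- function(assay, arm, group) {
    spec$multipliers[[assay]][[arm]][match(group, spec$groups)]
  }
  cb <- spec$curves$bradford; cd <- spec$curves$dns; cg <- spec$curves$densitometry
  .with_seed(spec$seed, {
    noisy <- function(x, sd) x + rnorm(length(x), 0, sd)
    tab <- function(assay_label, value) {
      out <- tibble::tibble(arm = g$arm, group = g$group,
                            replicate = g$replicate, assay = assay_label,
                            value = unname(pmax(value, 0)))
      class(out) <- c("assay_table", class(out))
      out
    }
    prot <- spec$control_levels$protein_mg_ml *
      mapply(mult, "bradford", g$arm, g$group)
    bradford <- tab("Bradford_A595", noisy(
      cb["intercept"] + cb["slope"] * (prot + spec$background_conc),
      spec$noise_sd[["bradford"]]))
    gluc <- spec$control_levels$glucose_mM *
      mapply(mult, "activity", g$arm, g$group)
    dns <- tab("DNS_A540", noisy(cd["intercept"] + cd["slope"] * gluc,
                                 spec$noise_sd[["dns"]]))
    od600 <- tab("OD600", noisy(
      spec$control_levels$od600 * mapply(mult, "od600", g$arm, g$group),
      spec$noise_sd[["od600"]]))
    mtt <- tab("MTT_A", noisy(
      spec$control_levels$mtt_A * mapply(mult, "mtt", g$arm, g$group),
      spec$noise_sd[["mtt"]]))
    dens_prot <- spec$control_levels$protein_mg_ml *
      mapply(mult, "band_area", g$arm, g$group)
    band <- tab("band_area", noisy(
      cg["intercept"] + cg["slope"] * (dens_prot + spec$background_conc),
      spec$noise_sd[["band_area"]]))
    bsa_conc <- c(0.125, 0.25, 0.5, 1)
    bsa_standards <- tibble::tibble(
      concentration = bsa_conc,
      absorbance = unname(noisy(cb["intercept"] + cb["slope"] * bsa_conc,
                                spec$noise_sd[["bradford"]])))
    glu_conc <- c(0.5, 1, 2, 4)
    glucose_standards <- tibble::tibble(
      concentration = glu_conc,
      absorbance = unname(noisy(cd["intercept"] + cd["slope"] * glu_conc,
                                spec$noise_sd[["dns"]])))
    lane_conc <- c(0.25, 0.5, 1)
    bsa_lanes <- tibble::tibble(
      concentration = lane_conc,
      area = unname(noisy(cg["intercept"] + cg["slope"] * lane_conc,
                          spec$noise_sd[["band_area"]])))
    background_A595 <- cb["slope"] * spec$background_conc
    structure(list(
      bradford = bradford, dns = dns, od600 = od600, mtt = mtt,
      band_area = band, bsa_standards = bsa_standards,
      glucose_standards = glucose_standards, bsa_lanes = bsa_lanes,
      background_A595 = unname(background_A595),
      background_area = unname(cg["slope"] * spec$background_conc),
      truth = spec
    ), class = "assay_tables")
  })
}

#' Discharge test fixtures with constructed truth
#'
#' `translating-pulse` returns a stack of electron-density snapshots in
#' which a Gaussian pulse moves at a stated velocity, for checking
#' ionization-front tracking; `uniform-0D` returns a spatially uniform
#' discharge state for chemistry-only comparisons.
#'
#' @param kind `"translating-pulse"` or `"uniform-0D"`.
#' @param velocity Pulse velocity, m/s (translating-pulse).
#' @param n_frames,dt Number of snapshots and frame spacing, s.
#' @param L,n_z Domain length (m) and number of grid points.
#' @param ne0 Density scale (m^-3); for uniform-0D, the uniform electron
#'   and He+ density.
#' @param Te0 Uniform electron temperature, eV (uniform-0D).
#' @return translating-pulse: a tibble (time_s, z_m, ne) with attribute
#'   `truth`; uniform-0D: a `discharge_state` (see [discharge_state()]).
#' @export
make_discharge_fixture <- function(kind = c("translating-pulse", "uniform-0D"),
                                   velocity = 1e5, n_frames = 8, dt = 1e-9,
                                   L = 1e-3, n_z = 201, ne0 = 1e18, Te0 = 2) {
  kind <- match.arg(kind)
  z <- seq(0, L, length.out = n_z)
  if (kind == "translating-pulse") {
    w <- L / 25
    frames <- purrr::map_dfr(seq_len(n_frames) - 1L, function(k) {
      c0 <- L / 5 + velocity * k * dt
      tibble::tibble(time_s = k * dt, z_m = z,
                     ne = ne0 * exp(-(z - c0)^2 / (2 * w^2)))
    })
    attr(frames, "truth") <- list(velocity = velocity, width = w)
    frames
  } else {
    discharge_state(
      z_m = z,
      densities = list(e = rep(ne0, n_z), `He*` = rep(0, n_z),
                       `He2*` = rep(0, n_z), `He+` = rep(ne0, n_z),
                       `He2+` = rep(0, n_z)),
      Te_eV = rep(Te0, n_z)
    )
  }
}
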