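#' Drive waveform
#'
#' The two power-supply modes of the jet: sinusoidal AC (default 4 kV
#' peak-to-peak at 20 kHz) and pulsed DC (default 10 kV amplitude at
#' 10 kHz, 2% duty cycle, i.e. on for 2 us of every 100 us).
#'
#' @param mode `"sinusoidal_AC"` or `"pulsed_DC"` (`"ac"`/`"dc"` accepted).
#' @param Vpp Peak-to-peak voltage for AC, V.
#' @param frequency Drive frequency, Hz (NULL = mode default: 20 kHz AC,
#'   10 kHz DC).
#' @param amplitude DC pulse amplitude, V.
#' @param duty Duty cycle fraction for pulsed DC.
#' @return A list of class `drive_waveform`.
#' @export
drive_waveform <- function(mode = c("sinusoidal_AC", "pulsed_DC", "ac", "dc"),
                           Vpp = 4000, frequency = NULL, amplitude = 10000,
                           duty = 0.02) {
  mode <- match.arg(mode)
  mode <- if (mode %in% c("ac", "sinusoidal_AC")) "sinusoidal_AC" else "pulsed_DC"
  if (is.null(frequency))
    frequency <- if (mode == "sinusoidal_AC") 20e3 else 10e3
  stopifnot(frequency > 0, duty > 0, duty <= 1, Vpp >= 0, amplitude >= 0)
  structure(list(mode = mode, Vpp = Vpp, frequency = frequency,
                 amplitude = amplitude, duty = duty),
            class = "drive_waveform")
}

#' Applied potential at time t
#'
#' AC: `(Vpp/2) sin(2 pi f t)`; pulsed DC: `amplitude` while
#' `t mod T < duty * T`, else 0.
#'
#' @param waveform A [drive_waveform()].
#' @param t Time(s), s (>= 0).
#' @return Applied potential(s), V.
#' @export
#' @examples
#' drive_voltage(drive_waveform("ac"), 1 / (4 * 20e3))   # 2000 V
#' drive_voltage(drive_waveform("dc"), c(1e-6, 50e-6))   # 10000, 0
drive_voltage <- function(waveform, t) {
  stopifnot(all(t >= 0))
  if (waveform$mode == "sinusoidal_AC") {
    (waveform$Vpp / 2) * sin(2 * pi * waveform$frequency * t)
  } else {
    Tp <- 1 / waveform$frequency
    ifelse((t %% Tp) < waveform$duty * Tp, waveform$amplitude, 0)
  }
}

#' Charged-species and metastable transport coefficients
#'
#' Mobilities and diffusivities in atmospheric-pressure helium at 300 K.
#' Electron diffusivity follows the Einstein relation with the local
#' electron temperature (`D_e = mu_e Te`), ion diffusivities the Einstein
#' relation at the gas temperature; metastables diffuse only.
#'
#' @param mu_e Electron mobility, m^2/(V s).
#' @param mu_He_ion,mu_He2_ion Ion mobilities, m^2/(V s).
#' @param D_He_star,D_He2_star Metastable/excimer diffusivities, m^2/s.
#' @return A list of class `transport_coefficients` with per-species
#'   vectors `mu`, `D`, thermal speeds and charge signs, ordered
#'   (e, He*, He2*, He+, He2+).
#' @export
transport_coefficients <- function(mu_e = 0.1132,
                                   mu_He_ion = 1.1e-3, mu_He2_ion = 1.8e-3,
                                   D_He_star = 6.2e-5, D_He2_star = 4.5e-5) {
  stopifnot(mu_e >= 0, mu_He_ion >= 0, mu_He2_ion >= 0,
            D_He_star >= 0, D_He2_star >= 0)
  Tg <- .const$Tg_eV
  structure(list(
    species = c("e", "He*", "He2*", "He+", "He2+"),
    mu = c(mu_e, 0, 0, mu_He_ion, mu_He2_ion),
    D = c(NA_real_, D_He_star, D_He2_star, mu_He_ion * Tg, mu_He2_ion * Tg),
    vth = c(NA_real_,
            sqrt(8 * 1.380649e-23 * 300 / (pi * .const$m_he)),
            sqrt(8 * 1.380649e-23 * 300 / (pi * 2 * .const$m_he)),
            sqrt(8 * 1.380649e-23 * 300 / (pi * .const$m_he)),
            sqrt(8 * 1.380649e-23 * 300 / (pi * 2 * .const$m_he))),
    z = c(-1L, 0L, 0L, 1L, 1L)
  ), class = "transport_coefficients")
}

# Rate tables for the kernel: log k on a log-spaced Te grid plus integer
# consumption/production matrices in kernel species order (e, He*, He2*,
# He+, He2+, He).
.chem_tables <- function(set = he_chemistry(), n_Te = 1500) {
  Te <- exp(seq(log(0.02), log(60), length.out = n_Te))
  nR <- nrow(set$reactions)
  K <- matrix(0, n_Te, nR)
  for (r in seq_len(nR)) K[, r] <- evaluate_rate(set$reactions[r, ], Te)
  sp <- c("e", "He*", "He2*", "He+", "He2+", "He")
  cons <- prodm <- matrix(0L, nR, 6)
  for (r in seq_len(nR)) {
    for (s in set$reactions$reactants[[r]])
      cons[r, match(s, sp)] <- cons[r, match(s, sp)] + 1L
    for (s in set$reactions$products[[r]])
      prodm[r, match(s, sp)] <- prodm[r, match(s, sp)] + 1L
  }
  list(Te = Te, K = K, cons = cons, prod = prodm,
       act = set$reactions$activation_eV)
}

#' Discharge state
#'
#' A gridded state of the 1D gap model: per-species densities, electron
#' temperature (stored as electron energy density `w = 3/2 ne Te`),
#' dielectric surface charge and time.
#'
#' @param z_m Axial node positions across the gas gap, m (uniform).
#' @param densities Named list of numeric vectors (m^-3) for
#'   `e`, `He*`, `He2*`, `He+`, `He2+`.
#' @param Te_eV Electron temperature per node, eV (scalar recycled).
#' @param sigma Dielectric surface charge density, C/m^2.
#' @param time_s State time, s.
#' @return A list of class `discharge_state`.
#' @export
discharge_state <- function(z_m, densities, Te_eV = 0.5, sigma = 0,
                            time_s = 0) {
  nz <- length(z_m)
  sp <- c("e", "He*", "He2*", "He+", "He2+")
  stopifnot(all(sp %in% names(densities)))
  n <- do.call(rbind, lapply(sp, function(s) {
    v <- rep_len(densities[[s]], nz)
    if (any(v < 0)) stop("negative density for ", s, call. = FALSE)
    v
  }))
  Te <- rep_len(Te_eV, nz)
  stopifnot(all(Te > 0))
  structure(list(z_m = z_m, n = n, species = sp,
                 w = 1.5 * n[1, ] * Te, sigma = sigma, time_s = time_s),
            class = "discharge_state")
}

#' @export
print.discharge_state <- function(x, ...) {
  cat("<discharge_state> t =", format(x$time_s, digits = 4), "s, ",
      length(x$z_m), "nodes; peak ne =",
      format(max(x$n[1, ]), digits = 3), "m^-3\n")
  invisible(x)
}

#' Electron temperature of a discharge state
#' @param state A `discharge_state`.
#' @return Te per node, eV.
#' @export
state_Te <- function(state) {
  ne <- state$n[1, ]
  ifelse(ne > 1e10, pmax(2 / 3 * state$w / ne, .const$Tg_eV), .const$Tg_eV)
}

#' Solve the 1D Poisson equation with dielectric and surface charge
#'
#' Finite-difference solve of `d/dz (eps dphi/dz) = -rho - sigma delta(z)`
#' on a uniform node grid with Dirichlet boundary potentials. Permittivity
#' is specified per face so a dielectric slab is a run of faces with
#' `eps_r > 1`; the jump in normal displacement across a node equals the
#' sheet charge placed there.
#'
#' @param rho Node charge density, C/m^3 (length `n`).
#' @param dx Node spacing, m.
#' @param V_left,V_right Boundary potentials, V.
#' @param eps_r Relative permittivity per face (length `n - 1`, scalar
#'   recycled).
#' @param sigma Sheet charge per node, C/m^2 (length `n`, scalar 0).
#' @return A tibble with `z_m`, `phi_V` and the face field `E_face` padded
#'   with NA at the last node.
#' @export
#' @examples
#' # zero charge between grounded plates: linear potential
#' solve_poisson(rep(0, 11), dx = 1e-4, V_left = 100, V_right = 0)
solve_poisson <- function(rho, dx, V_left = 0, V_right = 0, eps_r = 1,
                          sigma = 0) {
  n <- length(rho)
  stopifnot(n >= 3, dx > 0)
  eps_f <- rep_len(eps_r, n - 1) * .const$eps0
  sg <- rep_len(sigma, n)
  phi <- poisson1d_cpp(eps_f, rho, sg, dx, V_left, V_right)
  tibble::tibble(
    z_m = (seq_len(n) - 1) * dx,
    phi_V = as.numeric(phi),
    E_face = c(-diff(phi) / dx, NA_real_)
  )
}

# Local-field equilibrium electron temperature vs field strength: solves
# the per-electron power balance mu_e E^2 = elastic + inelastic collision
# losses using the package's own rate set. Used by the kernel as an upper
# limiter on Te (energy relaxation is ~ps at atmospheric pressure, so the
# transported Te cannot meaningfully exceed this equilibrium).
.Te_eq_table <- function(chemistry = he_chemistry(),
                         mu_e = 0.1132, n_E = 80) {
  E <- exp(seq(log(1e2), log(1e9), length.out = n_E))
  N <- .const$N_gas
  Tg <- .const$Tg_eV
  rx <- chemistry$reactions
  loss <- function(Te) {     # eV/s per electron
    3 * 1.3706e-4 * (Te - Tg) * evaluate_rate(rx[1, ], Te) * N +
      19.8 * evaluate_rate(rx[2, ], Te) * N +
      24.6 * evaluate_rate(rx[3, ], Te) * N
  }
  TeEq <- vapply(E, function(Ei) {
    gain <- mu_e * Ei^2
    lo <- Tg; hi <- 60
    if (loss(hi) < gain) return(hi)
    for (k in 1:60) {
      mid <- 0.5 * (lo + hi)
      if (loss(mid) < gain) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }, numeric(1))
  list(E = E, Te = TeEq)
}

# Shared kernel driver.
.run_kernel <- function(state, t_end, waveform = NULL, chemistry = he_chemistry(),
                        transport = transport_coefficients(),
                        dielectric_thickness = 0.5e-3, dielectric_eps_r = 3.8,
                        gamma_se = 0.05, background_ionization = 0,
                        rise_time = 2e-7,
                        dt_init = 1e-12, dt_min = 1e-14,
                        dt_max = 1e-9, rtol = 0.05, adapt = TRUE,
                        chemistry_on = TRUE, field_on = TRUE,
                        closed_boundaries = FALSE, freeze_energy = FALSE,
                        sample_dt = 0, snap_dt = 0, max_steps = 2e7) {
  z <- state$z_m
  N <- length(z) - 1L
  dx <- z[2] - z[1]
  Md <- if (field_on) max(1L, as.integer(round(dielectric_thickness / dx))) else 1L
  if (is.null(waveform)) {
    mode <- 0L; amp <- 0; freq <- 1e4; duty <- 1
  } else {
    mode <- if (waveform$mode == "sinusoidal_AC") 0L else 1L
    amp <- if (mode == 0L) waveform$Vpp / 2 else waveform$amplitude
    freq <- waveform$frequency; duty <- waveform$duty
  }
  tab <- .chem_tables(chemistry)
  teq <- .Te_eq_table(chemistry, mu_e = transport$mu[1])
  vth <- transport$vth; vth[1] <- 0
  res <- discharge_kernel(
    n0 = state$n, w0 = state$w, sigma0 = state$sigma,
    t0 = state$time_s, t_end = t_end, dt_init = dt_init,
    N = N, dx = dx, Md = Md, eps_r_d = dielectric_eps_r,
    mode = mode, amp = amp, freq = freq, duty = duty,
    t_rise = rise_time,
    TeTab = tab$Te, logKtab = tab$K,
    consM = tab$cons, prodM = tab$prod, act = tab$act,
    EeqTab = teq$E, TeEqTab = teq$Te,
    mu = transport$mu, difc = ifelse(is.na(transport$D), 0, transport$D),
    vth_heavy = ifelse(is.na(vth), 0, vth), zs = transport$z,
    gamma_se = gamma_se, N_gas = .const$N_gas, Tg_eV = .const$Tg_eV,
    S_bg = background_ionization,
    chem_on = chemistry_on, field_on = field_on,
    closed_bc = closed_boundaries, freeze_energy = freeze_energy,
    adapt = adapt, dt_min = dt_min, dt_max = dt_max, rtol = rtol,
    sample_dt = sample_dt, snap_dt = snap_dt, max_steps = max_steps)
  res
}

#' Advance a discharge state by one time interval
#'
#' Runs the implicit Scharfetter-Gummel / semi-implicit Poisson stepper
#' from the state's time over `dt`. With `closed_boundaries = TRUE` and
#' chemistry off, each species' total population is conserved to
#' round-off; the implicit scheme preserves nonnegativity.
#'
#' @param state A [discharge_state()].
#' @param dt Time interval, s.
#' @param waveform A [drive_waveform()] or NULL for no applied drive.
#' @param n_substeps Number of equal substeps (default 1; fixed dt, no
#'   adaptation).
#' @param chemistry,transport Reaction set and coefficients.
#' @param chemistry_on,field_on,closed_boundaries,freeze_energy Physics
#'   switches (freeze_energy holds Te at its initial per-node value).
#' @param ... Further arguments passed to the kernel driver (e.g.
#'   `dielectric_thickness`, `gamma_se`).
#' @return The advanced `discharge_state`.
#' @export
discharge_step <- function(state, dt, waveform = NULL, n_substeps = 1,
                           chemistry = he_chemistry(),
                           transport = transport_coefficients(),
                           chemistry_on = TRUE, field_on = !is.null(waveform),
                           closed_boundaries = FALSE, freeze_energy = FALSE,
                           ...) {
  stopifnot(dt > 0, n_substeps >= 1)
  h <- dt / n_substeps
  res <- .run_kernel(state, t_end = state$time_s + dt, waveform = waveform,
                     chemistry = chemistry, transport = transport,
                     dt_init = h, dt_min = h, dt_max = h, adapt = FALSE,
                     chemistry_on = chemistry_on, field_on = field_on,
                     closed_boundaries = closed_boundaries,
                     freeze_energy = freeze_energy, ...)
  out <- state
  out$n <- res$n; out$w <- as.numeric(res$w)
  out$sigma <- res$sigma; out$time_s <- res$t
  out
}

#' Run a full discharge simulation
#'
#' Integrates the reduced 1D gap model over `cycles` drive periods from a
#' uniform seed plasma (optionally with a seeded random perturbation) and
#' summarizes the final cycle. The model spans the actual DBD gap between
#' the powered rod (behind the quartz dielectric) and the grounded ring;
#' see the methods vignette for the geometry rationale.
#'
#' @param mode `"ac"` or `"dc"` (selects the default [drive_waveform()]).
#' @param cycles Number of drive periods to run (the last one is the
#'   measurement cycle).
#' @param duration Optional run length in seconds, overriding `cycles`;
#'   used for pulsed-DC runs where a window covering the on-phase and
#'   early afterglow stands in for the full period (see the vignette).
#' @param n_cells Number of gas-gap intervals.
#' @param gap_length Gas gap, m.
#' @param dielectric_thickness,dielectric_eps_r Quartz barrier, m / relative
#'   permittivity.
#' @param waveform Optional [drive_waveform()] overriding the mode default.
#' @param seed_density Initial uniform plasma density, m^-3.
#' @param seed_Te Initial electron temperature, eV.
#' @param perturbation Relative amplitude of the random seed perturbation.
#' @param seed Integer RNG seed for the perturbation (deterministic rerun).
#' @param gamma_se Secondary electron emission coefficient.
#' @param background_ionization Constant volumetric electron/ion production
#'   rate (m^-3 s^-1) representing residual pre-ionization between
#'   discharge events; keeps the afterglow seeded so re-ignition is
#'   gradual.
#' @param rtol Relative-change target of the adaptive time stepper.
#' @param samples_per_cycle,snapshots_per_cycle Recording rates.
#' @param max_steps Step budget before aborting with a diagnostic.
#' @param chemistry,transport Reaction set and transport coefficients.
#' @return An object of class `discharge_run`: list with `samples` and
#'   `snapshots` tibbles, the final `state`, the `summary` one-row tibble
#'   (peak/average ne, average Te full-period and on-time, front trace),
#'   and the configuration.
#' @export
run_discharge <- function(mode = c("ac", "dc"), cycles = 2, duration = NULL,
                          n_cells = 120,
                          gap_length = 1e-3, dielectric_thickness = 0.5e-3,
                          dielectric_eps_r = 3.8, waveform = NULL,
                          seed_density = 1e15, seed_Te = 0.5,
                          perturbation = 0.01, seed = 1L, gamma_se = 0.05,
                          background_ionization = 1e14,
                          rtol = 0.05, samples_per_cycle = 400,
                          snapshots_per_cycle = 40, max_steps = 2e7,
                          chemistry = he_chemistry(),
                          transport = transport_coefficients()) {
  mode <- match.arg(mode)
  if (is.null(waveform))
    waveform <- drive_waveform(if (mode == "ac") "sinusoidal_AC" else "pulsed_DC")
  period <- 1 / waveform$frequency
  if (is.null(duration)) {
    stopifnot(cycles >= 1)
    duration <- cycles * period
  }
  z <- seq(0, gap_length, length.out = n_cells + 1)
  ne0 <- rep(seed_density, n_cells + 1)
  if (perturbation > 0)
    ne0 <- .with_seed(seed, ne0 * (1 + perturbation * runif(n_cells + 1, -1, 1)))
  st <- discharge_state(z, densities = list(
    e = ne0, `He*` = rep(0, n_cells + 1), `He2*` = rep(0, n_cells + 1),
    `He+` = ne0, `He2+` = rep(0, n_cells + 1)), Te_eV = seed_Te)
  t_end <- duration
  res <- .run_kernel(st, t_end = t_end, waveform = waveform,
                     chemistry = chemistry, transport = transport,
                     dielectric_thickness = dielectric_thickness,
                     dielectric_eps_r = dielectric_eps_r,
                     gamma_se = gamma_se,
                     background_ionization = background_ionization,
                     rtol = rtol,
                     dt_max = period / 500,
                     sample_dt = period / samples_per_cycle,
                     snap_dt = period / snapshots_per_cycle,
                     max_steps = max_steps)
  if (!res$completed)
    warning("discharge run hit the step budget before t_end; ",
            "summary reflects the partial run", call. = FALSE)
  ns <- res$n_samples
  samples <- tibble::as_tibble(setNames(
    as.data.frame(res$samples[seq_len(ns), , drop = FALSE]),
    c("time_s", "applied_V", "peak_ne", "mean_ne", "mean_Te", "sigma_C_m2",
      "gap_voltage_V", "mean_He_star", "dt_s", "ens_Te")))
  nsn <- res$n_snaps
  snapmat <- res$snapshots[seq_len(nsn), , drop = FALSE]
  snapshots <- tibble::tibble(
    time_s = rep(res$snap_t[seq_len(nsn)], each = n_cells + 1),
    z_m = rep(z, nsn),
    ne = as.vector(t(snapmat)))
  final <- st
  final$n <- res$n; final$w <- as.numeric(res$w)
  final$sigma <- res$sigma; final$time_s <- res$t
  run <- structure(list(
    mode = mode, waveform = waveform, samples = samples,
    snapshots = snapshots, state = final,
    config = list(cycles = cycles, n_cells = n_cells,
                  gap_length = gap_length,
                  dielectric_thickness = dielectric_thickness,
                  dielectric_eps_r = dielectric_eps_r,
                  seed_density = seed_density, seed_Te = seed_Te,
                  perturbation = perturbation, seed = seed,
                  gamma_se = gamma_se, rtol = rtol),
    steps = res$steps, completed = res$completed
  ), class = "discharge_run")
  run$summary <- summarize_discharge(run)
  run
}

#' Final-cycle summary of a discharge run
#'
#' Statistics over the last full drive period: peak electron density (max
#' over space and the cycle), time-averaged volume-mean density, and
#' volume-mean electron temperature averaged over the full period and --
#' for pulsed drive -- over the on-time only (both averages are reported
#' because a 2% duty cycle makes them very different quantities).
#'
#' @param run A `discharge_run`.
#' @return A one-row tibble.
#' @export
summarize_discharge <- function(run) {
  period <- 1 / run$waveform$frequency
  t1 <- max(run$samples$time_s)
  window <- if (t1 >= period) period else t1
  fin <- dplyr::filter(run$samples, .data$time_s > t1 - window)
  on_win <- if (run$waveform$mode == "pulsed_DC") {
    ph <- fin$time_s %% period
    ph < run$waveform$duty * period
  } else rep(TRUE, nrow(fin))
  tibble::tibble(
    mode = run$mode,
    peak_ne = max(fin$peak_ne),
    avg_ne = mean(fin$mean_ne),
    avg_Te_full = mean(fin$ens_Te),
    avg_Te_cells = mean(fin$mean_Te),
    avg_Te_on = if (any(on_win)) mean(fin$ens_Te[on_win]) else NA_real_,
    peak_Te = max(fin$mean_Te),
    sigma_final = run$state$sigma,
    cycles = run$config$cycles,
    n_cells = run$config$n_cells
  )
}

#' @export
print.discharge_run <- function(x, ...) {
  s <- x$summary
  cat("<discharge_run> mode:", x$mode, " (", x$config$cycles, "cycles,",
      x$config$n_cells, "cells,", x$steps, "steps )\n")
  cat("  final-cycle peak ne :", format(s$peak_ne, digits = 3), "m^-3\n")
  cat("  final-cycle avg  ne :", format(s$avg_ne, digits = 3), "m^-3\n")
  cat("  avg Te (full period):", format(s$avg_Te_full, digits = 3), "eV\n")
  if (x$waveform$mode == "pulsed_DC")
    cat("  avg Te (on-time)    :", format(s$avg_Te_on, digits = 3), "eV\n")
  invisible(x)
}

#' @method glance discharge_run
#' @export
#' @importFrom generics glance
glance.discharge_run <- function(x, ...) x$summary

#' @method tidy discharge_run
#' @export
#' @importFrom generics tidy
tidy.discharge_run <- function(x, ...) x$samples

#' Track the ionization-front (plasma bullet) position
#'
#' For each snapshot, the front is the outermost axial position where the
#' electron density reaches `threshold` times the instantaneous spatial
#' peak; velocity follows by finite differences. An all-zero snapshot
#' yields a missing (NA) front rather than an error, and fronts at the
#' last grid node are flagged as clipped by the domain edge.
#'
#' @param snapshots Tibble with columns `time_s`, `z_m`, `ne` (as produced
#'   by [run_discharge()] or [make_discharge_fixture()]).
#' @param threshold Fraction of the instantaneous peak defining the front
#'   (in (0, 1); default 0.3).
#' @return A tibble with `time_s`, `front_z_m`, `front_velocity_m_s`,
#'   `clipped`.
#' @export
track_front <- function(snapshots, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1,
            all(c("time_s", "z_m", "ne") %in% names(snapshots)))
  times <- sort(unique(snapshots$time_s))
  if (length(times) < 2) stop("need at least 2 snapshots", call. = FALSE)
  if (is.unsorted(times)) stop("time stamps must be increasing", call. = FALSE)
  zmax <- max(snapshots$z_m)
  pos <- vapply(times, function(tt) {
    s <- snapshots[snapshots$time_s == tt, ]
    pk <- max(s$ne)
    if (pk <= 0) return(NA_real_)
    max(s$z_m[s$ne >= threshold * pk])
  }, numeric(1))
  vel <- rep(NA_real_, length(times))
  if (length(times) >= 2) {
    dtv <- diff(times)
    dzv <- diff(pos)
    vel[-1] <- dzv / dtv
    vel[1] <- vel[2]
  }
  tibble::tibble(time_s = times, front_z_m = pos,
                 front_velocity_m_s = vel,
                 clipped = !is.na(pos) & pos >= zmax - 1e-12)
}
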