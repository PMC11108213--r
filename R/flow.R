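#' Jet geometry
#'
#' Axisymmetric description of the DBD jet channel: a quartz tube housing a
#' coaxial rod electrode, a converging nozzle, and the free gap between
#' nozzle and target. The study fixes only the nozzle-to-target gap
#' (10 mm); the remaining dimensions default to values calibrated by
#' continuity so that 3 slm gives ~10 m/s mean outlet speed and ~15 m/s
#' peak speed in the annular channel beside the rod.
#'
#' @param tube_radius Tube inner radius, m.
#' @param rod_radius,rod_length Rod electrode radius and axial extent, m.
#' @param channel_length Length of the tube section, m.
#' @param nozzle_radius,nozzle_length Nozzle exit radius and taper length, m.
#' @param gap Nozzle-to-target distance, m (default 10 mm).
#' @param spread_half_angle_deg Free-jet spreading half-angle, degrees.
#' @return A list of class `jet_geometry`.
#' @export
jet_geometry <- function(tube_radius = 1.4e-3, rod_radius = 0.6e-3,
                         rod_length = 40e-3, channel_length = 50e-3,
                         nozzle_radius = 1.26e-3, nozzle_length = 5e-3,
                         gap = 10e-3, spread_half_angle_deg = 3) {
  stopifnot(rod_radius < tube_radius, nozzle_radius <= tube_radius,
            tube_radius > 0, rod_radius > 0, rod_length > 0,
            channel_length > rod_length, nozzle_length > 0, gap > 0)
  structure(list(tube_radius = tube_radius, rod_radius = rod_radius,
                 rod_length = rod_length, channel_length = channel_length,
                 nozzle_radius = nozzle_radius, nozzle_length = nozzle_length,
                 gap = gap, spread_half_angle_deg = spread_half_angle_deg),
            class = "jet_geometry")
}

#' Flow configuration
#'
#' @param slm Volumetric flow rate, standard litres per minute (default 3).
#' @param density Gas density, kg/m^3 (helium at 300 K, 1 atm).
#' @param viscosity Dynamic viscosity, Pa s (helium at 300 K).
#' @return A list of class `flow_config` with the derived `Q_m3s`.
#' @export
flow_config <- function(slm = 3, density = 0.1625, viscosity = 1.99e-5) {
  stopifnot(slm >= 0, density > 0, viscosity > 0)
  structure(list(slm = slm, Q_m3s = slm * 1e-3 / 60,
                 density = density, viscosity = viscosity),
            class = "flow_config")
}

# Fully developed axial Stokes profile on [ri, ro] for unit pressure
# forcing: u'' + u'/r = -1 with no-slip at ro and at ri (annulus) or
# symmetry at r = 0 (pipe). Tridiagonal finite differences.
.station_profile <- function(ri, ro, n_r) {
  if (ri > 0) {
    r <- seq(ri, ro, length.out = n_r)
    dr <- r[2] - r[1]
    m <- n_r - 2L
    a <- b <- cc <- d <- numeric(m)
    for (k in seq_len(m)) {
      rj <- r[k + 1]
      a[k]  <- 1 / dr^2 - 1 / (2 * rj * dr)
      b[k]  <- -2 / dr^2
      cc[k] <- 1 / dr^2 + 1 / (2 * rj * dr)
      d[k]  <- -1
    }
    u <- c(0, .thomas(a, b, cc, d), 0)
  } else {
    r <- seq(0, ro, length.out = n_r)
    dr <- r[2] - r[1]
    m <- n_r - 1L                      # unknowns j = 0..n_r-2 (u = 0 at ro)
    a <- b <- cc <- d <- numeric(m)
    b[1] <- -4 / dr^2; cc[1] <- 4 / dr^2; d[1] <- -1   # r = 0: 2 u'' = -1
    for (k in 2:m) {
      rj <- r[k]
      a[k]  <- 1 / dr^2 - 1 / (2 * rj * dr)
      b[k]  <- -2 / dr^2
      cc[k] <- 1 / dr^2 + 1 / (2 * rj * dr)
      d[k]  <- -1
    }
    u <- c(.thomas(a[-1], b, cc[-m], d), 0)
  }
  list(r = r, u = u)
}

.thomas <- function(a, b, cc, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
  if (n > 1) for (i in 2:n) {
    den <- b[i] - a[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) cc[i] / den else 0
    dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / den
  }
  x <- numeric(n); x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

.trap_flux <- function(r, u) {   # 2 pi int u r dr
  2 * pi * sum(diff(r) * (head(r * u, -1) + tail(r * u, -1)) / 2)
}

#' Solve the steady laminar jet flow
#'
#' Locally-fully-developed reduction of the steady incompressible
#' axisymmetric Navier-Stokes problem: at each axial station the radial
#' Stokes profile is solved by finite differences on the local annulus or
#' pipe cross-section and scaled so the volumetric flux equals the inlet
#' flux exactly (continuity); in the free gap the exit profile is
#' stretched over the spreading jet radius, so speed falls as the jet
#' cross-section expands. Radial velocity follows from discrete
#' continuity and pressure from the integrated axial gradient.
#'
#' @param geometry A [jet_geometry()].
#' @param config A [flow_config()].
#' @param n_r,n_z Radial and axial grid sizes.
#' @return A `flow_field`: tibble (z_m, r_m, u_z, u_r, p_Pa) with geometry,
#'   config and per-station metadata in attributes.
#' @export
#' @examples
#' field <- solve_flow(jet_geometry(), flow_config())
#' summarize_flow(field)
solve_flow <- function(geometry, config, n_r = 61, n_z = 81) {
  g <- geometry; Q <- config$Q_m3s
  z_exit <- g$channel_length + g$nozzle_length
  z_end <- z_exit + g$gap
  z <- sort(unique(c(seq(0, z_end, length.out = n_z),
                     g$rod_length, g$channel_length, z_exit)))
  tanth <- tan(g$spread_half_angle_deg * pi / 180)
  bounds <- function(zi) {
    if (zi <= g$rod_length) c(g$rod_radius, g$tube_radius)
    else if (zi <= g$channel_length) c(0, g$tube_radius)
    else if (zi <= z_exit) {
      f <- (zi - g$channel_length) / g$nozzle_length
      c(0, g$tube_radius + f * (g$nozzle_radius - g$tube_radius))
    } else c(0, g$nozzle_radius + (zi - z_exit) * tanth)
  }
  # reference exit profile shape for the free-jet stretch
  exit_prof <- .station_profile(0, g$nozzle_radius, n_r)
  exit_shape <- exit_prof$u / max(exit_prof$u)
  r_max <- max(g$tube_radius, bounds(z_end)[2])
  r_out <- seq(0, r_max, length.out = n_r)
  u_mat <- matrix(0, length(z), n_r)
  dpdz <- numeric(length(z))
  stations <- vector("list", length(z))
  for (i in seq_along(z)) {
    b <- bounds(z[i]); ri <- b[1]; ro <- b[2]
    if (Q == 0) { stations[[i]] <- list(ri = ri, ro = ro); next }
    if (z[i] <= z_exit) {
      pr <- .station_profile(ri, ro, n_r)
      fx <- .trap_flux(pr$r, pr$u)
      cscale <- Q / fx
      u <- pr$u * cscale
      dpdz[i] <- -config$viscosity * cscale
      r_loc <- pr$r
    } else {
      r_loc <- seq(0, ro, length.out = n_r)
      shape <- approx(exit_prof$r / g$nozzle_radius, exit_shape,
                      xout = r_loc / ro, rule = 2)$y
      fx <- .trap_flux(r_loc, shape)
      u <- shape * Q / fx
      dpdz[i] <- 0
    }
    u_mat[i, ] <- approx(r_loc, u, xout = r_out, yleft = 0, yright = 0,
                         rule = 2)$y
    u_mat[i, r_out < ri | r_out > ro] <- 0
    stations[[i]] <- list(ri = ri, ro = ro, flux = Q, peak = max(u))
  }
  # pressure by backward integration from the domain end (gauge 0)
  p <- rev(cumsum(rev(c(dpdz[-1] * diff(z), 0)))) * -1
  p <- p - p[length(p)]
  # radial velocity from discrete continuity:
  # u_r(r) = -(1/r) int_0^r r' du_z/dz dr'
  dudz <- u_mat
  dudz[1, ] <- (u_mat[2, ] - u_mat[1, ]) / (z[2] - z[1])
  nzz <- length(z)
  dudz[nzz, ] <- (u_mat[nzz, ] - u_mat[nzz - 1, ]) / (z[nzz] - z[nzz - 1])
  for (i in 2:(nzz - 1))
    dudz[i, ] <- (u_mat[i + 1, ] - u_mat[i - 1, ]) / (z[i + 1] - z[i - 1])
  ur_mat <- matrix(0, nzz, n_r)
  dr <- r_out[2] - r_out[1]
  for (i in seq_len(nzz)) {
    integ <- cumsum(c(0, (r_out[-1] * dudz[i, -1] +
                          head(r_out, -1) * head(dudz[i, ], -1)) / 2 * dr))
    ur_mat[i, -1] <- -integ[-1] / r_out[-1]
  }
  out <- tibble::tibble(
    z_m = rep(z, each = n_r), r_m = rep(r_out, length(z)),
    u_z = as.vector(t(u_mat)), u_r = as.vector(t(ur_mat)),
    p_Pa = rep(p, each = n_r)
  )
  class(out) <- c("flow_field", class(out))
  attr(out, "geometry") <- g
  attr(out, "config") <- config
  attr(out, "z_outlet") <- z_exit
  attr(out, "stations") <- tibble::tibble(
    z_m = z,
    ri = vapply(stations, function(s) s$ri, numeric(1)),
    ro = vapply(stations, function(s) s$ro, numeric(1))
  )
  out
}

#' Summary statistics of a flow field
#'
#' @param field A `flow_field` (from [solve_flow()] or built directly; the
#'   outlet is taken at the `z_outlet` attribute, else at the largest z).
#' @return A one-row tibble: peak channel speed, mean and peak outlet
#'   speed (m/s), outlet Reynolds number, laminar flag.
#' @export
summarize_flow <- function(field) {
  g <- attr(field, "geometry"); cfg <- attr(field, "config")
  z_out <- attr(field, "z_outlet")
  if (is.null(z_out)) z_out <- max(field$z_m)
  zs <- unique(field$z_m)
  z_sta <- zs[which.min(abs(zs - z_out))]
  st <- field[field$z_m == z_sta, ]
  sel <- st$u_z > 0
  if (any(sel)) {
    r_edge <- if (!is.null(g)) g$nozzle_radius else max(st$r_m[sel])
    flux <- .trap_flux(st$r_m, st$u_z)
    mean_out <- flux / (pi * r_edge^2)
  } else mean_out <- 0
  peak_out <- max(st$u_z)
  z_chan <- if (!is.null(g)) g$rod_length else max(field$z_m)
  peak_chan <- max(field$u_z[field$z_m <= z_chan])
  re <- if (!is.null(cfg) && !is.null(g))
    cfg$density * mean_out * 2 * g$nozzle_radius / cfg$viscosity
  else NA_real_
  tibble::tibble(
    peak_channel_speed = peak_chan,
    mean_outlet_speed = mean_out,
    peak_outlet_speed = peak_out,
    reynolds_outlet = re,
    laminar = (is.na(re) || re < 2300) && all(field$u_z >= -1e-12)
  )
}
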