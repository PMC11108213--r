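# Closed-form annular Poiseuille profile (unit pressure-gradient shape),
# the analytic oracle for the radial solver.
.annulus_exact <- function(r, ri, ro) {
  (ro^2 - r^2 + (ro^2 - ri^2) * log(r / ro) / log(ro / ri)) / 4
}

test_that("outlet mean speed equals Q / A by continuity", {
  g <- jet_geometry(); cfg <- flow_config(slm = 3)
  fld <- solve_flow(g, cfg)
  s <- summarize_flow(fld)
  expect_equal(s$mean_outlet_speed,
               cfg$Q_m3s / (pi * g$nozzle_radius^2), tolerance = 0.01)
  # the jet is laminar at 3 slm
  expect_lt(s$reynolds_outlet, 2300)
  expect_true(s$laminar)
})

test_that("straight-pipe sections recover the Poiseuille profile", {
  g <- jet_geometry(); cfg <- flow_config(slm = 3)
  fld <- solve_flow(g, cfg, n_r = 101)
  # a station in the open-tube region (past the rod, before the nozzle)
  zs <- unique(fld$z_m)
  z0 <- zs[which.min(abs(zs - (g$rod_length + g$channel_length) / 2))]
  st <- fld[fld$z_m == z0 & fld$r_m <= g$tube_radius, ]
  mean_u <- cfg$Q_m3s / (pi * g$tube_radius^2)
  expect_equal(max(st$u_z), 2 * mean_u, tolerance = 0.01)
})

test_that("annular channel matches the closed-form annulus to <1% L2 error", {
  g <- jet_geometry(); cfg <- flow_config(slm = 3)
  fld <- solve_flow(g, cfg, n_r = 101)
  zs <- unique(fld$z_m)
  z0 <- zs[which.min(abs(zs - g$rod_length / 2))]
  st <- fld[fld$z_m == z0, ]
  sel <- st$r_m > g$rod_radius & st$r_m < g$tube_radius
  r <- st$r_m[sel]; u <- st$u_z[sel]
  ex <- .annulus_exact(r, g$rod_radius, g$tube_radius)
  # normalize the exact shape to the same volumetric flux
  flux <- function(rr, uu) 2 * pi * sum(diff(rr) * (head(rr * uu, -1) +
                                                    tail(rr * uu, -1)) / 2)
  ex <- ex * flux(r, u) / flux(r, ex)
  l2 <- sqrt(sum((u - ex)^2) / sum(ex^2))
  expect_lt(l2, 0.01)
})

test_that("mass flux is conserved along the channel", {
  g <- jet_geometry(); cfg <- flow_config(slm = 3)
  fld <- solve_flow(g, cfg, n_r = 161)
  flux_at <- function(z0) {
    zs <- unique(fld$z_m)
    st <- fld[fld$z_m == zs[which.min(abs(zs - z0))], ]
    2 * pi * sum(diff(st$r_m) * (head(st$r_m * st$u_z, -1) +
                                 tail(st$r_m * st$u_z, -1)) / 2)
  }
  for (z0 in c(g$rod_length / 2, (g$rod_length + g$channel_length) / 2,
               g$channel_length + g$nozzle_length))
    expect_equal(flux_at(z0), cfg$Q_m3s, tolerance = 0.01)
})

test_that("speed falls as the free jet expands and summaries behave", {
  g <- jet_geometry(spread_half_angle_deg = 4)
  fld <- solve_flow(g, flow_config(slm = 3))
  z_exit <- g$channel_length + g$nozzle_length
  peak_at <- function(z0) {
    zs <- unique(fld$z_m)
    max(fld$u_z[fld$z_m == zs[which.min(abs(zs - z0))]])
  }
  expect_gt(peak_at(z_exit), peak_at(z_exit + 0.9 * g$gap))

  # uniform plug flow: peak equals mean
  plug <- tibble::tibble(
    z_m = rep(c(0, 1e-3), each = 50),
    r_m = rep(seq(0, 1e-3, length.out = 50), 2),
    u_z = 5, u_r = 0, p_Pa = 0)
  class(plug) <- c("flow_field", class(plug))
  sp <- summarize_flow(plug)
  expect_equal(sp$peak_outlet_speed, sp$mean_outlet_speed, tolerance = 1e-6)

  # zero flow gives an all-zero field
  f0 <- solve_flow(jet_geometry(), flow_config(slm = 0))
  expect_true(all(f0$u_z == 0))
  expect_equal(summarize_flow(f0)$mean_outlet_speed, 0)
})

test_that("radial velocity satisfies the discrete continuity construction", {
  fld <- solve_flow(jet_geometry(), flow_config(slm = 3))
  # u_r vanishes on the axis and is finite everywhere
  expect_true(all(is.finite(fld$u_r)))
  expect_true(all(fld$u_r[fld$r_m == 0] == 0))
})
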