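test_that("drive voltage follows the catalogued waveforms", {
  ac <- drive_waveform("ac")
  expect_equal(drive_voltage(ac, 0), 0)
  expect_equal(drive_voltage(ac, 1 / (4 * 20e3)), 2000)   # half of 4 kV pk-pk
  dc <- drive_waveform("dc")
  expect_equal(drive_voltage(dc, 1e-6), 10000)   # inside the 2% duty window
  expect_equal(drive_voltage(dc, 50e-6), 0)
  expect_equal(drive_voltage(dc, 101e-6), 10000) # periodicity
  expect_error(drive_waveform("ac", duty = 0))
})

test_that("Poisson solves match electrostatic closed forms", {
  # zero space charge between plates: linear potential
  ps <- solve_poisson(rep(0, 21), dx = 1e-4, V_left = 100, V_right = 0)
  expect_equal(ps$phi_V, seq(100, 0, length.out = 21), tolerance = 1e-9)

  # uniform charge slab between grounded plates: quadratic profile
  rho <- 1e-6; n <- 41; dx <- 5e-5; L <- (n - 1) * dx
  ps2 <- solve_poisson(rep(rho, n), dx = dx)
  z <- ps2$z_m
  analytic <- rho / (2 * 8.8541878128e-12) * z * (L - z)
  expect_equal(ps2$phi_V, analytic, tolerance = 1e-9)

  # dielectric half-gap: field ratio is the inverse permittivity ratio
  ps3 <- solve_poisson(rep(0, 21), dx = 1e-4, V_left = 100,
                       eps_r = c(rep(4, 10), rep(1, 10)))
  expect_equal(ps3$E_face[15] / ps3$E_face[5], 4, tolerance = 1e-9)

  # surface charge: jump in normal displacement at the sheet
  sg <- rep(0, 21); sg[11] <- 1e-6
  ps4 <- solve_poisson(rep(0, 21), dx = 1e-4, sigma = sg)
  eps0 <- 8.8541878128e-12
  jump <- eps0 * (ps4$E_face[12] - ps4$E_face[9])
  expect_equal(jump, 1e-6, tolerance = 1e-6 * 1e-6)
})

test_that("a uniform field-free state is stationary and conservative", {
  st <- uniform_state(ne = 1e16)
  # chemistry off, closed boundaries: nothing changes, populations conserved
  st2 <- discharge_step(st, 1e-9, n_substeps = 5, chemistry_on = FALSE,
                        field_on = FALSE, closed_boundaries = TRUE,
                        freeze_energy = TRUE)
  expect_equal(max(abs(st2$n - st$n)) / max(st$n), 0, tolerance = 1e-12)
  for (s in seq_len(nrow(st$n)))
    expect_equal(sum(st2$n[s, ]), sum(st$n[s, ]), tolerance = 1e-12)

  # chemistry on: still spatially uniform, totals change only via chemistry
  st3 <- discharge_step(st, 1e-9, n_substeps = 5, chemistry_on = TRUE,
                        field_on = FALSE, closed_boundaries = TRUE,
                        freeze_energy = TRUE)
  expect_lt(diff(range(st3$n[1, ])) / max(st3$n[1, ]), 1e-12)
})

test_that("0D chemistry in the stepper agrees with an independent ODE oracle", {
  ch <- he_chemistry()
  sp <- he_species()$name
  Te0 <- 2
  st <- uniform_state(n_z = 31, ne = 1e16, Te = Te0)

  # independent route: lsoda on the analytic source terms at fixed Te
  deriv <- function(t, y, p) {
    n <- setNames(pmax(y, 0), sp)
    d <- source_terms(ch, n, Te = Te0)$rate
    d[sp == "He"] <- 0
    list(d)
  }
  y0 <- setNames(c(1e16, 0, 0, 1e16, 0, 2.446e25),
                 c("e", "He*", "He2*", "He+", "He2+", "He"))
  y0 <- y0[sp]
  ref <- deSolve::lsoda(y0, c(0, 1e-7), deriv, NULL, rtol = 1e-8)
  ref <- ref[2, -1]

  st2 <- discharge_step(st, 1e-7, n_substeps = 1000, chemistry_on = TRUE,
                        field_on = FALSE, closed_boundaries = TRUE,
                        freeze_energy = TRUE)
  got <- st2$n[, 16]   # any interior node (state stays uniform)
  names(got) <- c("e", "He*", "He2*", "He+", "He2+")
  for (s in names(got)) {
    if (ref[[s]] > 1e8)
      expect_equal(got[[s]], ref[[s]], tolerance = 0.01)
  }
})

test_that("front tracking recovers constructed bullet kinematics", {
  # identical snapshots: zero velocity
  z <- seq(0, 1e-3, length.out = 101)
  one <- tibble::tibble(z_m = z, ne = exp(-(z - 3e-4)^2 / 1e-9))
  snaps <- dplyr::bind_rows(
    dplyr::mutate(one, time_s = 0), dplyr::mutate(one, time_s = 1e-9))
  fr <- track_front(snaps)
  expect_equal(fr$front_velocity_m_s, c(0, 0))

  # translating pulse: velocity recovered exactly on a commensurate grid
  fx <- make_discharge_fixture("translating-pulse", velocity = 1e5)
  fr2 <- track_front(fx)
  expect_equal(fr2$front_velocity_m_s[-1],
               rep(1e5, length(fr2$front_velocity_m_s) - 1),
               tolerance = 1e-10)

  # all-zero snapshot reports a missing front, not an error
  snaps0 <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, z_m = z, ne = 0),
    tibble::tibble(time_s = 1e-9, z_m = z, ne = 0))
  expect_true(all(is.na(track_front(snaps0)$front_z_m)))

  # pulse at the domain edge is flagged as clipped
  fx3 <- make_discharge_fixture("translating-pulse", velocity = 1e5,
                                n_frames = 12, dt = 1e-9)
  fr3 <- track_front(fx3)
  expect_true(any(fr3$clipped))
  expect_error(track_front(fx[fx$time_s == 0, ]), "2 snapshots")
})

test_that("discharge runs are deterministic given the seed", {
  r1 <- suppressWarnings(run_discharge("ac", duration = 4e-6, n_cells = 60,
                                       seed = 7L, max_steps = 3e6))
  r2 <- suppressWarnings(run_discharge("ac", duration = 4e-6, n_cells = 60,
                                       seed = 7L, max_steps = 3e6))
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$state$n, r2$state$n)
  r3 <- suppressWarnings(run_discharge("ac", duration = 4e-6, n_cells = 60,
                                       seed = 8L, max_steps = 3e6))
  expect_false(identical(r1$state$n, r3$state$n))
})

test_that("zero-amplitude drive lets the seed plasma decay", {
  wf <- drive_waveform("ac", Vpp = 0)
  run <- suppressWarnings(run_discharge("ac", duration = 5e-6, n_cells = 60,
                                        waveform = wf, perturbation = 0,
                                        background_ionization = 0,
                                        max_steps = 3e6))
  s <- run$samples
  # ambipolar decay is slow (~ms) but wall losses reduce the average and
  # the electron temperature relaxes to the gas floor within the window
  expect_lt(dplyr::last(s$mean_ne), s$mean_ne[1])
  expect_lt(dplyr::last(s$peak_ne), 1.1 * max(s$peak_ne))
  expect_lt(dplyr::last(s$mean_Te), 0.1)
})
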