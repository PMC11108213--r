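# Independent inversion of the Boltzmann line-ratio relation, written
# directly from the printed constants (oracle for estimate_Te).
.oracle_Te_ratio <- function(Te) {
  C1 <- (1.8299e7 * 1 * 706.5) / (1.5474e7 * 3 * 728.1)
  exp((22.9203 - 22.7185) / Te) / C1
}

# Independent Saha-Boltzmann arithmetic (oracle for estimate_ne), m^-3.
.oracle_ne <- function(r357, Te) {
  me <- 9.1093837015e-31; h <- 6.62607015e-34; e <- 1.602176634e-19
  saha <- 2 * (2 * pi * me * Te * e)^1.5 / h^3
  C2 <- (1.14e7 * 1 * 357.6) / (8.84e6 * 1 * 391.1)
  saha * C2 * r357 * exp(-(15.58 - 3.16 + 11.05) / Te)
}

test_that("line integration recovers closed-form Gaussian areas", {
  wl <- seq(500, 520, by = 0.01)
  flat <- spectrum_trace(wl, rep(7, length(wl)))
  expect_equal(integrate_line(flat, 510, 1), 0, tolerance = 1e-10)

  a <- 120; s <- 0.15
  g <- a * exp(-(wl - 510)^2 / (2 * s^2))
  tr <- spectrum_trace(wl, g)
  area <- integrate_line(tr, 510, 4 * s)
  expect_equal(area, a * s * sqrt(2 * pi), tolerance = 0.005)

  # baseline invariance: same Gaussian on a linear ramp
  tr2 <- spectrum_trace(wl, g + 40 + 3 * (wl - 500))
  expect_equal(integrate_line(tr2, 510, 4 * s), a * s * sqrt(2 * pi),
               tolerance = 0.01)

  # peak-height mode
  expect_equal(integrate_line(tr2, 510, 4 * s, mode = "height"), a,
               tolerance = 0.01)

  expect_error(integrate_line(tr, 499, 2), "outside")
})

test_that("electron temperature estimate matches independent inversion", {
  # anchor: the ratio that the printed constants map to 1.4851 eV
  r <- .oracle_Te_ratio(1.4851)
  expect_equal(r, 2.995, tolerance = 2e-4)
  expect_equal(estimate_Te(I_706 = r, I_728 = 1), 1.4851, tolerance = 1e-4)
  # scale invariance
  expect_equal(estimate_Te(10 * r, 10), estimate_Te(r, 1))
  # round trip across a Te grid, 4 significant figures
  for (Te in c(0.8, 1.2, 1.4851, 2, 3))
    expect_equal(estimate_Te(.oracle_Te_ratio(Te), 1), Te,
                 tolerance = 5e-5)
  # errors for non-physical ratios
  expect_error(estimate_Te(1, 1), "non-physical")
  expect_error(estimate_Te(-1, 1), "positive")
})

test_that("Te is strictly increasing in the singlet/triplet intensity ratio", {
  # hotter plasmas populate the higher (728.1 nm) level more strongly
  ratios_728_706 <- seq(0.15, 0.36, length.out = 30)  # valid domain
  Te <- vapply(ratios_728_706, function(r) estimate_Te(1, r), numeric(1))
  expect_true(all(diff(Te) > 0))
})

test_that("electron density estimate matches independent Saha arithmetic", {
  got <- estimate_ne(I_357 = 0.0567, I_391 = 1, Te = 1.4851)
  expect_equal(got, .oracle_ne(0.0567, 1.4851), tolerance = 1e-10)
  expect_equal(got / 1e6, 1e14, tolerance = 0.01)   # the anchor, cm^-3
  # linearity in the intensity ratio
  expect_equal(estimate_ne(2 * 0.0567, 1, 1.4851), 2 * got)
  # continuity in Te
  Te <- seq(1, 2, length.out = 100)
  ne <- vapply(Te, function(x) estimate_ne(0.0567, 1, x), numeric(1))
  expect_true(all(abs(diff(log(ne))) < 0.3))
  expect_error(estimate_ne(1, 1, Te = 0), "positive")
})

test_that("full-spectrum diagnosis inverts synthetic truth", {
  tr <- make_spectrum(spectrum_spec(noise_sd = 0, baseline_level = 0,
                                    baseline_slope = 0))
  d <- diagnose_spectrum(tr)
  expect_equal(d$Te_eV, 1.4851, tolerance = 1e-3)
  expect_equal(d$ne_cm3, 1e14, tolerance = 5e-3)
  expect_false(d$ne_missing)
  expect_s3_class(generics::tidy(d), "tbl_df")

  # truncated trace: Te-only partial result, ne flagged missing
  keep <- tr$wavelength_nm > 450
  tr2 <- spectrum_trace(tr$wavelength_nm[keep], tr$intensity[keep])
  d2 <- diagnose_spectrum(tr2)
  expect_true(d2$ne_missing)
  expect_true(is.na(d2$ne_m3))
  expect_equal(d2$Te_eV, 1.4851, tolerance = 1e-3)

  # missing He windows cannot be diagnosed at all
  keep <- tr$wavelength_nm < 600
  expect_error(diagnose_spectrum(
    spectrum_trace(tr$wavelength_nm[keep], tr$intensity[keep])), "He I")
})

test_that("round-trip identity holds over the (Te, ne) plane", {
  for (Te in c(0.6, 1, 1.5, 2.2, 3)) {
    for (ne in c(1e12, 1e14, 1e16)) {
      tr <- make_spectrum(spectrum_spec(Te_eV = Te, ne_cm3 = ne,
                                        noise_sd = 0))
      d <- diagnose_spectrum(tr)
      expect_equal(d$Te_eV, Te, tolerance = 0.005)
      expect_equal(d$ne_cm3, ne, tolerance = 0.02)
    }
  }
})
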