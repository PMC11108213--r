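test_that("rate coefficients evaluate as catalogued", {
  ch <- he_chemistry()
  rx <- function(idx) ch$reactions[ch$reactions$index == idx, ]

  # constant forms are Te independent
  for (Te in c(0.5, 1, 3, 10))
    expect_equal(evaluate_rate(rx("R14"), Te), 9e-15)
  expect_equal(evaluate_rate(rx("R8"), 2), 1e-43)

  # unit power at Te = 1 eV
  expect_equal(evaluate_rate(rx("R11"), 1), 5.12e-39)

  # power-exponential form, direct arithmetic oracle
  expect_equal(evaluate_rate(rx("R5"), 1), 1.268e-18 * exp(-3.4),
               tolerance = 1e-12)
  expect_equal(evaluate_rate(rx("R5"), 2.5),
               1.268e-18 * 2.5^0.71 * exp(-3.4 / 2.5), tolerance = 1e-12)

  # domain errors
  expect_error(evaluate_rate(rx("R5"), 0), "positive")
  expect_error(evaluate_rate(rx("R5"), -1), "positive")
  bad <- rx("R1"); bad$table <- list(list(Te = numeric(0), k = numeric(0)))
  expect_error(evaluate_rate(bad, 1), "empty table")
})

test_that("evaluate_rate is continuous in Te and tabulated forms are monotone", {
  ch <- he_chemistry()
  # continuity: refining the grid shrinks the largest log-step
  step_max <- function(n) {
    Te <- seq(0.3, 20, length.out = n)
    max(abs(diff(log(evaluate_rate(ch$reactions[5, ], Te)))))
  }
  expect_lt(step_max(801), 0.55 * step_max(401))
  Te <- seq(0.3, 20, length.out = 400)
  # electron-impact tables: monotone increasing over the thermal range
  for (i in 2:4) {
    k <- evaluate_rate(ch$reactions[i, ], Te)
    expect_true(all(diff(k) > 0))
  }
})

test_that("every reaction conserves charge and helium nuclei", {
  ch <- he_chemistry()
  expect_silent(validate_chemistry(ch))
  sp <- he_species()
  chg <- setNames(sp$charge, sp$name)
  nuc <- setNames(sp$helium_nuclei, sp$name)
  orc <- oracle_stoich()
  expect_equal(nrow(ch$reactions), 14L)
  for (i in seq_len(14)) {
    o <- orc$reactions[[i]]
    expect_equal(sum(chg[o$re]), sum(chg[o$pr]), info = names(orc$reactions)[i])
    expect_equal(sum(nuc[o$re]), sum(nuc[o$pr]), info = names(orc$reactions)[i])
    # the package's reaction list agrees with the hand-written stoichiometry
    expect_equal(sort(ch$reactions$reactants[[i]]), sort(o$re))
    expect_equal(sort(ch$reactions$products[[i]]), sort(o$pr))
  }
})

test_that("source terms match a brute-force oracle and conserve invariants", {
  ch <- he_chemistry()
  sp <- he_species()
  orc <- oracle_stoich()
  set.seed(42)
  for (rep in 1:5) {
    n <- setNames(10^runif(6, 12, 19), sp$name)
    n["He"] <- 2.45e25
    Te <- runif(1, 0.5, 5)
    got <- source_terms(ch, n, Te)
    # brute force: loop the hand-written reaction list
    want <- setNames(numeric(6), sp$name)
    for (i in seq_len(14)) {
      k <- evaluate_rate(ch$reactions[i, ], Te)
      o <- orc$reactions[[i]]
      rate <- k * prod(n[o$re])
      for (s in o$re) want[s] <- want[s] - rate
      for (s in o$pr) want[s] <- want[s] + rate
    }
    expect_equal(got$rate, unname(want[got$species]), tolerance = 1e-12)
    scale <- max(abs(got$rate))
    expect_lt(abs(sum(got$rate * sp$charge[match(got$species, sp$name)])),
              1e-10 * scale)
    expect_lt(abs(sum(got$rate * sp$helium_nuclei[match(got$species, sp$name)])),
              1e-10 * scale)
  }
  # degenerate inputs
  zero <- setNames(rep(0, 6), sp$name)
  expect_true(all(source_terms(ch, zero, 2)$rate == 0))
  neg <- zero; neg["e"] <- -1
  expect_error(source_terms(ch, neg, 2), "negative")
})

test_that("only ionization active gives matched electron and ion production", {
  ch <- he_chemistry()
  n <- setNames(rep(0, 6), he_species()$name)
  n["e"] <- 1e15; n["He"] <- 2.45e25
  st <- source_terms(ch, n, Te = 3)
  de <- st$rate[st$species == "e"]
  dip <- st$rate[st$species == "He+"]
  dm <- st$rate[st$species == "He*"]
  # R3 produces one electron per He+; R2 produces He* without new electrons
  expect_equal(de, dip, tolerance = 1e-12)
  expect_gt(dm, 0)
})

test_that("energy source is minus the activation-weighted event-rate sum", {
  ch <- he_chemistry()
  sp <- he_species()$name
  orc <- oracle_stoich()

  # only R2 active: 19.8 eV lost per event
  n <- setNames(rep(0, 6), sp); n["e"] <- 1e15; n["He"] <- 2.45e25
  k2 <- evaluate_rate(ch$reactions[2, ], 3)
  k3 <- evaluate_rate(ch$reactions[3, ], 3)
  k1 <- evaluate_rate(ch$reactions[1, ], 3)
  got <- energy_source(ch, n, 3)
  want <- -(19.8 * k2 + 24.6 * k3 + 0 * k1) * n["e"] * n["He"]
  expect_equal(got, unname(want), tolerance = 1e-12)

  expect_equal(energy_source(ch, setNames(rep(0, 6), sp), 2), 0)

  # mixed state against the brute-force signed sum
  set.seed(7)
  n <- setNames(10^runif(6, 13, 18), sp); n["He"] <- 2.45e25
  want <- 0
  for (i in seq_len(14)) {
    k <- evaluate_rate(ch$reactions[i, ], 2)
    want <- want - orc$activation[i] * k * prod(n[orc$reactions[[i]]$re])
  }
  expect_equal(energy_source(ch, n, 2), want, tolerance = 1e-10)
})

test_that("well-mixed afterglow integration stays nonnegative and reaches steady state", {
  ch <- he_chemistry()
  sp <- he_species()$name
  # afterglow limit: electrons thermalized at the gas temperature, so the
  # system relaxes by recombination and metastable conversion
  deriv <- function(t, y, p) {
    n <- setNames(pmax(y, 0), sp)
    d <- source_terms(ch, n, Te = 0.026)$rate
    d[sp == "He"] <- 0            # fixed background
    list(d)
  }
  set.seed(11)
  for (rep in 1:3) {
    y0 <- setNames(10^runif(6, 12, 16), sp)
    y0["He"] <- 2.45e25
    out <- deSolve::lsoda(y0, c(0, 1, 2), deriv, NULL)
    expect_true(all(out[, -1] > -1e-6 * max(out[, -1])))
    # relative change over the second half is small: near steady state
    rel <- abs(out[3, -1] - out[2, -1]) / (out[3, -1] + 1)
    expect_true(all(rel < 0.35))
  }
})
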