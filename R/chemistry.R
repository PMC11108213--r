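#' Helium plasma species table
#'
#' The six species of the helium reaction set: electrons, ground-state
#' helium, the 2^3S metastable atom He*, the triplet excimer He2*, and the
#' atomic and molecular ions. `charge` is in elementary charges and
#' `helium_nuclei` counts He nuclei, the two quantities conserved by every
#' reaction.
#'
#' @return A tibble with columns `name`, `charge`, `helium_nuclei`.
#' @export
#' @examples
#' he_species()
he_species <- function() {
  tibble::tibble(
    name          = c("e", "He", "He*", "He2*", "He+", "He2+"),
    charge        = c(-1L, 0L, 0L, 0L, 1L, 1L),
    helium_nuclei = c(0L, 1L, 1L, 2L, 1L, 2L)
  )
}

# Rate-coefficient lookup tables for the electron-impact reactions whose
# coefficients come from a Boltzmann-solver treatment of the helium
# cross-sections. Built from Maxwellian-EEDF analytic fits (prefactors in
# cm^3/s with the temperature power taken in Kelvin, converted here to SI
# with Te in eV); thresholds 19.8, 24.6 and 4.78 eV match the reaction set.
# The elastic entry is a momentum-transfer estimate sigma_m * <v> with
# sigma_m = 6e-20 m^2. Tables are sampled on a log grid and interpolated
# log-linearly with clamping at the ends.
.boltzmann_rate_tables <- function() {
  Te <- exp(seq(log(0.05), log(50), length.out = 60)) # eV
  Tk <- Te * .const$eV_K
  vbar <- sqrt(8 * .const$e * Te / (pi * .const$me))
  list(
    R1 = list(Te = Te, k = 6e-20 * vbar),
    R2 = list(Te = Te, k = 2.308e-16 * Tk^0.31 * exp(-19.8 / Te)),
    R3 = list(Te = Te, k = 2.584e-18 * Tk^0.68 * exp(-24.6 / Te)),
    R4 = list(Te = Te, k = 4.661e-16 * Tk^0.6 * exp(-4.78 / Te))
  )
}

#' The 14-reaction helium chemistry set
#'
#' Builds the default helium reaction set used by the discharge model:
#' elastic scattering, excitation and ionization of He, stepwise and excimer
#' ionization, metastable pooling, three-body conversion and recombination.
#' Electron-impact coefficients (R1-R4) are tabulated against electron
#' temperature (provenance recorded in `$provenance`); the remainder are
#' constants or power-exponential expressions in Te (eV). Two-body
#' prefactors are m^3/s, three-body (R8, R9, R11) m^6/s. `activation_eV`
#' is the electron energy change per event with the table's sign convention:
#' positive = energy removed from the electron gas, negative = returned.
#'
#' Charge and helium-nucleus conservation are asserted for every reaction at
#' construction. Note the metastable-pooling activation entry (-15 eV for
#' R6) is retained exactly as catalogued even though it is not obviously
#' consistent with the 24.6 eV ionization threshold; see the methods
#' vignette.
#'
#' @return An object of class `chemistry_set`: a list with `species`
#'   (tibble), `reactions` (tibble, one row per reaction with list-columns
#'   `reactants` and `products`), and `provenance`.
#' @export
#' @examples
#' ch <- he_chemistry()
#' ch$reactions[, c("index", "label", "form", "activation_eV")]
he_chemistry <- function() {
  tabs <- .boltzmann_rate_tables()
  r <- function(index, reactants, products, form, prefactor = NA_real_,
                Te_exponent = 0, Te_scale_eV = 0, table = NULL, activation = 0) {
    tibble::tibble(
      index = index,
      label = paste(paste(reactants, collapse = " + "), "->",
                    paste(products, collapse = " + ")),
      reactants = list(reactants), products = list(products),
      form = form, prefactor = prefactor,
      Te_exponent = Te_exponent, Te_scale_eV = Te_scale_eV,
      table = list(table), activation_eV = activation
    )
  }
  reactions <- dplyr::bind_rows(
    r("R1",  c("e", "He"),        c("e", "He"),         "tabulated", table = tabs$R1, activation = 0),
    r("R2",  c("e", "He"),        c("e", "He*"),        "tabulated", table = tabs$R2, activation = 19.8),
    r("R3",  c("e", "He"),        c("e", "e", "He+"),   "tabulated", table = tabs$R3, activation = 24.6),
    r("R4",  c("e", "He*"),       c("e", "e", "He+"),   "tabulated", table = tabs$R4, activation = 4.78),
    r("R5",  c("e", "He2*"),      c("e", "e", "He2+"),  "power_exp", 1.268e-18, 0.71, 3.4, activation = 3.4),
    r("R6",  c("He*", "He*"),     c("e", "He", "He+"),  "constant",  4.5e-16,  activation = -15),
    r("R7",  c("He*", "He*"),     c("e", "He2+"),       "constant",  2.03e-15, activation = -19.6),
    r("R8",  c("He+", "He", "He"), c("He2+", "He"),     "constant",  1e-43,    activation = 0),
    r("R9",  c("He*", "He", "He"), c("He2*", "He"),     "constant",  1.3e-45,  activation = 0),
    r("R10", c("e", "He*"),       c("e", "He"),         "constant",  2.9e-15,  activation = -19.8),
    r("R11", c("e", "e", "He+"),  c("e", "He*"),        "power_exp", 5.12e-39, -4.5, 0, activation = -4.78),
    r("R12", c("e", "He+"),       c("He"),              "constant",  2e-18,    activation = -24.6),
    r("R13", c("e", "He2+"),      c("He*", "He"),       "power_exp", 5.386e-13, -0.5, 0, activation = -0.2),
    r("R14", c("e", "He2+"),      c("He", "He"),        "constant",  9e-15,    activation = -20)
  )
  set <- structure(
    list(
      species = he_species(),
      reactions = reactions,
      provenance = paste(
        "R1-R4 tabulated vs Te from Maxwellian-EEDF analytic fits to the",
        "helium cross-section set (thresholds 19.8/24.6/4.78 eV);",
        "R1 from sigma_m = 6e-20 m^2 momentum transfer."
      )
    ),
    class = "chemistry_set"
  )
  validate_chemistry(set)
  set
}

#' @export
print.chemistry_set <- function(x, ...) {
  cat("<chemistry_set> ", nrow(x$reactions), " reactions, ",
      nrow(x$species), " species\n", sep = "")
  print(x$reactions[, c("index", "label", "form", "prefactor", "activation_eV")])
  invisible(x)
}

#' Validate a chemistry set
#'
#' Asserts the structural invariants: known unique species, reaction order 2
#' or 3, and conservation of charge and helium nuclei across every reaction.
#'
#' @param set A `chemistry_set`.
#' @return `set`, invisibly; errors on violation.
#' @export
validate_chemistry <- function(set) {
  sp <- set$species
  stopifnot(!anyDuplicated(sp$name), all(sp$charge %in% -1:1),
            all(sp$helium_nuclei >= 0))
  look <- function(what, col) {
    vapply(what, function(nm) {
      i <- match(nm, sp$name)
      if (is.na(i)) stop("unknown species in reaction: ", nm, call. = FALSE)
      sp[[col]][i]
    }, integer(1))
  }
  for (i in seq_len(nrow(set$reactions))) {
    rx <- set$reactions[i, ]
    rs <- rx$reactants[[1]]; ps <- rx$products[[1]]
    if (!(length(rs) %in% 2:3))
      stop(rx$index, ": reaction order must be 2 or 3", call. = FALSE)
    if (sum(look(rs, "charge")) != sum(look(ps, "charge")))
      stop(rx$index, ": charge not conserved", call. = FALSE)
    if (sum(look(rs, "helium_nuclei")) != sum(look(ps, "helium_nuclei")))
      stop(rx$index, ": helium nuclei not conserved", call. = FALSE)
  }
  invisible(set)
}

#' Evaluate a rate coefficient at an electron temperature
#'
#' Constant-form reactions return the prefactor regardless of `Te`;
#' power-exponential forms evaluate `prefactor * Te^p * exp(-b/Te)` with
#' `Te` in eV; tabulated forms interpolate log-linearly in (Te, k) and clamp
#' at the table ends.
#'
#' @param reaction One row of `he_chemistry()$reactions` (or a compatible
#'   one-row tibble / list).
#' @param Te Electron temperature(s) in eV; must be > 0.
#' @return Rate coefficient(s), m^3/s (two-body) or m^6/s (three-body).
#' @export
#' @examples
#' ch <- he_chemistry()
#' evaluate_rate(ch$reactions[14, ], Te = 2)  # constant, 9e-15
evaluate_rate <- function(reaction, Te) {
  if (any(!is.finite(Te)) || any(Te <= 0))
    stop("Te must be positive and finite", call. = FALSE)
  form <- reaction$form[[1]]
  if (form == "constant") {
    rep(reaction$prefactor[[1]], length(Te))
  } else if (form == "power_exp") {
    b <- reaction$Te_scale_eV[[1]]
    reaction$prefactor[[1]] * Te^reaction$Te_exponent[[1]] *
      (if (b != 0) exp(-b / Te) else 1)
  } else if (form == "tabulated") {
    tab <- reaction$table[[1]]
    if (is.null(tab) || length(tab$Te) == 0)
      stop("tabulated reaction has an empty table", call. = FALSE)
    lk <- approx(log(tab$Te), log(tab$k), xout = log(pmin(pmax(Te, min(tab$Te)),
                                                          max(tab$Te))))$y
    exp(lk)
  } else stop("unknown rate form: ", form, call. = FALSE)
}

# Per-reaction event rates (events m^-3 s^-1) for a named density vector.
.event_rates <- function(set, densities, Te) {
  vapply(seq_len(nrow(set$reactions)), function(i) {
    rx <- set$reactions[i, ]
    k <- evaluate_rate(rx, Te)
    k * prod(densities[rx$reactants[[1]]])
  }, numeric(1))
}

#' Net species production rates for a well-mixed state
#'
#' Sums stoichiometric production minus consumption over all reactions at
#' the given densities and electron temperature. Charge and helium-nucleus
#' weighted sums of the result are zero by construction of the reaction set.
#'
#' @param set A `chemistry_set`.
#' @param densities Named numeric vector of number densities (m^-3) for the
#'   six species; all must be nonnegative.
#' @param Te Electron temperature, eV.
#' @return A tibble with columns `species` and `rate` (m^-3 s^-1).
#' @export
#' @examples
#' ch <- he_chemistry()
#' n <- c(e = 1e16, He = 2.45e25, `He*` = 1e16, `He2*` = 0, `He+` = 1e16, `He2+` = 0)
#' source_terms(ch, n, Te = 2)
source_terms <- function(set, densities, Te) {
  densities <- densities[set$species$name]
  if (anyNA(densities)) stop("densities must be named for all species", call. = FALSE)
  if (any(densities < 0)) stop("negative density", call. = FALSE)
  ev <- .event_rates(set, densities, Te)
  rate <- setNames(numeric(nrow(set$species)), set$species$name)
  for (i in seq_len(nrow(set$reactions))) {
    rx <- set$reactions[i, ]
    for (s in rx$reactants[[1]]) rate[s] <- rate[s] - ev[i]
    for (s in rx$products[[1]])  rate[s] <- rate[s] + ev[i]
  }
  tibble::tibble(species = names(rate), rate = unname(rate))
}

#' Electron energy density source from chemistry
#'
#' The net rate of change of electron energy density due to inelastic and
#' superelastic collisions and recombination: minus the sum over reactions
#' of activation energy times event rate (positive activation entries drain
#' the electron gas, negative entries heat it).
#'
#' @inheritParams source_terms
#' @return Scalar energy density rate, eV m^-3 s^-1.
#' @export
energy_source <- function(set, densities, Te) {
  densities <- densities[set$species$name]
  if (anyNA(densities)) stop("densities must be named for all species", call. = FALSE)
  if (any(densities < 0)) stop("negative density", call. = FALSE)
  ev <- .event_rates(set, densities, Te)
  -sum(set$reactions$activation_eV * ev)
}
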