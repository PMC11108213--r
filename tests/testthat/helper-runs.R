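# Shared, lazily computed discharge runs (expensive) reused across test
# files, plus small constructors used by several tests.

.run_cache <- new.env(parent = emptyenv())

cached_ac_run <- function() {
  if (is.null(.run_cache$ac))
    .run_cache$ac <- suppressWarnings(run_discharge("ac", seed = 1L))
  .run_cache$ac
}

cached_dc_run <- function() {
  if (is.null(.run_cache$dc))
    .run_cache$dc <- suppressWarnings(run_discharge("dc", seed = 1L))
  .run_cache$dc
}

uniform_state <- function(n_z = 61, ne = 1e16, Te = 2, L = 1e-3) {
  z <- seq(0, L, length.out = n_z)
  zero <- rep(0, n_z)
  discharge_state(z, list(e = rep(ne, n_z), `He*` = zero, `He2*` = zero,
                          `He+` = rep(ne, n_z), `He2+` = zero), Te_eV = Te)
}

# Independent stoichiometry table for the 14-reaction set, hand-written
# from the catalogued reaction equations (used as a brute-force oracle
# against the package's source-term assembly).
oracle_stoich <- function() {
  sp <- c("e", "He", "He*", "He2*", "He+", "He2+")
  r <- list(
    R1  = list(re = c("e", "He"),         pr = c("e", "He")),
    R2  = list(re = c("e", "He"),         pr = c("e", "He*")),
    R3  = list(re = c("e", "He"),         pr = c("e", "e", "He+")),
    R4  = list(re = c("e", "He*"),        pr = c("e", "e", "He+")),
    R5  = list(re = c("e", "He2*"),       pr = c("e", "e", "He2+")),
    R6  = list(re = c("He*", "He*"),      pr = c("e", "He", "He+")),
    R7  = list(re = c("He*", "He*"),      pr = c("e", "He2+")),
    R8  = list(re = c("He+", "He", "He"), pr = c("He2+", "He")),
    R9  = list(re = c("He*", "He", "He"), pr = c("He2*", "He")),
    R10 = list(re = c("e", "He*"),        pr = c("e", "He")),
    R11 = list(re = c("e", "e", "He+"),   pr = c("e", "He*")),
    R12 = list(re = c("e", "He+"),        pr = c("He")),
    R13 = list(re = c("e", "He2+"),       pr = c("He*", "He")),
    R14 = list(re = c("e", "He2+"),       pr = c("He", "He"))
  )
  list(species = sp, reactions = r,
       activation = c(0, 19.8, 24.6, 4.78, 3.4, -15, -19.6, 0, 0,
                      -19.8, -4.78, -24.6, -0.2, -20))
}
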