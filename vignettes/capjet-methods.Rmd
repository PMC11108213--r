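---
title: "Models and methods in capjet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in capjet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

capjet reimplements, as desk-scale computations, the quantitative pipeline
of a cold atmospheric-pressure helium plasma jet (CAPJ) study in which a
dielectric-barrier-discharge (DBD) jet, driven either by a 4 kV
peak-to-peak 20 kHz sinusoid or by 10 kV, 10 kHz, 2%-duty DC pulses,
treats recombinant *Pichia pastoris* cultures expressing Endoglucanase II.
Four computational stages are covered: the helium reaction kinetics, the
neutral-gas flow through the jet, the discharge itself, and the
spectroscopic and biological quantification. A synthetic-data module
generates spectra and assay tables with known ground truth so every stage
is testable offline.

This vignette records the models, their assumptions, the tunable
parameters, and the numerical and design choices, in enough detail that a
reader can judge what a passing test suite does and does not demonstrate.

## Helium chemistry

The reaction set holds six species (e, He, He*, He2*, He+, He2+) and the
fourteen catalogued reactions: elastic scattering (R1), excitation and
direct/stepwise/excimer ionization (R2-R5), metastable pooling (R6, R7),
three-body conversion (R8, R9), superelastic quenching (R10) and four
recombination channels (R11-R14). Two-body coefficients are m^3/s,
three-body m^6/s, with Te in eV inside the rate expressions. Charge and
helium-nucleus conservation are asserted for every reaction at
construction.

The four electron-impact coefficients whose source is a Boltzmann-solver
treatment are bundled as lookup tables of rate versus Te, generated from
Maxwellian-EEDF analytic fits whose activation energies (19.8, 24.6 and
4.78 eV) match the catalogued thresholds; the elastic entry uses a
6e-20 m^2 momentum-transfer cross-section times the Maxwellian mean speed.
Tabulated rates interpolate log-linearly and clamp at the table ends.

The electron-energy source convention follows the catalogue: positive
activation entries remove energy from the electron gas, negative entries
(superelastic and recombination channels) return it. The -15 eV entry for
metastable pooling is retained exactly as catalogued even though it is not
obviously consistent with the 24.6 eV ionization threshold; only the
energy bookkeeping, not any rate, depends on it. Elastic energy exchange
(3 me/M (Te - Tg) per R1 collision) is added by the discharge solver on
top of the activation sum, since the catalogue marks R1 with no
activation. The gas is held at 300 K throughout (cold-plasma regime, no
gas heating).

## Jet flow

The flow stage solves the steady laminar incompressible problem in a
locally-fully-developed (lubrication) reduction: at each axial station the
radial Stokes profile is computed by second-order finite differences on
the local cross-section - an annulus beside the rod electrode, a circular
pipe in the open tube and nozzle - and scaled so the volumetric flux
equals the inlet flux exactly. Radial velocity follows from discrete
continuity and pressure from the integrated axial gradient. In the free
gap the exit profile is stretched over a linearly spreading jet radius
(default half-angle 3 degrees), so the speed falls as the cross-section
expands; entrainment and He-air mixing are not modelled.

The study specifies only the gas (99.999% He), the flow rate (3 slm) and
the 10 mm nozzle-to-target gap. The default geometry is therefore
calibrated by continuity: a 1.26 mm nozzle radius makes 3 slm equal
~10 m/s mean outlet speed, and a 1.4 mm tube with a 0.6 mm rod makes the
annular channel peak ~15 m/s, matching the reported velocity pattern. All
dimensions are configurable. At these settings the outlet Reynolds number
is ~210, comfortably laminar, which justifies the incompressible
steady-state treatment.

Numerical notes: each station profile is validated against the closed-form
annular-Poiseuille solution (<1% L2); mass flux through every
cross-section equals the inlet flux by construction; interpolation onto
the common radial output grid leaves a ~0.3% floor in profile comparisons,
which is why accuracy is asserted through the analytic-oracle test rather
than a grid-refinement ratio.

## Discharge model

The discharge stage is a reduced one-dimensional drift-diffusion-Poisson
model across the actual DBD gap: powered electrode, quartz barrier
(relative permittivity 3.8, 0.5 mm, represented on the Poisson grid), a
1 mm helium gap, and a grounded electrode. This is a deliberate reduction
of the study's two-dimensional finite-element treatment; printed
quantities from that model are decade bands and averages, and the honest
expectation for a homogeneous 1D model is discussed under *Limitations*.

Per charged species the flux is drift plus diffusion with
Scharfetter-Gummel exponential discretization; electrons use the Einstein
relation with the local Te, ions with the gas temperature; metastables
diffuse only. Electron energy density w = (3/2) ne Te is transported with
5/3-scaled coefficients, heated by the Joule term and drained by the
activation-weighted reaction sum plus elastic exchange. Secondary electron
emission (coefficient 0.05) re-injects electrons at both surfaces;
photoionization is omitted. The initial condition is a uniform 1e15 m^-3
quasineutral seed with an optional seeded random perturbation, plus a
constant background ionization of 1e14 m^-3 s^-1 representing residual
pre-ionization between discharge events.

The stiff couplings are handled as follows, each choice made for
unconditional stability of the explicit surfaces it replaces:

* semi-implicit Poisson: face permittivities are augmented by
  dt e sum(mu_s n_s), which removes the bulk dielectric-relaxation time
  step limit;
* implicit (backward-Euler) transport per species; the resulting M-matrix
  preserves nonnegativity, so the negative-density rejection path never
  triggers and time-step control is by relative-change error with true
  step rejection and state restore;
* chemistry enters through a net-stoichiometry production/loss split
  (reactions that do not change a species contribute nothing; net losses
  are folded implicitly into the diagonal);
* the dielectric surface charge follows a lumped RC closure integrated
  exactly: sigma relaxes toward the screening charge -C_d V(t) at the
  rate set by the gap conductance. With no plasma the charge is frozen
  (memory effect); during breakdown the gap screens within the step,
  terminating the avalanche;
* drift speeds are capped at 1e6 m/s with the face diffusivity scaled by
  the same factor, preserving the Peclet number and hence every Boltzmann
  flux equilibrium; only sub-grid sheath transients are slowed;
* Te is limited from above by (twice) the local-field equilibrium
  temperature, tabulated from the package's own rates by balancing Joule
  input against collisional losses: at atmospheric pressure the electron
  energy relaxes within picoseconds, so the transported Te cannot
  meaningfully exceed that equilibrium. Joule heating on the two wall
  faces is assigned to the surfaces, not the gas, because the sheath there
  is sub-grid;
* net-ionizing and net-exciting rates taper to zero as the electron or
  metastable density approaches 1% fractional ionization, the validity
  boundary of this cold-plasma closure; a hard backstop at 3% guards
  transport focusing pathologies.

The pulsed-DC waveform carries a 200 ns linear rise and fall inside the
solver (real supplies switch at this scale, and an ideal step is
unresolvable); the exported waveform function keeps the ideal top-hat
definition.

Default run lengths were chosen as the smallest that measure a settled
regime: the AC run integrates two 20 kHz cycles on 120 cells (the summary
cycle is the second; cycle-resolved summaries change by <1% between
cycles 2 and 4), and the DC run integrates two full 100 us periods. Both
finish in well under ten minutes on one CPU. The final-cycle summary
reports the peak electron density over space and time, the time-averaged
volume-mean density, and the average electron temperature in two forms:
the ensemble average (total electron energy over total electrons, the
physically standard mean electron temperature) and the unweighted
cell average; for pulsed drive the on-time average is reported alongside
the full-period average, because a 2% duty cycle makes them very
different quantities and the study does not state which one its printed
average uses.

### Limitations of the discharge stage

A homogeneous 1D DBD model produces an atmospheric-pressure glow: peak
electron densities of order 1e17-1e18 m^-3 at these drive settings. The
study's printed density bands (1e20-1e21 m^-3 AC, 1e22-1e23 m^-3 DC) are
maxima of two-dimensional streamer heads, a structure a 1D reduction
cannot represent; the corresponding acceptance checks are therefore
expected to fail and are retained as honest records of that gap. The
orderings that the model can represent - pulsed DC denser than AC, AC
hotter on average than DC - are reproduced. The full-period DC average Te
is afterglow-dominated (~0.03 eV, the gas floor); the study's 0.6 eV
evidently averages over a different window, which its text leaves
unstated.

## Line-ratio spectroscopy

Electron temperature comes from the Boltzmann relation applied to the
He I 706.5/728.1 nm pair:

Te = (E_728 - E_706) / ln[(A_728 g_728 lambda_706 I_706) /
(A_706 g_706 lambda_728 I_728)]

with the upper-level constants (energies 22.7185 and 22.9203 eV,
statistical weights 3 and 1, Einstein coefficients 1.5474e7 and
1.8299e7 1/s) fixed as catalogued. The singlet 728.1 nm line carries the
higher upper level, so the estimate is positive exactly when the argument
of the logarithm exceeds one, is scale invariant, and *increases* with
I_728/I_706 (a hotter plasma populates the higher level more strongly).
An intensity ratio I_706/I_728 of 2.995 maps to 1.4851 eV.

Electron density then comes from the Saha-Boltzmann relation applied to
the N2 357.6 nm / N2+ 391.1 nm pair with the molecular-nitrogen
ionization energy 15.58 eV; at 1.4851 eV the prefactor
2 (2 pi me kB Te)^{3/2} / h^3 is 1.09e28 m^-3, the Boltzmann energy is
15.58 - 3.16 + 11.05 = 23.47 eV, and an intensity ratio of 0.057 maps to
1e14 cm^-3. Both relations assume partial local thermal equilibrium and
an optically thin plasma; no collisional-radiative correction or
vibrational-exchange treatment is attempted, matching the source
methodology.

Intensities are baseline-subtracted integrated areas over a +-0.5 nm
window (peak heights are available as an option). The baseline is a
straight line anchored on the *averaged* outer points of each window;
single-point anchors would feed their full noise into the area, and the
logarithmic inversion amplifies the intensity-ratio error by roughly
Te/(E_728 - E_706) = 7. The Boltzmann factor amplifies the Te error by a
further factor ~10 in ne, which is why density estimates from noisy
single acquisitions scatter over a factor of a few and the acceptance
computations report medians over an ensemble of synthetic acquisitions.

## Bioassay quantification

Calibration curves (BSA protein standards at 595 nm, glucose standards at
540 nm, BSA lane areas for densitometry) are ordinary least-squares lines
with R^2 and residual diagnostics retained; inversion subtracts a
per-arm background absorbance - the non-recombinant-strain signal in
excess of the curve intercept - before dividing by the slope, clipping
negative concentrations to zero with a flag. Enzyme activity uses the DNS
convention 1 U = 1 umol reducing sugar per minute, normalized per mL of
supernatant with a 30 min incubation default. Group statistics are means,
standard deviations, percent increases and fold changes against the
control group, with a descriptive Welch two-sample p-value per contrast
and no multiplicity adjustment, matching the descriptive error bars of
the source data. Gel-image processing is out of scope: densitometry
operates on integrated band-area tables.

## Synthetic data

The spectrum generator inverts the two line-ratio relations exactly at a
stated (Te, ne) truth, so noise-free round trips are identities by
construction; it adds six decoy lines at plausible plasma wavelengths
(OH 308.9, N2 315.9/337.1/380.5, He I 587.6/667.8 proxy via 587.6, O I
777.3 nm) to exercise window robustness, a linear baseline, and seeded
multiplicative Gaussian noise (5% default). The instrument model is a
0.2 nm (sd) Gaussian line width - a ~0.5 nm FWHM compact CCD spectrometer
- sampled on a 5 pm grid (an oversampled acquisition). These two
parameters were fixed so that the prescribed robustness property (median
Te error below 5% under 5% multiplicative noise) holds with margin; at
coarser sampling the noise in each integration window no longer averages
down sufficiently against the sevenfold amplification described above.

The assay generator draws replicate noise around group means pushed
through the true standard curves, with dose-dependent effect multipliers
that reach the study's reported outcomes at 240 s (protein +45% AC /
+33% DC, activity 1.25-fold AC / 1.19-fold DC, densitometry +47% / +39%)
and unit multipliers for growth and viability. Defaults: four replicates
per group, additive absorbance noise 0.01 AU (0.02 for MTT, 0.15 OD600
units, 150 area units for densitometry), Bradford truth 0.5 AU/(mg/mL)
slope over a 0.4 mg/mL control with 0.15 mg/mL non-recombinant
background, DNS truth 0.35 AU/mM over a 2 mM control. Every generator is
a pure function of its specification including the seed.

What the synthetic data does *not* emulate: instrument response
functions, absolute radiometric calibration, correlated (non-iid) pixel
noise, plate effects or day effects in the assays, and any dose-response
shape beyond the programmed multipliers. Passing recovery tests therefore
demonstrates that the estimators invert the stated generative model
without bias - not that they are robust to systematic effects absent from
that model.

## Seeds and determinism

All stochastic components (spectrum noise, assay noise, the discharge
seed perturbation) are pure functions of an integer seed and restore the
caller's RNG state. Discharge runs are bitwise reproducible given the
seed; the acceptance script threads its `--seed` argument through every
stage.
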