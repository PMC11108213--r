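# capjet

Reduced modelling and diagnostics for a helium cold atmospheric-pressure
plasma jet (CAPJ) used to stimulate recombinant protein production in
*Pichia pastoris*.

A dielectric-barrier-discharge (DBD) helium jet — a quartz tube with a
coaxial rod electrode, fed with 3 slm helium and driven either by a 4 kV
peak-to-peak 20 kHz sinusoid or by 10 kV, 10 kHz pulses at 2% duty —
produces a cold plasma plume whose reactive species can up-regulate
secretion of recombinant Endoglucanase II without harming the cells.
Understanding and quantifying that treatment requires four linked
computations, and `capjet` implements all of them as tested,
desk-scale R functions:

* **Helium chemistry** — the 14-reaction set (excitation, direct /
  stepwise / excimer ionization, metastable pooling, three-body
  conversion, recombination) with rate-coefficient evaluation
  `k(Te)`, species source terms and the electron-energy source
  `-Σ_r ΔE_r R_r`.
* **Jet flow** — steady laminar incompressible flow through the annular
  channel, nozzle and free gap, solved in a locally-fully-developed
  reduction with exact continuity (`Q = ∫ u 2πr dr` at every station).
* **Discharge** — a reduced 1D drift-diffusion–Poisson model of the DBD
  gap with a gridded dielectric barrier, Scharfetter–Gummel fluxes,
  semi-implicit Poisson coupling, electron energy transport and a lumped
  RC closure for the surface-charge memory, under either drive waveform.
* **Line-ratio spectroscopy** — electron temperature from the Boltzmann
  pair He I 706.5/728.1 nm,
  `Te = (E_m − E_i) / ln(A_mn g_n I_ij λ_ij / (A_ij g_i I_mn λ_mn))`,
  and electron density from the Saha–Boltzmann pair N₂ 357.6 nm /
  N₂⁺ 391.1 nm with E_ion = 15.58 eV.
* **Bioassay quantification** — standard-curve calibration (Bradford,
  DNS, densitometry), background-normalized concentration inversion,
  enzyme activity in U/mL, and per-group percent-increase / fold-change
  statistics with descriptive Welch contrasts.
* **Synthetic data** — seeded generators that invert the spectroscopy
  relations exactly at a stated (Te, ne) truth and push programmed assay
  effect sizes through true standard curves, so every estimator can be
  scored against known ground truth offline.

All user-facing functions take data frames and return tibbles; fitted
objects support `tidy()`/`glance()` and results have `autoplot()`
methods.

## Worked example

```r
library(capjet)

# --- spectroscopy: diagnose a synthetic plume spectrum -------------------
trace <- make_spectrum(spectrum_spec(seed = 1))   # truth: 1.4851 eV, 1e14 cm^-3
diagnose_spectrum(trace)
#> <line_ratio_result>
#>   Te = 1.3725 eV  (I706/I728 = 3.029 )
#>   ne = 2.43e+19 m^-3 = 2.43e+13 cm^-3  (I357/I391 = 0.05678 )

# single noisy acquisitions scatter; the median over an ensemble is stable
median(vapply(1:31, function(s)
  diagnose_spectrum(make_spectrum(spectrum_spec(seed = s)))$Te_eV, 1))
#> [1] 1.464181

# --- flow: outlet speed at 3 slm ----------------------------------------
summarize_flow(solve_flow(jet_geometry(), flow_config(slm = 3)))
#> # A tibble: 1 x 5
#>   peak_channel_speed mean_outlet_speed peak_outlet_speed reynolds_outlet laminar
#>                <dbl>             <dbl>             <dbl>           <dbl> <lgl>
#> 1               15.0              10.0              20.1            210. TRUE

# --- discharge: one reduced AC run --------------------------------------
run <- run_discharge("ac", seed = 1)
run$summary[, c("peak_ne", "avg_ne", "avg_Te_full")]
#> # A tibble: 1 x 3
#>    peak_ne  avg_ne avg_Te_full
#>      <dbl>   <dbl>       <dbl>
#> 1 2.22e17  9.77e15        1.40

# --- bioassay: recover programmed effect sizes --------------------------
tabs <- make_assay_tables(assay_spec(seed = 7))
curve <- fit_standard_curve(tabs$bsa_standards)
protein <- tabs$bradford
protein$value <- quantify(protein, curve,
                          background = tabs$background_A595)$concentration
subset(compare_groups(protein), group == "240",
       c(arm, percent_increase, fold))
#> # A tibble: 2 x 3
#>   arm   percent_increase  fold
#>   <chr>            <dbl> <dbl>
#> 1 AC                43.8  1.44
#> 2 DC                31.2  1.31
```

The first spectroscopy call shows a single noisy acquisition (Te 1.37 eV,
ne 2.4e13 cm⁻³): the logarithmic and Boltzmann inversions amplify
acquisition noise, which is why the ensemble median (1.46 eV here, against
a 1.4851 eV truth) is the robust estimate. The flow summary reproduces the
~10 m/s outlet and ~15 m/s channel speeds implied by continuity at 3 slm.
The AC discharge summary gives the final-cycle peak density and the
ensemble-average electron temperature (1.40 eV); the bioassay block
recovers the programmed +45%/+33% protein increases within replicate
noise.

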