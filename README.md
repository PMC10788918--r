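# trastkit

Dark-state fluorescence bar-coding: simulation and fitting of
photoinduced dark-state (transient-state, TRAST) kinetics of
fluorophores across four readout modalities.

## The problem

Almost every organic fluorophore blinks: under excitation it is
reversibly driven into long-lived (microsecond–millisecond)
non-emissive states. Cyanines such as Cy5 photoisomerize from the
fluorescent all-*trans* form *N* into a dark *cis* form *P*;
rhodamine-type dyes such as CF640R instead cross into a triplet state
*T*. Because these kinetics are dye-specific, they can act as an extra
encoding dimension — a "bar code" — that distinguishes fluorophores
with practically identical emission spectra, in solution, in flow, and
pixel-by-pixel in cell images.

`trastkit` implements the computational core of this idea for users of
TRAST and FCS instrumentation: forward models with known ground truth,
and the corresponding Levenberg–Marquardt fitting routines, for

* **stationary TRAST curves** — the normalized time-averaged
  fluorescence `⟨F_exc(w)⟩_norm` versus excitation pulse width `w` in a
  modulated pulse train (duty cycle η, constant illumination time
  `t_ill = N·w`), including two-component brightness-weighted mixtures
  and incomplete inter-pulse recovery;
* **FCS curves** — `G(τ) = (1/N_m) G_diff(τ) (1 + A/(1−A) e^(−τ/τ_dark))`,
  with the dark-state amplitude and relaxation time mapped from the
  photophysical rate model, brightness²-weighted multi-species
  mixtures, global fits across irradiances, and burst pre-filtering;
* **microfluidic flow-TRAST profiles** — fluorophores transiting two
  Gaussian excitation curtains at plug velocity υ, with the bright
  fraction `N(t)` propagated through the time-varying field
  (`dN/dt = −k'_iso(t) N + k'_biso(t)(1−N)`) and mixture-fraction /
  thermal-back-isomerization fitting;
* **pixel-wise TRAST images** — per-pixel monoexponential
  `(A_TRAST, τ_TRAST)` maps, cumulative 2-D histograms with axis-projected
  PDFs, and per-pixel two-species unmixing by maximizing the product of
  the R-mixture PDFs.

The photophysical engine converts irradiance Φ (W/cm²) into effective
rates via the photon flux `k_exc = σ Φ λ/(h c)`:

    k'_iso  = k_exc/(k_exc + k10) · k_iso        (trans → cis)
    k'_biso = σ_biso · Φλ/(hc) + k_biso^Th       (cis → trans)
    k'_isc  = k_exc/(k_exc + k10) · k_isc        (S1 → T);  T → S0 at k_T

Shipped presets (`fluorophore("Cy5_free")`, `"Cy5_SUV"`, `"CF640R"`)
carry the published fitted parameter sets for free Cy5, vesicle-bound
Cy5 and CF640R.

## Worked example

```r
library(trastkit)

cy5 <- fluorophore("Cy5_free")
print(cy5)
#> Fluorophore model 'Cy5_free' (isomerization scheme)
#>   sigma_N    = 6.2e-16 cm^2
#>   k_iso      = 29 us^-1
#>   sigma_biso = 1.5e-17 cm^2
#>   k_biso_th  = 0.0016 us^-1
#>   triplet branch: k_isc = 1.1 us^-1, k_T = 0.5 us^-1
#>   k10 = 1e+09 s^-1

# steady-state dark (cis) fraction at the FCS excitation condition
steady_state(cy5, excitation(16e3, 640))
#> [1] 0.5373675

# simulate a shot-noisy 30-point TRAST curve and invert it
s <- synth_trast_curve(monoexp_params(A = 0.45, tau = 12.4e-6),
                       photon_budget = 1e5, seed = 42)
fit_trast(s$curve)
#> Monoexponential TRAST fit (A, tau)
#>   A            0.452963  (se 0.00114)
#>   tau          1.23172e-05  (se 1.52e-07)
#>   residual sum of squares: 0.0004205 on 30 points
```

About half of the free-Cy5 population sits in the dark *cis* state at
16 kW/cm², which is why its measured molecular brightness is roughly
half that of the non-isomerizing CF640R. The TRAST fit recovers the
generating relaxation amplitude (0.45) and time (12.4 µs) from a curve
with ~10⁵ detected photons per point.

Fit objects are ordinary S3 models: `print()`, `summary()`, `coef()`,
`residuals()`, `fitted()`, `predict()` and `plot()` work on the results
of `fit_trast()`, `global_fit_fcs()` and `fit_flow()`. Curve I/O uses
plain CSV (`read_curve()`/`write_curve()`), fluorophore models are JSON
records, and `run_session()` drives a whole analysis from a YAML/JSON
config to a JSON report.

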