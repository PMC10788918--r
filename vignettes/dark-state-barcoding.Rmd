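---
title: "Dark-state bar-coding: models, parameters and design choices"
author: "trastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-state bar-coding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trastkit)
```

# The photophysical model

`trastkit` treats a fluorophore as a two-state system: an emissive
manifold (ground plus excited singlet) and one long-lived dark state.
Two realizations are supported.

**Isomerization scheme** (cyanines, e.g. Cy5). The fluorescent
all-*trans* state *N* converts to a dark *cis* photoisomer *P* from its
excited singlet, and *P* returns to *N* both photo-driven and
thermally. With the photon absorption rate
$k_{exc} = \sigma_N \Phi \lambda / (hc)$, the effective ground-state
rates are

$$k'_{iso} = \frac{k_{exc}}{k_{exc}+k_{10}}\,k_{iso}, \qquad
  k'_{biso} = \sigma_{biso}\,\frac{\Phi\lambda}{hc} + k_{biso}^{Th}.$$

The back-isomerization channel is deliberately lumped into a single
cross section $\sigma_{biso}$: the cis-state absorption cross section,
its excited-state lifetime and the microscopic back-isomerization yield
only ever appear as a product and cannot be determined separately from
any of the four readout modalities. No attempt is made to model them
individually.

**Triplet scheme** (rhodamines, e.g. CF640R). Intersystem crossing
feeds a triplet *T* at $k'_{isc} = k_{exc}/(k_{exc}+k_{10}) \cdot
k_{isc}$, and *T* decays at an excitation-independent $k_T$.

Both schemes reduce to the same two-state relaxation: switching the
excitation on at $t=0$ with everything bright, the emissive probability
is $S(t) = S_\infty + (1-S_\infty)e^{-t/\tau}$ with
$\tau = 1/(k_{on}+k_{off})$ and dark amplitude
$A = k_{on}/(k_{on}+k_{off})$. This single closed form feeds all four
modalities, which is what makes the bar-coding idea practical: the
*same* $(A, \tau)$ pair shows up as a TRAST curve depression, an FCS
relaxation shoulder, a flow-profile second-peak suppression, and a
pixel cluster in an image histogram.

An optional three-state extension (N, P, T) handles the minor triplet
buildup of Cy5 at high irradiance. It is solved by matrix exponential
and switched on automatically above 100 kW/cm² (configurable); below
that threshold the triplet branch contributes negligibly and the
two-state analytic path is used.

## Key parameters

| parameter | units | default (free Cy5) | meaning |
|---|---|---|---|
| `sigma_N` / `sigma_S` | cm² | 6.2e-16 / 4e-16 | ground-state absorption cross section |
| `k_iso` | s⁻¹ | 29e6 | isomerization rate out of S1 |
| `sigma_biso` | cm² | 0.15e-16 | lumped photo-driven back-isomerization |
| `k_biso_th` | s⁻¹ | 1600 | thermal cis→trans recovery |
| `k_isc`, `k_T` | s⁻¹ | 0.7e6, 0.5e6 (CF640R) | triplet crossing / decay |
| `k10` | s⁻¹ | 1e9 | S1 decay rate (1 ns lifetime), fixed by default |

Cross sections are stored in cm², irradiance in W/cm², all rates in
s⁻¹; display methods convert to µs⁻¹ but storage never does, to avoid
unit drift. Wavelengths are in nm (300–1000).

# Modalities

**TRAST.** A train of rectangular pulses of width $w$ (duty cycle
$\eta$, default 0.01; illumination time $t_{ill}=N w$, default 1 ms)
yields the pulse-window average
$\langle F(w)\rangle = 1-A+\frac{A\tau}{w}(1-e^{-w/\tau})$, normalized
at a reference width $w_0$ (default: the shortest width of the series,
100 ns on the default 30-point log grid from 100 ns to 1 ms). The
normalization cancels concentration, detection efficiency and quantum
yields. At $\eta=0.01$ the single-pulse expression is used; a
`per_pulse = TRUE` path chains the pulses through the inter-pulse
recovery recursion for higher duty cycles or very slow thermal
recovery. A warning is raised when the model predicts more than 0.1%
dark buildup at $w_0$, since that biases real normalizations; the
synthetic generator suppresses it because it renormalizes its own exact
forward model.

One subtlety worth recording: with $\eta = 0.01$ and a slow
$k_{biso}^{Th}$, the *reference* train at $w_0$ itself accumulates a
steady carry-over dark population. The per-train average is therefore
always below the first-pulse average at fixed $w$, but the
$w_0$-normalized curve can sit slightly above the single-pulse curve.
Tests assert the former (which is the physically guaranteed
inequality), not the latter.

**FCS.** $G(\tau) = \frac{1}{N_m} G_{diff}(\tau)\left(1 +
\frac{A}{1-A}e^{-\tau/\tau_{dark}}\right)$ with a 3-D Gaussian-volume
diffusion factor $G_{diff} = (1+\tau/\tau_D)^{-1}
(1+\tau/(s^2\tau_D))^{-1/2}$, structure ratio $s=5$ by default and a
2-D variant available. The exact instrument-specific diffusion term is
not critical here because generation and fitting share the same form;
all recovery checks fix $s$ between the two. Mixtures weight each
species by $R_i Q_i^2$ (fraction times brightness squared), normalized
so a single species reproduces the plain model bit-for-bit. Global
fits share the photophysical pair ($k_{iso}, \sigma_{biso}$ or
$k_{isc}, k_T$) across curves recorded at different irradiances while
$N_m$ and $\tau_D$ stay free per curve; residuals are unweighted, and
the optimizer is Levenberg–Marquardt (`minpack.lm`) on log10-scaled
parameters with physical bounds. The default lag grid is
quasi-logarithmic, 16 points per octave from 0.1 µs to 1 s, mimicking a
multi-tau correlator layout. `burst_filter()` excises bins above
mean + kσ (k = 5), with mean and SD computed on the bins at or below
the 90% quantile so bursts do not inflate their own threshold.

A note on amplitude constancy: for an isomerization dye with both
channels photo-driven and negligible thermal recovery, $A$ is nearly
irradiance-independent — but not exactly. The saturation factor
$k_{exc}/(k_{exc}+k_{10})$ lowers $A$ from ≈0.55 at 1 kW/cm² to ≈0.50
at 100 kW/cm² (≈9% relative span). The property tests assert <5%
variation over 1–30 kW/cm² and <10% over the full decade-and-a-half.

**Flow-TRAST.** The excitation field is two Gaussian curtains
(1/e radius 15 µm along the flow axis, 100 µm across the channel,
peak 1.3 kW/cm² by default, optionally calibrated from a total beam
power through the Gaussian integral $\sqrt{\pi} r L$ per curtain).
The curtain center separation is not a published quantity (it was
tunable on the instrument); the default is 50 µm center-to-center, and
all flow acceptance checks are self-consistent parameter-recovery round
trips rather than comparisons to published profile shapes. Plug flow
at $\upsilon = Q_{vol}/(w\,d)$ (500 µm × 50 µm channel) maps position
to transit time, and the bright fraction obeys
$dN/dt = -k'_{iso}(t)N + k'_{biso}(t)(1-N)$ with $N(0)=1$ on entering
the first curtain. Triplet buildup and photobleaching are omitted in
flow: at ≤3.4 kW/cm² peak irradiance with single curtain passages both
are negligible for these dyes. Profiles are normalized to unit
first-curtain peak; a non-isomerizing species then reproduces the
normalized excitation profile identically, and the second-peak ratio of
an isomerizing species encodes the thermal recovery between curtains —
stronger suppression at faster flow, which is the fitted signal for
$k_{biso}^{Th}$ and, in mixtures, for $R_{Cy5}$.

**Imaging.** Stacks (one frame per pulse width) are background
subtracted, optionally bleach-corrected, and $w_0$-normalized per
pixel. Bleach correction uses reference frames at $w_0$ recorded
before and after the series: the per-pixel survival ratio is
interpolated linearly in acquisition order — the published pipeline
does not print its method, so this one is documented and swappable.
Pixel masking uses median + 3×MAD of the per-pixel summed intensity
(computed before clipping negatives, so background stays centered at
zero). Per-pixel $(A_{TRAST}, \tau_{TRAST})$ fitting runs a coarse
grid search (48×48 over linear $A$ and log $\tau$) followed by eight
damped Gauss–Newton steps vectorized across all pixels; non-converged
pixels carry NaN. Reference 2-D histograms use 50 linear $A$ bins on
[0,1] and 60 log $\tau$ bins on [0.5 µs, 1 ms]; the axis projections
are normalized to unit area on their own axis (linear in $A$,
logarithmic in $\tau$) and smoothed with a 1-bin Gaussian to avoid
zero-probability holes.

**Unmixing objective.** The per-pixel fraction maximizes
$L(R) = \prod_{i\in\{A,\tau\}}\left[R\,\mathrm{PDF}^i_1(x) +
(1-R)\,\mathrm{PDF}^i_2(x)\right]$ over $R\in[0,1]$. The published
wording ("a linear combination of their PDFs") is ambiguous between a
product and a sum over the two axes; the product is the default because
it uses both coordinates as (approximately) independent evidence and
has a closed-form maximizer — $L$ is quadratic in $R$, so the interior
stationary point is compared against the endpoints analytically. The
sum variant (linear in $R$, endpoint solutions only) is available via
`objective = "sum"`. Pixels outside both supports return NaN with a
flag; pixels where the two references are exactly equal return 0.5
with a degeneracy flag.

# The synthetic-data generator

The generator emulates, with known ground truth: shot-noise-corrupted
TRAST curves (Poisson counts at a per-point photon budget, then
renormalized noisy-by-noisy exactly as a real normalization would);
FCS curves with lag-dependent multiplicative noise
($\mathrm{sd} \propto \mathrm{level}/\sqrt{\mathrm{lag\ index}}$,
mimicking correlator statistics); flow profiles with additive noise
relative to the unit first peak; and dual-label cell stacks with a
nuclear-rim structure carrying fast/low-amplitude triplet-like kinetics
(A = 0.2, τ = 2 µs) and a filament structure carrying slow,
high-amplitude isomerization-like kinetics (A = 0.45, τ = 30 µs),
per-pixel brightness variation (uniform ±40%), Poisson shot noise and a
constant Poisson background. These cluster centers sit inside the
ranges observed for Cy5- and AS635-labeled cell structures
(amplitudes ~0.1–0.6 vs ~0–0.3; relaxation times ~20–50 µs vs <5 µs).

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: camera read noise and gain maps,
detector afterpulsing and dead time, diffusion-driven intensity traces
(FCS curves are generated at model level, not correlated from photon
streams), spatially varying illumination, cell autofluorescence,
partial-volume mixing at structure boundaries (structures are binary),
and any photobleaching beyond the synthetic test of the correction
path. Everything is seeded; identical seeds give identical output.

# Numerical choices

* **Rate conversion** uses CODATA $h$ and $c$; this reproduces the
  ~50% steady-state cis fraction of free Cy5 at 16 kW/cm².
* **Flow integrator**: exact exponential relaxation per step with rates
  frozen at the step midpoint, step
  $\Delta t = \min(0.05/(k'_{iso}+k'_{biso})_{max},\ \mathrm{curtain
  transit}/200)$ (with a 2% safety margin); this keeps $N\in[0,1]$
  unconditionally, and `propagate_N()` refuses coarser grids rather
  than silently degrading. When a fit requests model values on a
  measurement grid, integration still runs on the internally refined
  grid and is interpolated onto the output grid. Agreement with a
  stiff ODE solver (`deSolve::lsoda`, rtol 1e-10) is better than
  1e-4 absolute in $N$.
* **Optimizer scaling**: rates and per-curve nuisance parameters are
  fitted on log10 scale with physical bounds (e.g. $k_{iso} < k_{10}$);
  standard errors are mapped back by the delta method. Start values
  are data-driven (curve amplitude, half-decay lag) rather than the
  generating truth.
* **Pixel fits**: the $2\times2$ Gauss–Newton normal equations are
  solved in closed form per pixel, with step damping (max step 0.5 in
  $(A, \log\tau)$) and box constraints; the $w_0$ renormalization is
  part of the model and its derivative.
* **Tie-breaks / degenerate inputs**: all-zero traces pass the burst
  filter unchanged with a warning; a constant trace is returned
  unchanged; histogram values at the upper bin edge are clamped into
  the last bin; degenerate unmixing pixels return 0.5 flagged.

# Problem sizes

The test suite and the acceptance script use: 30-point TRAST grids;
three-irradiance FCS sets of ~370 lags each with 50 seeded replicates
per recovery study; five flow profiles (130–670 mm/s, ~1000 output
points each); and 48×48-pixel image stacks with 30 frames. These sizes
give sub-minute FCS recovery studies and seconds-scale imaging runs
while keeping Monte-Carlo standard errors a factor of several below the
tolerances they are tested against.

# Known limitations

* Only one dark state per scheme (plus the optional Cy5 triplet
  branch); radical/photoionized states and photobleaching channels are
  out of scope.
* The flow model assumes uniform plug velocity across the analysis
  window; no parabolic-profile correction.
* The FCS path generates curves at model level; correlating synthetic
  photon streams is not implemented.
* $\sigma_P$, $k_{biso}$ and the cis-state lifetime are intentionally
  not separable; any direct cis-state excitation beyond the lumped
  $\sigma_{biso}$ term is not represented.
* The inter-pulse recovery recursion and the burst-filter threshold are
  documented reconstructions validated by self-consistency (recovered
  parameters match generating ones), not against an external reference
  implementation.
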