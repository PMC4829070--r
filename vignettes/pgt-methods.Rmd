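---
title: "Models and methods behind pgtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtsim)
```

`pgtsim` simulates and analyses prompt gamma-ray timing (PGT) spectra for
in-vivo proton range verification. This vignette is the package's own account
of the physics it implements, the parameters that matter, the numerical
choices, and what the tests do and do not establish. No empirical claim is
made here that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Proton transport (CSDA)

Energy loss is the continuous-slowing-down approximation,
$\mathrm{d}E/\mathrm{d}z = -\rho(z)\,S(E)$, with the proton velocity
$v(E) = c\sqrt{1 - (1 + E/m_p c^2)^{-2}}$ and transit time
$t_p(z) = \int_0^z \mathrm{d}z'/v(E(z'))$.

**Stopping-power model.** Measured PGT campaigns do not constrain $S(E)$
directly, so the default is the Bragg–Kleeman range–energy law
$R(E) = \alpha E^{p}$ calibrated in water: $p = 1.77$ and $\alpha$ fixed by
$R(230\ \mathrm{MeV}) = 330$ mm. Materials are water-referenced through their
linear relative stopping power (RSP): PMMA 1.16, cortical bone 1.57, and air
carries the water *mass* stopping power at its true density
$1.204\times10^{-3}$ g/cm³ (never zero, so every integral stays finite).
Within a slice the residual range is then linear in $E^{p}$, making energy
propagation closed-form; only the transit time needs quadrature, done
adaptively after exchanging depth for energy
($\mathrm{d}z = \mathrm{d}E / (\rho S)$). A two-column $(E, S)$ table per
material can override the analytic law (log–log interpolation); transport
then builds the residual-range map by cumulative quadrature on a fine
log-energy grid. This model is accurate at the few-percent level, which is
what the qualitative campaign figures require; it deliberately omits lateral
scattering, energy straggling and nuclear attenuation of the fluence.

**Energy floor.** Integration stops at $E_\mathrm{floor} = 1$ MeV, where both
$S(E)$ and $1/v$ grow steeply; the induced range error is below 0.03 mm,
an order of magnitude under the 0.1-mm tolerances used in the tests.

**Numerical guarantees** (all asserted in `tests/testthat/test-transport.R`):
adaptive results agree with a fixed 1-µm Euler/trapezoid oracle to
0.01 MeV / 1 ps; a homogeneous water range matches $\alpha E_0^{p}$ to
0.1 mm; an air cavity of thickness $h$ shifts the range by $+h \pm 0.1$ mm;
`depth_at_time()` inverts `transit_time()` to 0.01 mm.

## 2. The PGT forward model

The detection-time density for emission at depth $z$ is

$$\Phi(t) = \int_0^{R} \varepsilon(z)\, w(z)\,
  g\!\left(t - t_p(z) - |r_\mathrm{det} - z\hat e_z|/c;\ \Sigma_\mathrm{sys}\right)
  \mathrm{d}z + \mathrm{pedestal},$$

folded modulo the bunch period $T_\mathrm{bunch} = 1/f_\mathrm{bunch}$.

- **Emission density** $\varepsilon(z) \propto \rho(z)\cdot$`yield_factor`,
  uniform per unit mass path ("box" emission). This reproduces the cavity dip
  and bone bump of heterogeneous targets but intentionally ignores the
  depth dependence of the nuclear cross section, so the very fall-off shape
  near the Bragg peak is not faithful — the same caveat the box model is
  known for.
- **Total yield** is `gamma_yield` = 0.16 prompt gammas (> 1 MeV) per proton
  over the *full* slowing-down track. For shoot-through (thin) targets the
  normalization extends the track virtually in the last slice's material, so
  a target covering half the track intercepts half the gammas; stacked
  targets therefore grow the spectrum area and saturate exactly once the
  protons stop inside. (The design alternative — normalizing by the
  in-target emission only — would give thin targets the full yield and
  contradict the stacked-target behaviour, so it was rejected.)
- **Sensitivity** $w(z) = r^2 / (4 D(z)^2)$, the far-field solid-angle
  fraction of a disc of radius $r$ at distance $D(z)$.
- **Resolution** $\Sigma_\mathrm{sys}^2 = \Sigma_\mathrm{det}^2 +
  \Sigma_\mathrm{bunch}^2$ (all FWHM). The bunch spread interpolates
  linearly between the measured anchors 2 ns at 100 MeV and 350 ps at
  230 MeV, constant outside; a scalar override is available.
- **Background**: a single flat pedestal, default 5 % of total counts,
  uniform over the period. Campaign data show background but do not quantify
  its fraction; 5 % of the in-peak statistics is a realistic scale for an
  energy-gated fast scintillator and is a free parameter everywhere.
- **Geometry reference**: the detector ring centre `z_ref` defaults to the
  phantom mid-length (targets are held at the ring centre); configurable.
- **Detector timing** for the bundled fixtures is 0.3 ns FWHM — typical for
  a 2-inch fast monolithic scintillator (LaBr₃-class) at prompt-gamma
  energies. It is a stated-world constant, not a fitted value.
- **Binning default**: 100 bins over one bunch period.

The Monte Carlo twin (`sample_events()`) draws a Poisson number of detected
gammas with mean
$N_p\,Y\,\epsilon\,\int \varepsilon w \,\mathrm{d}z / \int_\mathrm{track} \varepsilon\, \mathrm{d}z$,
samples depths by inverse CDF from $\varepsilon(z) w(z)$, adds Gaussian
timing jitter and the background admixture, and wraps to $[0, T)$. One
integer seed fixes the event list exactly; `derive_seed()` fans a global
seed out to pipeline stages so adding a stage never perturbs earlier
streams. Wall-clock stamps allow piecewise-linear accelerator phase drifts
(`apply_drift()`) to be injected after the fact.

A χ² test (`test-model.R`) checks the sampler against the analytic spectrum
bin by bin; conservation tests check the wrapped integral against the Poisson
mean.

## 3. Range-shift analysis

**Trailing edge.** The campaign literature does not define how the falling
edge was extracted. `pgtsim` uses the 50 %-of-plateau crossing, with the
plateau estimated as the median of the top quartile of in-window bins, and
the crossing solved from a local least-squares line through the falling
flank (the bins between 75 % and 25 % of the plateau). On a noiseless step
this is the exact midpoint crossing; on an erf-smeared box it sits at the box
end to within 0.02 Σ. The flank fit matters under Poisson noise: a bare
"last crossing above threshold" rule is biased late by upward noise
excursions in the low tail, while the fitted crossing is symmetric and has
several-fold lower variance. A logistic-fit refinement is available behind
`method = "sigmoid"`. Spectra are unwrapped by rotating the longest
below-10 %-of-peak gap to the start of the frame, which makes the estimator
exactly equivariant under integer-bin circular shifts.

**Time-to-depth conversion of a shift.** A density perturbation at depth $f$
that changes the range by $\Delta z$ delays the trailing edge by
$\Delta t \approx \Delta z \left[1/v(E(f)) + \partial_z \mathrm{TOF}(R)\right]$:
the extra path is traversed at the *local* proton speed at the perturbation,
while the stopping point itself moves by $\Delta z$ at the range. The
conversion derivative in `edge_shift()` is therefore evaluated at the
perturbation depth (auto-located via `first_divergence()` when both phantoms
are given, or supplied as `z_shift`), with the time-of-flight term at the
reference range. Evaluating the whole derivative at the reference range — the
naive reading, with $1/v(E_\mathrm{floor}) \approx 0.07$ ns/mm — would
under-convert a cavity-induced 38-ps edge shift to 0.5 mm instead of 5 mm;
this choice is deliberate and is exercised by the noiseless recovery test
(4.5–5.5 mm for the 5-mm cavity, negative for the 20-mm bone insert, whose
water-equivalent excess corresponds to about −7 mm).

**Time→depth inversion.** `time_to_depth()` checks that arrival time is
monotone in depth, subtracts the pedestal (estimated from off-signal bins),
interpolates the count density at $t(z)$, and corrects by the Jacobian
$|\mathrm{d}t/\mathrm{d}z|$ and the sensitivity $w(z)$. In the limit of
small $\Sigma_\mathrm{sys}$ it recovers $\varepsilon(z)$ up to scale. At
finite resolution the recovered shape is $\varepsilon$ convolved with the
local kernel of width $\sigma_t \cdot \mathrm{d}z/\mathrm{d}t$: at 200 ps
FWHM this is ±12 mm at mid-track, so a 20-mm insert (136 ps wide in time) is
at the resolution limit and exact-shape recovery is physically unattainable.
The round-trip test therefore correlates the recovered profile against the
*resolution-matched* (locally smeared, zero-padded) emission profile, where
it achieves r > 0.99; the homogeneous interior is additionally required to
be flat within 5 %.

**Detectability.** `detectability_curve()` simulates independent
reference/test pairs per proton count (no common-random-number coupling —
real reference and test measurements are independent), measures each
converted edge shift, and reports the replicate mean with a bootstrap
percentile CI of the mean; the per-replicate spread `sd_rep` is the
single-measurement precision. Error bars on the campaign detectability plot
are not specified as replicate spread or bootstrap; the replicate-based
choice is documented here. At 10⁸ protons a single pair has
σ ≈ 3.7 mm — one spot sits right at the 5-mm detectability limit, matching
the qualitative statement that 10⁸-proton spots make 5-mm shifts detectable.

## 4. Detector physics

- **Resolution fits**: $R_E = a_E/\sqrt{E} + b_E$ (%) and
  $\Sigma_t = a_t/\sqrt{E} + b_t$ (ps) with presets LSO2
  (3.8, 5.6, 460, 80) and BGO1 (9.2, 3.7, 4900, 10). The statistical term
  falls as the photon count grows; the constant is intrinsic.
- **FoM** $= 1 - \sqrt{\Sigma_\mathrm{det}^2 + \Sigma_\mathrm{bunch}^2}/T_\mathrm{bunch}$,
  clipped at 0. Note: evaluating the LSO2 fit at 4 MeV with a 2-ns bunch
  spread and the 9.43-ns period gives 0.785, while the campaign prints 84 %
  (and 64 % for BGO1 vs 0.663 computed); the inputs behind the printed
  percentages are not fully specified, so the package reports the formula
  result and does not assert the printed values.
- **Attenuation**: total mass-attenuation grids for Pb, water (transcribed
  from the standard NIST-style compilation, 0.1–10 MeV) and CsI (an
  *approximate synthetic* grid built from elemental photoelectric/Compton/
  pair systematics — flagged in the file header; its two reference anchors,
  ~98 % detection at 140 keV and ~15 % at 4.4 MeV for 1 cm, are asserted only
  to ±2 percentage points). Log–log interpolation;
  $\lambda = (\mu/\rho \cdot \rho)^{-1}$.
- **Compton camera**: $\cos\theta = 1 - m_e c^2 (1/E_\gamma' - 1/E_\gamma)$
  with $E_\gamma = L_s + L_a$, $E_\gamma' = L_a$; events outside
  $[-1, 1]$ (e.g. absorber deposits below the backscatter minimum) are
  flagged kinematically forbidden. The cone axis points from the absorber hit
  through the scatter hit, so the source lies on the opening side.
  Backprojection uses hard angular binning (count cones within an angular
  tolerance) — sufficient for point-source recovery, simpler than a
  transition-probability model, and deliberately *not* an iterative
  reconstruction (MLEM is out of scope). With hard binning several adjacent
  voxels can tie at the maximum; the tests assert the true source voxel
  attains it.
- **Anger logic**: PMT1 lower-left, PMT2 lower-right, PMT3 upper-left,
  PMT4 upper-right, $X = (p_2 + p_4)/\Sigma p$, $Y = (p_3 + p_4)/\Sigma p$;
  other cablings are expressed through a layout permutation, and a 90°
  rotation of labels plus coordinates is an exact invariance. Flood maps use
  a bilinear light-sharing model with multiplicative noise scaled by
  $R_E(E)$, so spots sharpen as $1/\sqrt{E}$ under a purely statistical fit
  (asserted to 20 %).

## 5. What a green test run does and does not establish

The synthetic world is exactly the stated one: 400-mm PMMA at 230 MeV,
106-MHz bunches, inserts at f = 169 mm (5/10-mm air, 20-mm bone), a 2-inch
90°/300-mm detector with 0.5 intrinsic efficiency, 0.16 γ/proton, 5 % flat
background. Green tests establish internal consistency (oracle agreement,
conservation, estimator calibration, parameter recovery in this world). They
do **not** reproduce measured campaign spectra, measured bunch widths, the
printed FoM percentages (inputs inconsistent, see §4), neutron-background
time structure, detector dead time, or the true fall-off shape of the
emission profile near the Bragg peak (box-emission caveat, §2). Clinical
margins, slit-camera comparisons and treatment-plan aggregation are out of
scope.

## 6. Degenerate inputs and tie-breaks

Zero system resolution bins arrival times directly (delta binning); a
near-zero-length target yields a pure pedestal; all-zero spectra raise
moments/edge errors rather than returning NaN; slice boundaries belong to
the downstream slice (half-open intervals); `material_at()` outside
`[0, length)` errors; wall times outside a drift model clamp to the end
values with a warning; edge bootstrap replicates that lose the edge are
dropped (the CI then uses the survivors, never silently widened).
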