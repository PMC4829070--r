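# pgtsim — prompt gamma-ray timing simulation for proton range verification

Proton beams stop at a well-defined depth (the Bragg peak), but anatomical
changes — an unexpected air cavity, a denser bone structure — shift that
stopping depth and force clinics to plan with conservative safety margins.
**Prompt gamma-ray timing (PGT)** verifies the range in vivo with a single
uncollimated fast scintillator: prompt gammas are emitted quasi-instantly
along the proton track, so their detection times relative to the accelerator
RF phase encode the proton transit time plus the gamma time of flight, and
therefore the depth of emission.

`pgtsim` is a desk-scale simulator and analysis toolkit for this method,
aimed at medical physicists studying detector requirements and shift
detectability. It covers:

- **CSDA proton transport** in heterogeneous layered phantoms
  (PMMA / air / cortical bone / water). Energy loss follows
  dE/dz = −ρ(z) S(E) with a water-calibrated Bragg–Kleeman range law
  R(E) = α E^p (p = 1.77, R(230 MeV) = 330 mm water); velocity is the
  relativistic v(E) = c √(1 − (1 + E/m_p c²)^−2) and transit time
  t_p(z) = ∫ dz′/v(E(z′)), evaluated by adaptive quadrature in the energy
  variable. Per-material (E, S) tables can override the analytic model.
- **PGT spectra**: the analytic "box-emission" forward model
  Φ(t) = ∫ ε(z) w(z) g(t − t_arr(z); Σ_sys) dz with ε(z) ∝ ρ(z), solid-angle
  sensitivity w(z), Gaussian system resolution
  Σ_sys = √(Σ_det² + Σ_bunch²), wrap-around modulo the bunch period
  T_bunch = 1/f_bunch, a flat background pedestal — and its Monte Carlo twin
  (Poisson statistics, seeded, with wall-clock stamps so accelerator phase
  drifts can be injected).
- **Range-shift analysis**: spectrum moments, trailing-edge localization
  (50 %-of-plateau crossing via a local linear fit of the falling flank),
  time→depth inversion with sensitivity / Jacobian / background corrections,
  and detectability-vs-statistics curves with bootstrap confidence
  intervals.
- **Detector physics**: empirical resolution fits
  R_E = a/√E + b and Σ_t = a_t/√E + b_t for LSO and BGO block detectors, the
  background-suppression figure of merit
  FoM_BSR = 1 − √(Σ_t,det² + Σ_t,bunch²)/T_bunch, photon attenuation tables
  (Pb, CsI, water), Compton kinematics
  cos θ = 1 − m_e c² (1/E_γ′ − 1/E_γ) with cone backprojection, and
  Anger-logic flood-map simulation.

## Worked example: detecting a 5-mm air cavity

A 230-MeV pencil beam (106-MHz bunches, 10⁸ protons) hits a full 400-mm PMMA
cylinder; a 2-inch detector sits at 90° and 300 mm. The second phantom hides
a 5-mm air cavity 169 mm behind the front face — a 5-mm overshoot.

```r
library(pgtsim)
fx  <- make_fixture("wpe_homogeneous_230")
cav <- make_fixture("wpe_cavity_5mm")

ref <- sample_events(fx$phantom,  fx$beam,  fx$detector,  seed = 1)$spectrum
tst <- sample_events(cav$phantom, cav$beam, cav$detector, seed = 2)$spectrum
ref
#> <PGT spectrum: 100 bins over [0, 9.434] ns, total 1.364e+04 counts>

m <- spectrum_moments(ref)
#> integral 12702 counts, mean 1.985 ns, sd 0.530 ns
trailing_edge(ref)
#> 2.782 ns

edge_shift(ref, tst, fx$phantom, fx$beam, fx$detector,
           phantom_test = cav$phantom, seed = 1)
#> <edge shift: delta_t = 0.02634 ns, delta_z = 3.42 mm [-1.65, 10.7]>
```

About 1.4 × 10⁴ gammas are detected per 10⁸ protons (0.16 γ/proton, ~1.8 × 10⁻³
solid-angle fraction, 50 % intrinsic efficiency, 5 % flat background). The
cavity delays the spectrum's falling edge by a few tens of picoseconds; the
local derivative of arrival time at the cavity depth converts that into
millimetres of range shift. A *single* spectrum pair is noisy (here 3.4 mm
with a wide bootstrap CI — one measurement at 10⁸ protons sits right at the
detectability limit); averaging replicate pairs recovers the true 5 mm:

```r
detectability_curve(fx$phantom, cav$phantom, fx$beam, fx$detector,
                    n_grid = 1e8, replicates = 100, seed = 20)
#>   n_protons delta_t delta_z ci_low ci_high sd_rep replicates
#> 1     1e+08 0.04165   5.403  4.686   6.134  3.741        100
```

Detector-side quantities:

```r
fom_bsr(time_resolution("LSO2", 4) / 1000, 2, 1000 / 106)  # 0.785
attenuation_fraction("Pb", 0.2, 0.140)                     # 99.6 %
```

## Command line

```sh
inst/cli/pgt simulate --phantom wpe_homogeneous_230 --seed 1 -o ref.tsv
inst/cli/pgt simulate --phantom wpe_cavity_5mm     --seed 2 -o tst.tsv
inst/cli/pgt analyze ref.tsv --phantom wpe_homogeneous_230
inst/cli/pgt compare ref.tsv tst.tsv --phantom wpe_homogeneous_230 \
    --phantom-test wpe_cavity_5mm
inst/cli/pgt detector fom --preset LSO2 --energy 4 --bunch-fwhm 2 --period 9.434
```

Phantoms can also be plain-text files (`material thickness_mm` per line) and
scenes YAML-style config files (see `load_config()`).

## Documentation

The methods vignette (`vignettes/pgt-methods.Rmd`) documents the model
assumptions, parameter choices, numerical tolerances and known limitations.
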