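test_that("arrival time combines transit time and gamma time of flight", {
  cc <- pgt_constants()$c
  ph <- phantom_homogeneous("pmma", 400)
  beam <- beam_spec(230)
  # perpendicular detector aimed at the front face: TOF is exactly d/c at z=0
  det <- detector_spec(alpha = 90, d = 300, z_ref = 0)
  expect_equal(arrival_time(ph, beam, det, 0), 300 / cc, tolerance = 1e-12)
  # explicit Euclidean oracle at an oblique angle
  det2 <- detector_spec(alpha = 60, d = 450, z_ref = 120)
  z <- 87
  pos <- c(450 * sin(pi / 3), 0, 120 + 450 * cos(pi / 3))
  oracle <- transit_time(ph, 230, z) + sqrt(sum((pos - c(0, 0, z))^2)) / cc
  expect_equal(arrival_time(ph, beam, det2, z), oracle, tolerance = 1e-12)
})

test_that("emission density reflects local density and stops at the range", {
  beam <- beam_spec(230)
  p0 <- phantom_homogeneous("pmma", 400)
  R <- csda_range(p0, 230)
  z <- seq(0, 399, by = 1)
  eps <- emission_density(p0, 230, z)
  expect_true(all(eps[z < R] == eps[1]))      # box profile
  expect_true(all(eps[z > R] == 0))
  pc <- phantom_with_insert("pmma", 400, "air", f = 169, h = 5)
  ratio <- emission_density(pc, 230, 171) / emission_density(pc, 230, 100)
  expect_equal(ratio, 1.204e-3 / 1.19, tolerance = 1e-9)  # production deficit
  pb <- phantom_with_insert("pmma", 400, "cortical_bone", f = 169, h = 20)
  expect_equal(emission_density(pb, 230, 171) / emission_density(pb, 230, 100),
               1.85 / 1.19, tolerance = 1e-9)              # production excess
})

test_that("sensitivity is the far-field solid-angle fraction", {
  ph <- phantom_homogeneous("pmma", 400)
  det <- detector_spec(alpha = 90, d = 300, z_ref = 200, radius = 25.4)
  # 2-inch face at 300 mm, closest approach
  expect_equal(sensitivity(ph, det, 200), 25.4^2 / (4 * 300^2),
               tolerance = 1e-12)
  # inverse square in distance
  det2 <- detector_spec(alpha = 90, d = 600, z_ref = 200, radius = 25.4)
  expect_equal(sensitivity(ph, det2, 200), sensitivity(ph, det, 200) / 4,
               tolerance = 1e-12)
  # symmetric about the ring centre at 90 degrees
  expect_equal(sensitivity(ph, det, 150), sensitivity(ph, det, 250),
               tolerance = 1e-12)
  expect_error(detector_spec(alpha = 90, d = 20, z_ref = 200, radius = 25.4),
               "exceed")
  det4 <- det; det4$radius <- 350   # bypass the constructor guard
  expect_error(sensitivity(ph, det4, 200), "radius")
})

test_that("a thin target produces a single Gaussian line at the right place", {
  ph <- phantom_homogeneous("pmma", 1)
  beam <- beam_spec(230, n_protons = 1e8)
  det <- detector_spec(alpha = 90, d = 300, z_ref = 0.5, sigma_det = 0.3)
  fw <- forward_model(ph, beam, det)   # shoot-through target
  sp <- expected_spectrum(ph, beam, det, bins = 400, background_frac = 0,
                          forward = fw)
  tc <- bin_centers(sp)
  t0 <- arrival_time(ph, beam, det, 0.5)
  sd <- system_sigma(beam, det) / (2 * sqrt(2 * log(2)))
  gauss <- sum(sp$counts) * diff(sp$bin_edges[1:2]) * dnorm(tc, t0, sd)
  expect_gt(cor(sp$counts, gauss), 0.9999)
  m <- spectrum_moments(sp, window = seq_along(sp$counts))
  expect_equal(m$mean, t0, tolerance = 0.02 / t0)
  expect_equal(m$sd, sd, tolerance = 0.05)
})

test_that("stacked targets grow the spectrum area and shift its mean to later times", {
  beam <- beam_spec(230, n_protons = 1e8)
  det <- detector_spec(alpha = 90, d = 300, z_ref = 150)
  thicknesses <- c(100, 200, 300, 400)
  stats <- lapply(thicknesses, function(L) {
    ph <- phantom_homogeneous("pmma", L)
    fw <- suppressWarnings(forward_model(ph, beam, det))
    sp <- expected_spectrum(ph, beam, det, background_frac = 0, forward = fw)
    spectrum_moments(sp)
  })
  areas <- vapply(stats, `[[`, numeric(1), "integral")
  means <- vapply(stats, `[[`, numeric(1), "mean")
  # strict growth while the target still intercepts new track...
  expect_true(all(diff(areas[1:3]) > 0))
  expect_true(all(diff(means[1:3]) > 0))
  # ...and exact saturation once the protons stop inside (300 vs 400 mm)
  expect_lt(abs(areas[4] - areas[3]) / areas[3], 1e-9)
  expect_lt(abs(means[4] - means[3]), 1e-9)
})

test_that("expected spectrum conserves counts under wrap-around", {
  fx <- make_fixture("wpe_homogeneous_230")
  fw <- forward_model(fx$phantom, fx$beam, fx$detector)
  wrapped <- expected_spectrum(fx$phantom, fx$beam, fx$detector, forward = fw)
  wide <- expected_spectrum(fx$phantom, fx$beam, fx$detector,
                            bins = seq(-20, 30, by = 0.05), wrap = FALSE,
                            background_frac = 0, forward = fw)
  expect_equal(sum(wrapped$counts),
               fw$mean_detected / (1 - 0.05), tolerance = 1e-6)
  expect_equal(sum(wide$counts), fw$mean_detected, tolerance = 1e-6)
})

test_that("a near-zero-length target yields background only", {
  ph <- phantom_homogeneous("pmma", 1e-6)
  beam <- beam_spec(230, n_protons = 1e8)
  det <- detector_spec(z_ref = 0)
  sp <- suppressWarnings(
    expected_spectrum(ph, beam, det, background_frac = 0.05))
  # essentially flat pedestal: residual signal structure is < 1e-3 counts
  expect_lt(max(sp$counts) - min(sp$counts), 1e-3)
})

test_that("Monte Carlo sampling is Poisson-consistent with the analytic model", {
  fx <- make_fixture("wpe_homogeneous_230")
  fw <- forward_model(fx$phantom, fx$beam, fx$detector)
  # closed-form mean: n_p * yield * <w> * eff (w nearly constant here)
  expect_equal(fw$mean_detected,
               1e8 * 0.16 * fw$int_epsw / fw$int_eps * 0.5, tolerance = 1e-12)
  expect_gt(fw$mean_detected, 1.1e4)
  expect_lt(fw$mean_detected, 1.6e4)
  s <- sample_events(fx$phantom, fx$beam, fx$detector, seed = 9, forward = fw)
  n_exp <- fw$mean_detected / (1 - 0.05)
  expect_lt(abs(nrow(s$events) - n_exp), 4 * sqrt(n_exp))
  # identical event lists for a fixed seed
  s2 <- sample_events(fx$phantom, fx$beam, fx$detector, seed = 9, forward = fw)
  expect_identical(s$events, s2$events)
  s3 <- sample_events(fx$phantom, fx$beam, fx$detector, seed = 10, forward = fw)
  expect_false(identical(s$events$time, s3$events$time))
  # chi-square compatibility with the expected spectrum
  es <- expected_spectrum(fx$phantom, fx$beam, fx$detector, forward = fw)
  chi2 <- sum((s$spectrum$counts - es$counts)^2 / pmax(es$counts, 1e-9))
  df <- length(es$counts)
  expect_gt(stats::pchisq(chi2, df, lower.tail = FALSE), 0.001)
})

test_that("phase drifts translate and broaden spectra as expected", {
  fx <- make_fixture("wpe_homogeneous_230")
  fw <- forward_model(fx$phantom, fx$beam, fx$detector)
  s <- sample_events(fx$phantom, fx$beam, fx$detector, seed = 4, forward = fw)
  tb <- fx$beam$t_bunch
  # zero drift is the identity
  ev0 <- apply_drift(s$events, drift_model(c(0, 1), c(0, 0)), tb)
  expect_equal(ev0$time, s$events$time, tolerance = 1e-15)
  # constant offset shifts the mean by exactly the offset (mod T)
  evc <- apply_drift(s$events, drift_model(c(0, 1), c(0.5, 0.5)), tb)
  m0 <- spectrum_moments(s$spectrum)
  mc <- spectrum_moments(events_to_spectrum(evc, tb))
  expect_equal((mc$mean - m0$mean) %% tb, 0.5, tolerance = 0.02)
  # a linear drift across the run broadens the merged spectrum
  evl <- apply_drift(s$events, drift_model(c(0, 1), c(-0.6, 0.6)), tb)
  ml <- spectrum_moments(events_to_spectrum(evl, tb))
  drift_var <- 1.2^2 / 12
  expect_gt(ml$sd^2, m0$sd^2 + 0.5 * drift_var)
  # out-of-domain wall times warn and clamp
  expect_warning(apply_drift(s$events, drift_model(c(2, 3), c(0, 0)), tb),
                 "outside")
})

test_that("seed fan-out is deterministic and stage-independent", {
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
  expect_false(derive_seed(7, 3) == derive_seed(7, 4))
  expect_true(all(vapply(0:50, function(s) derive_seed(123456, s),
                         integer(1)) < 2^31))
})
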