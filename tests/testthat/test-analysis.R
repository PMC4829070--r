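test_that("moments: delta bin, Gaussian recovery, undefined cases", {
  edges <- seq(0, 10, length.out = 101)
  counts <- numeric(100); counts[37] <- 500
  sp <- pgt_spectrum(edges, counts, meta = list(t_bunch = 10))
  m <- spectrum_moments(sp)
  expect_equal(m$mean, (edges[37] + edges[38]) / 2, tolerance = 1e-12)
  expect_identical(m$sd, 0)
  # Gaussian-shaped counts reproduce the generating parameters
  tc <- (edges[-1] + edges[-101]) / 2
  g <- pgt_spectrum(edges, 1e4 * dnorm(tc, 4.2, 0.5), meta = list(t_bunch = 10))
  mg <- spectrum_moments(g, window = seq_len(100))
  expect_equal(mg$mean, 4.2, tolerance = 0.02)
  expect_equal(mg$sd, 0.5, tolerance = 0.02)
  expect_error(spectrum_moments(pgt_spectrum(edges, numeric(100))), "all-zero")
})

test_that("background subtraction removes a known pedestal and guards its window", {
  edges <- seq(0, 10, length.out = 101)
  tc <- (edges[-1] + edges[-101]) / 2
  # pedestal-only spectrum comes back all zero
  flat <- pgt_spectrum(edges, rep(7, 100), meta = list(t_bunch = 10))
  expect_identical(sum(subtract_background(flat, c(0, 2))$counts), 0)
  # signal plus known pedestal: integral drops by pedestal * n_bins
  sig <- 1e3 * dnorm(tc, 5, 0.4) + 20
  sp <- pgt_spectrum(edges, sig, meta = list(t_bunch = 10))
  out <- subtract_background(sp, c(0.05, 2))
  expect_equal(sum(out$counts), sum(sig) - 20 * 100, tolerance = 1e-6)
  # a window overlapping the signal support is rejected
  expect_error(subtract_background(sp, c(4.5, 5.5)), "overlaps")
  expect_error(subtract_background(sp, c(20, 30)), "no bins")
})

test_that("trailing edge: noiseless step, erf-smeared box, translation equivariance", {
  edges <- seq(0, 10, length.out = 101)
  w <- diff(edges[1:2])
  counts <- c(rep(100, 40), rep(0, 60))
  sp <- pgt_spectrum(edges, counts, meta = list(t_bunch = 10))
  # midpoint of the 50% crossing segment = the step boundary
  expect_equal(trailing_edge(sp), edges[41], tolerance = 1e-9)
  # Gaussian-smeared box: the half-height point sits at the box end
  tc <- (edges[-1] + edges[-101]) / 2
  Sig <- 0.4                       # FWHM of the smearing
  sd <- Sig / (2 * sqrt(2 * log(2)))
  box <- 100 * (pnorm((tc - 1) / sd) - pnorm((tc - 6.5) / sd))
  spb <- pgt_spectrum(edges, box, meta = list(t_bunch = 10))
  expect_equal(trailing_edge(spb), 6.5, tolerance = 0.02 * Sig)
  # integer-bin circular shift moves the edge by exactly the shift
  k <- 17
  shifted <- pgt_spectrum(edges, c(tail(box, k), head(box, 100 - k)),
                          meta = list(t_bunch = 10))
  expect_equal((trailing_edge(shifted) - trailing_edge(spb)) %% 10, k * w,
               tolerance = 1e-9)
  # wrap-around: a box crossing the period boundary is still found
  k2 <- 60
  wrapped <- pgt_spectrum(edges, c(tail(box, k2), head(box, 100 - k2)),
                          meta = list(t_bunch = 10))
  expect_equal((trailing_edge(wrapped) - trailing_edge(spb)) %% 10, k2 * w,
               tolerance = 1e-9)
  expect_error(trailing_edge(pgt_spectrum(edges, rep(5, 100))), "edge not found")
  # sigmoid refinement stays close to the crossing estimate
  expect_equal(trailing_edge(spb, method = "sigmoid"), 6.5, tolerance = 0.05)
})

test_that("edge shift: null case, noiseless cavity recovery, bone undershoot", {
  fx0 <- make_fixture("wpe_homogeneous_230")
  fxc <- make_fixture("wpe_cavity_5mm")
  fxb <- make_fixture("wpe_bone_20mm")
  e0 <- expected_spectrum(fx0$phantom, fx0$beam, fx0$detector)
  sh0 <- edge_shift(e0, e0, fx0$phantom, fx0$beam, fx0$detector, n_boot = 0)
  expect_identical(sh0$delta_t, 0)
  expect_identical(sh0$delta_z, 0)
  ec <- expected_spectrum(fxc$phantom, fxc$beam, fxc$detector)
  shc <- edge_shift(e0, ec, fx0$phantom, fx0$beam, fx0$detector,
                    phantom_test = fxc$phantom, n_boot = 50, seed = 2)
  expect_gt(shc$delta_z, 4.5); expect_lt(shc$delta_z, 5.5)
  expect_identical(shc$z_shift, 169)
  expect_true(shc$ci_low <= shc$delta_z && shc$delta_z <= shc$ci_high)
  eb <- expected_spectrum(fxb$phantom, fxb$beam, fxb$detector)
  shb <- edge_shift(e0, eb, fx0$phantom, fx0$beam, fx0$detector,
                    phantom_test = fxb$phantom, n_boot = 0)
  expect_lt(shb$delta_z, -4)   # undershoot, about -7 mm water-equivalent excess
  expect_error(edge_shift(e0, pgt_spectrum(seq(0, 5, length.out = 51),
                                           rep(1, 50)),
                          fx0$phantom, fx0$beam, fx0$detector),
               "share binning")
})

test_that("time-to-depth: flat box recovery, bump localization, degenerate input", {
  fx <- sharp_scene()
  e0 <- expected_spectrum(fx$phantom, fx$beam, fx$detector, bins = 600,
                          background_frac = 0)
  pr <- time_to_depth(e0, fx$phantom, fx$beam, fx$detector, dz = 2)
  R <- csda_range(fx$phantom, 230)
  zc <- (pr$z_bin_edges[-1] + pr$z_bin_edges[-length(pr$z_bin_edges)]) / 2
  interior <- pr$intensity[zc > 5 & zc < R - 10]
  expect_lt(stats::sd(interior) / mean(interior), 0.05)
  # bone insert appears as a bump within [f, f+h]
  fxb <- sharp_scene("wpe_bone_20mm")
  eb <- expected_spectrum(fxb$phantom, fxb$beam, fxb$detector, bins = 600,
                          background_frac = 0)
  prb <- time_to_depth(eb, fxb$phantom, fxb$beam, fxb$detector, dz = 2)
  zcb <- (prb$z_bin_edges[-1] + prb$z_bin_edges[-length(prb$z_bin_edges)]) / 2
  zmax <- zcb[which.max(prb$intensity)]
  expect_gt(zmax, 169); expect_lt(zmax, 189)
  # zero-count spectrum gives a zero profile
  z0 <- pgt_spectrum(e0$bin_edges, numeric(length(e0$counts)),
                     meta = e0$meta)
  pr0 <- time_to_depth(z0, fx$phantom, fx$beam, fx$detector)
  expect_identical(sum(pr0$intensity), 0)
})

test_that("time-to-depth round trip recovers the resolution-matched emission profile", {
  # 200-ps FWHM system: the 20-mm bone insert is at the resolution limit, so
  # the recovered shape is compared against the emission density smeared with
  # the local time-resolution kernel mapped to depth
  fxb <- sharp_scene("wpe_bone_20mm", sigma_bunch = 0.141, sigma_det = 0.141)
  eb <- expected_spectrum(fxb$phantom, fxb$beam, fxb$detector, bins = 400,
                          background_frac = 0)
  prb <- time_to_depth(eb, fxb$phantom, fxb$beam, fxb$detector, dz = 2)
  zcb <- (prb$z_bin_edges[-1] + prb$z_bin_edges[-length(prb$z_bin_edges)]) / 2
  Rb <- csda_range(fxb$phantom, 230)
  fw <- forward_model(fxb$phantom, fxb$beam, fxb$detector)
  sd_t <- system_sigma(fxb$beam, fxb$detector) / (2 * sqrt(2 * log(2)))
  dzdt <- stats::approxfun(fw$z, c(diff(fw$z) / diff(fw$t_arr),
                                   utils::tail(diff(fw$z) / diff(fw$t_arr), 1)),
                           rule = 2)
  zext <- seq(-60, Rb + 60, by = 0.2)
  eps_ext <- ifelse(zext >= 0 & zext < Rb,
                    emission_density(fxb$phantom, 230,
                                     pmin(pmax(zext, 0), Rb * 0.999999)), 0)
  eps_sm <- vapply(zcb, function(z0) {
    w <- stats::dnorm(zext, z0, sd_t * dzdt(z0))
    sum(w * eps_ext) / sum(w)
  }, numeric(1))
  keep <- zcb < Rb - 6
  expect_gt(stats::cor(prb$intensity[keep], eps_sm[keep]), 0.95)
})

test_that("detectability: null calibration and precision gain with statistics", {
  fx0 <- make_fixture("wpe_homogeneous_230")
  fxc <- make_fixture("wpe_cavity_5mm")
  tn <- detectability_curve(fx0$phantom, fx0$phantom, fx0$beam, fx0$detector,
                            n_grid = 1e8, replicates = 40, seed = 1)
  expect_true(tn$ci_low <= 0 && 0 <= tn$ci_high)
  expect_lt(abs(tn$delta_z), (tn$ci_high - tn$ci_low) / 2)
  tg <- detectability_curve(fx0$phantom, fxc$phantom, fx0$beam, fx0$detector,
                            n_grid = c(1e6, 1e8), replicates = 30, seed = 6)
  expect_true(all(tg$ci_low <= tg$delta_z & tg$delta_z <= tg$ci_high))
  # CI width shrinks with proton statistics
  expect_lt(tg$ci_high[2] - tg$ci_low[2], tg$ci_high[1] - tg$ci_low[1])
})
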