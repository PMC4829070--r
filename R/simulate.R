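# Forward PGT model: gamma emission density along the track, solid-angle
# sensitivity, arrival time (proton transit plus gamma time of flight),
# analytic expected spectra and their Monte Carlo twin.

#' Gamma arrival time for emission at depth z
#'
#' t(z) = t_p(z) + |r_det - (0,0,z)| / c: proton transit time to the emission
#' point plus the gamma time of flight to the detector front face centre.
#'
#' @param phantom A [layered_phantom()].
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()].
#' @param z Emission depth(s) in mm within `[0, range]`.
#' @return Arrival time(s) in ns (not wrapped).
#' @export
arrival_time <- function(phantom, beam, detector, z) {
  pos <- .detector_position(detector, phantom)
  transit_time(phantom, beam$E0, z) +
    sqrt(pos[1]^2 + pos[2]^2 + (pos[3] - z)^2) / .const$c
}

#' Relative prompt-gamma emission density at depth
#'
#' The "box" emission model generalized to heterogeneous targets:
#' epsilon(z) = rho(z) * yield_factor(z) per mm while the proton is moving,
#' 0 at and beyond the stopping depth. An air cavity therefore shows a
#' production deficit of order rho_air/rho_PMMA and a bone insert an excess
#' of rho_bone/rho_PMMA.
#'
#' @inheritParams arrival_time
#' @param E0 Initial proton energy in MeV.
#' @return Relative intensity per mm (vectorized over `z`).
#' @export
emission_density <- function(phantom, E0, z) {
  R <- suppressWarnings(csda_range(phantom, E0))
  out <- numeric(length(z))
  live <- z >= 0 & z < min(R, phantom$length)
  if (any(live)) {
    idx <- .slice_index(phantom, z[live])
    rho <- vapply(phantom$slices, function(s) s$material$rho, numeric(1))
    yf <- vapply(phantom$slices, function(s) s$material$yield_factor, numeric(1))
    out[live] <- rho[idx] * yf[idx]
  }
  out
}

#' Detector solid-angle fraction for emission at depth z
#'
#' Far-field approximation: w(z) = (pi r^2) / (4 pi D(z)^2) with D(z) the
#' distance from the emission point to the detector face centre.
#'
#' @inheritParams arrival_time
#' @return Dimensionless solid-angle fraction.
#' @export
sensitivity <- function(phantom, detector, z) {
  pos <- .detector_position(detector, phantom)
  D <- sqrt(pos[1]^2 + pos[2]^2 + (pos[3] - z)^2)
  if (any(D <= detector$radius))
    stop("emission point lies within one detector radius of the detector")
  detector$radius^2 / (4 * D^2)
}

#' Precompute the PGT forward model on a fine depth grid
#'
#' Caches arrival times, emission density and sensitivity on a fine grid over
#' `[0, range]`, plus derived quantities reused by [expected_spectrum()],
#' [sample_events()] and [time_to_depth()]. Building it once and passing it
#' explicitly speeds up replicate studies considerably.
#'
#' @inheritParams arrival_time
#' @param dz Grid step in mm (default 0.1).
#' @return A list of class `pgt_forward`.
#' @export
forward_model <- function(phantom, beam, detector, dz = 0.1) {
  # shoot-through targets are allowed: emission then spans the full length
  R <- suppressWarnings(csda_range(phantom, beam$E0))
  R <- min(R, phantom$length)
  # grid: uniform plus slice boundaries plus a refined tail near the range
  zg <- sort(unique(c(seq(0, R, by = dz),
                      phantom$boundaries[phantom$boundaries < R],
                      seq(max(0, R - 2), R, by = dz / 20), R)))
  E <- energy_at_depth(phantom, beam$E0, pmin(zg, R * (1 - 1e-12)))
  E <- pmax(E, .E_FLOOR)
  v <- velocity(E)
  # transit time by cumulative trapezoid of 1/v (dense grid), anchored by the
  # adaptive quadrature at the slice boundaries to remove accumulation error
  tp <- c(0, cumsum(diff(zg) * (1 / v[-1] + 1 / v[-length(v)]) / 2))
  anchors <- c(phantom$boundaries[phantom$boundaries > 0 & phantom$boundaries < R], R)
  if (length(anchors)) {
    ta <- transit_time(phantom, beam$E0, anchors)
    corr <- stats::approx(c(0, anchors), c(0, ta - tp[match(anchors, zg)]),
                          xout = zg, rule = 2)$y
    tp <- tp + corr
  }
  pos <- .detector_position(detector, phantom)
  D <- sqrt(pos[1]^2 + pos[2]^2 + (pos[3] - zg)^2)
  t_arr <- tp + D / .const$c
  eps <- emission_density(phantom, beam$E0, pmin(zg, R * (1 - 1e-12)))
  w <- detector$radius^2 / (4 * D^2)
  # expected detections per proton and mean over the emission profile
  seg <- diff(zg)
  mids <- function(x) (x[-1] + x[-length(x)]) / 2
  int_eps <- sum(mids(eps) * seg)
  int_epsw <- sum(mids(eps * w) * seg)
  # gamma_yield counts gammas over the FULL slowing-down track, so the
  # emission integral in the denominator refers to the whole track: for a
  # shoot-through target, extend it with the residual track in the last
  # slice's material (a thin target therefore intercepts proportionally
  # fewer gammas, and stacked targets grow the spectrum area)
  int_eps_track <- int_eps
  E_exit <- E[length(E)]
  if (E_exit > .E_FLOOR) {
    m_last <- phantom$slices[[length(phantom$slices)]]$material
    int_eps_track <- int_eps + .range_funs(m_last)$r(E_exit) *
      m_last$rho * m_last$yield_factor
  }
  mean_det <- beam$n_protons * beam$gamma_yield * detector$eff *
    int_epsw / int_eps_track
  list(phantom = phantom, beam = beam, detector = detector,
       range = R, z = zg, t_p = tp, t_arr = t_arr, eps = eps, w = w,
       int_eps = int_eps, int_epsw = int_epsw, mean_detected = mean_det,
       t_bunch = beam$t_bunch,
       sigma_sys = system_sigma(beam, detector),
       t_of_z = stats::approxfun(zg, t_arr),
       z_of_t = {
         keep <- c(TRUE, diff(t_arr) > 0)
         stats::approxfun(t_arr[keep], zg[keep])
       })
}

# fold a set of (time, weight) Gaussian kernels into uniform bins modulo T
.fold_gaussian <- function(times, weights, edges, sd, t_bunch, wrap = TRUE) {
  nb <- length(edges) - 1
  counts <- numeric(nb)
  ks <- if (wrap) seq(-ceiling((max(times) + 6 * sd) / t_bunch) - 1,
                      ceiling((max(times) + 6 * sd) / t_bunch) + 1) else 0
  for (k in ks) {
    tk <- times + k * t_bunch
    keep <- tk > edges[1] - 6 * sd - 1e-12 & tk < edges[nb + 1] + 6 * sd
    if (!any(keep)) next
    tk <- tk[keep]; wk <- weights[keep]
    if (sd > 0) {
      cdf <- stats::pnorm(outer(edges, tk, "-") / sd)
      counts <- counts + as.numeric((cdf[-1, , drop = FALSE] -
                                     cdf[-(nb + 1), , drop = FALSE]) %*% wk)
    } else {
      idx <- findInterval(tk, edges, rightmost.closed = TRUE)
      ok <- idx >= 1 & idx <= nb
      counts <- counts + as.numeric(tapply(wk[ok], factor(idx[ok], levels = 1:nb),
                                           sum, default = 0))
    }
  }
  counts
}

#' Analytic expected PGT spectrum
#'
#' Phi(t) = integral of eps(z) w(z) g(t - t_arr(z); Sigma_sys) dz, folded
#' modulo the bunch period, scaled so that the signal integral equals the
#' Poisson mean used by [sample_events()], plus a flat background pedestal.
#'
#' @inheritParams arrival_time
#' @param bins Number of uniform bins over one bunch period (default 100), or
#'   a numeric vector of bin edges in ns.
#' @param background_frac Flat background pedestal as a fraction of total
#'   counts (default 0.05).
#' @param wrap Fold times modulo the bunch period (default TRUE).
#' @param forward Optional precomputed [forward_model()].
#' @return A [pgt_spectrum()] of expected intensities.
#' @export
expected_spectrum <- function(phantom, beam, detector, bins = 100,
                              background_frac = 0.05, wrap = TRUE,
                              forward = NULL) {
  fw <- forward %||% forward_model(phantom, beam, detector)
  edges <- if (length(bins) == 1) seq(0, fw$t_bunch, length.out = bins + 1)
           else as.numeric(bins)
  seg <- diff(fw$z)
  mids <- function(x) (x[-1] + x[-length(x)]) / 2
  mass <- mids(fw$eps * fw$w) * seg
  tmid <- mids(fw$t_arr)
  scale <- fw$mean_detected / sum(mass)
  sd <- fw$sigma_sys / .FWHM
  counts <- .fold_gaussian(tmid, mass * scale, edges, sd, fw$t_bunch, wrap)
  n_sig <- fw$mean_detected
  bg_total <- n_sig * background_frac / (1 - background_frac)
  counts <- counts + bg_total / (length(edges) - 1)
  pgt_spectrum(edges, counts,
               meta = list(n_protons = beam$n_protons, t_bunch = fw$t_bunch,
                           wrapped = wrap, expected = TRUE,
                           background_frac = background_frac))
}

#' Monte Carlo PGT event sample
#'
#' The stochastic twin of [expected_spectrum()]: the number of detected
#' signal gammas is Poisson with the same mean, depths are drawn by inverse
#' CDF from eps(z) w(z), detection times get Gaussian timing jitter of FWHM
#' Sigma_sys and are wrapped to `[0, T_bunch)`; a Poisson number of flat
#' background events is admixed. Each event carries a wall-clock time stamp
#' (uniform over `duration_s`) so phase drifts can be injected afterwards.
#'
#' @inheritParams expected_spectrum
#' @param seed Integer seed; fixed seed implies an identical event list.
#' @param duration_s Wall-clock duration of the delivery in seconds.
#' @return A list with `events` (data frame: `time` ns phase, `wall_time` s,
#'   `background` logical) and `spectrum` (a [pgt_spectrum()]).
#' @export
sample_events <- function(phantom, beam, detector, seed, bins = 100,
                          background_frac = 0.05, duration_s = 1,
                          forward = NULL) {
  fw <- forward %||% forward_model(phantom, beam, detector)
  edges <- if (length(bins) == 1) seq(0, fw$t_bunch, length.out = bins + 1)
           else as.numeric(bins)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_sig <- stats::rpois(1, fw$mean_detected)
  # inverse-CDF depth sampling from eps(z) w(z) on the cached grid
  seg <- diff(fw$z)
  mids <- function(x) (x[-1] + x[-length(x)]) / 2
  pdf_seg <- mids(fw$eps * fw$w) * seg
  cdf <- c(0, cumsum(pdf_seg)) / sum(pdf_seg)
  u <- stats::runif(n_sig)
  iseg <- findInterval(u, cdf, rightmost.closed = TRUE)
  iseg <- pmin(pmax(iseg, 1), length(seg))
  frac <- (u - cdf[iseg]) / pmax(cdf[iseg + 1] - cdf[iseg], 1e-300)
  zs <- fw$z[iseg] + frac * seg[iseg]
  sdj <- fw$sigma_sys / .FWHM
  t_sig <- fw$t_of_z(zs) + stats::rnorm(n_sig, 0, sdj)
  bg_mean <- fw$mean_detected * background_frac / (1 - background_frac)
  n_bg <- stats::rpois(1, bg_mean)
  t_bg <- stats::runif(n_bg, 0, fw$t_bunch)
  tt <- c(t_sig, t_bg) %% fw$t_bunch
  events <- data.frame(time = tt,
                       wall_time = stats::runif(n_sig + n_bg, 0, duration_s),
                       background = rep(c(FALSE, TRUE), c(n_sig, n_bg)))
  counts <- .hist_counts(events$time, edges)
  spec <- pgt_spectrum(edges, counts,
                       meta = list(n_protons = beam$n_protons, seed = seed,
                                   t_bunch = fw$t_bunch, wrapped = TRUE,
                                   background_frac = background_frac))
  list(events = events, spectrum = spec)
}

#' Apply accelerator phase drift to an event list
#'
#' Shifts each detection phase by the piecewise-linear drift offset at its
#' wall time and re-wraps modulo the bunch period. Wall times outside the
#' drift domain are extrapolated with the end values (with a warning).
#'
#' @param events Event data frame from [sample_events()] (`time`,
#'   `wall_time`).
#' @param drift A [drift_model()].
#' @param t_bunch Bunch period in ns.
#' @return The event data frame with shifted, re-wrapped `time`.
#' @export
apply_drift <- function(events, drift, t_bunch) {
  stopifnot(inherits(drift, "pgt_drift"))
  wt <- events$wall_time
  if (any(wt < min(drift$wall_time) | wt > max(drift$wall_time)))
    warning("wall times outside the drift model domain; end values used")
  off <- if (length(drift$wall_time) == 1) rep(drift$offset, length(wt))
         else stats::approx(drift$wall_time, drift$offset, xout = wt, rule = 2)$y
  events$time <- (events$time + off) %% t_bunch
  events
}

#' Histogram an event list into a PGT spectrum
#'
#' @param events Event data frame with a `time` column (ns).
#' @param t_bunch Bunch period in ns.
#' @param bins Number of bins or edge vector.
#' @param meta Metadata list.
#' @export
events_to_spectrum <- function(events, t_bunch, bins = 100, meta = list()) {
  edges <- if (length(bins) == 1) seq(0, t_bunch, length.out = bins + 1)
           else as.numeric(bins)
  meta$t_bunch <- meta$t_bunch %||% t_bunch
  pgt_spectrum(edges, .hist_counts(events$time %% t_bunch, edges), meta)
}

# uniform-bin histogram counts (values outside the edges are dropped)
.hist_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1 & idx <= length(edges) - 1], length(edges) - 1)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out so that adding a pipeline stage never perturbs the
#' random stream of earlier stages; results stay below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage counter (non-negative integer).
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 1013904223) %%
               2147483647) + 1L
}
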