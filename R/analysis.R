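# Range information from PGT spectra: moments, trailing-edge localization,
# time-to-depth conversion, and shift detectability versus proton statistics.

# --- signal-window detection ------------------------------------------------
# The signal support is the contiguous (modulo wrap) region above 10% of the
# peak, provided a clear signal exists (peak > 1.5x the median bin). Returns
# integer bin indices in spectrum order plus the rotation used to unwrap.
.signal_window <- function(counts) {
  n <- length(counts)
  if (max(counts) <= 0) return(NULL)
  # a clear signal either towers above the median bin (a peak) or leaves a
  # genuinely empty floor somewhere (a wide box); a flat pedestal does neither
  if (max(counts) <= 1.5 * stats::median(counts) &&
      min(counts) >= 0.1 * max(counts)) return(NULL)
  above <- counts > 0.1 * max(counts)
  if (all(above)) return(list(idx = seq_len(n), rot = 0L))
  # rotate so the spectrum starts inside the below-threshold gap: find the
  # longest run of consecutive below-threshold bins (circularly)
  runs <- rle(rep(!above, 2))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values & starts <= n)
  len <- pmin(runs$lengths[cand], n)
  k <- cand[which.max(len)]
  rot <- (starts[k] - 1L) %% n  # rotate so the longest gap begins at position 1
  rotated <- counts[((seq_len(n) - 1L + rot) %% n) + 1L]
  ab <- rotated > 0.1 * max(rotated)
  first <- which(ab)[1]
  last <- max(which(ab))
  idx_rot <- first:last
  idx <- ((idx_rot - 1L + rot) %% n) + 1L
  list(idx = idx, rot = rot)
}

#' Detected signal window of a spectrum
#'
#' Contiguous region (modulo wrap-around) above 10% of the peak bin; `NULL`
#' when no clear signal is present.
#'
#' @param spectrum A [pgt_spectrum()].
#' @return Integer vector of bin indices, or `NULL`.
#' @export
signal_window <- function(spectrum) .signal_window(spectrum$counts)$idx

# --- moments ----------------------------------------------------------------

#' Moments of a PGT spectrum
#'
#' Background-subtracted integral, mean and standard deviation over the
#' signal window (auto-detected, or supplied as bin indices), computed on the
#' unwrapped time axis so a window crossing the period boundary is handled
#' correctly.
#'
#' @param spectrum A [pgt_spectrum()].
#' @param window Optional integer bin indices of the signal window.
#' @return Named list `integral`, `mean` (ns), `sd` (ns).
#' @export
spectrum_moments <- function(spectrum, window = NULL) {
  counts <- spectrum$counts
  if (sum(counts) <= 0) stop("moments are undefined for an all-zero spectrum")
  sw <- if (is.null(window)) .signal_window(counts) else list(idx = window, rot = 0L)
  if (is.null(sw)) stop("no signal window found (flat spectrum)")
  idx <- sw$idx
  n <- length(counts)
  t_b <- spectrum$meta$t_bunch %||% (max(spectrum$bin_edges) - min(spectrum$bin_edges))
  off <- setdiff(seq_len(n), idx)
  ped <- if (length(off)) mean(counts[off]) else 0
  cs <- pmax(counts[idx] - ped, 0)
  if (sum(cs) <= 0) stop("moments are undefined: no counts above background")
  ctr <- bin_centers(spectrum)[idx]
  # unwrap: make centres increasing along the (circular) window
  if (length(idx) > 1) {
    jumps <- c(0, cumsum(diff(idx) < 0))
    ctr <- ctr + jumps * t_b
  }
  m <- sum(cs * ctr) / sum(cs)
  v <- sum(cs * (ctr - m)^2) / sum(cs)
  list(integral = sum(cs), mean = m %% t_b, sd = sqrt(v))
}

#' Subtract a flat background pedestal estimated in an off-signal window
#'
#' @param spectrum A [pgt_spectrum()].
#' @param window Numeric length-2 phase interval `c(t0, t1)` in ns whose bins
#'   are used to estimate the pedestal; must not overlap the detected signal
#'   support.
#' @return The background-subtracted [pgt_spectrum()] (negative bins clipped
#'   to 0).
#' @export
subtract_background <- function(spectrum, window) {
  stopifnot(is.numeric(window), length(window) == 2)
  ctr <- bin_centers(spectrum)
  inwin <- ctr >= window[1] & ctr <= window[2]
  if (!any(inwin)) stop("background window contains no bins")
  sig <- .signal_window(spectrum$counts)
  if (!is.null(sig) && any(which(inwin) %in% sig$idx))
    stop("background window overlaps the signal support")
  ped <- mean(spectrum$counts[inwin])
  out <- spectrum
  out$counts <- pmax(spectrum$counts - ped, 0)
  out$meta$pedestal <- ped
  out
}

# --- trailing edge ----------------------------------------------------------

#' Locate the trailing (falling) edge of a PGT spectrum
#'
#' The plateau level is the median of the top quartile of bins inside the
#' signal window; the edge is where the counts cross 50% of the plateau on
#' the falling side, linearly interpolated between bin centres. For a
#' Gaussian-smeared box profile this estimator sits at the box end (erf
#' midpoint). An optional logistic-fit refinement is available.
#'
#' @param spectrum A [pgt_spectrum()].
#' @param method `"crossing"` (default) or `"sigmoid"` (logistic fit of the
#'   falling flank, falling back to the crossing on non-convergence).
#' @return Edge time in ns, modulo the bunch period.
#' @export
trailing_edge <- function(spectrum, method = c("crossing", "sigmoid")) {
  method <- match.arg(method)
  counts <- spectrum$counts
  n <- length(counts)
  t_b <- spectrum$meta$t_bunch %||% (max(spectrum$bin_edges) - min(spectrum$bin_edges))
  sw <- .signal_window(counts)
  if (is.null(sw)) stop("edge not found: no signal region in spectrum")
  rot <- sw$rot
  rc <- counts[((seq_len(n) - 1L + rot) %% n) + 1L]   # unwrapped ordering
  ab <- which(rc > 0.1 * max(rc))
  first <- ab[1]; last <- max(ab)
  seg <- rc[first:last]
  qtop <- sort(seg, decreasing = TRUE)[seq_len(max(1L, ceiling(length(seg) / 4)))]
  plateau <- stats::median(qtop)
  thr <- plateau / 2
  w <- .bin_width(spectrum)
  centers_rot <- (seq_len(n) - 0.5) * w  # centres in the rotated frame
  # falling flank: from the last bin still at >= 75% of the plateau to the
  # first subsequent bin at <= 25%; a local least-squares line through the
  # flank is solved at the 50% level. On a noiseless step or an erf-smeared
  # box this reduces to the midpoint crossing, but it is robust against
  # Poisson fluctuations in the low tail (a bare "last crossing" rule is
  # biased late by upward noise excursions there).
  hi <- which(rc >= 0.75 * plateau)
  if (!length(hi)) stop("edge not found: no plateau region")
  j_hi <- max(hi)
  # the fall may run off the end of the rotated frame straight into the
  # below-threshold gap; extend circularly by one bin so the first gap bin
  # can close the flank
  rc_ext <- c(rc, rc[1])
  centers_ext <- c(centers_rot, n * w + w / 2)
  lo_after <- which(rc_ext <= 0.25 * plateau)
  lo_after <- lo_after[lo_after > j_hi]
  if (!length(lo_after))
    stop("edge not found: spectrum does not fall below 25% of the plateau")
  j_lo <- min(lo_after)
  rc <- rc_ext
  centers_rot <- centers_ext
  flank <- j_hi:j_lo
  if (length(flank) >= 2) {
    fit <- stats::lm.fit(cbind(1, centers_rot[flank]), rc[flank])
    slope <- fit$coefficients[2]
    tstar <- if (is.finite(slope) && slope < 0)
      (thr - fit$coefficients[1]) / slope
    else (centers_rot[j_hi] + centers_rot[j_lo]) / 2
    # guard against ill-conditioned fits far outside the flank
    if (tstar < centers_rot[j_hi] - w || tstar > centers_rot[j_lo] + w)
      tstar <- (centers_rot[j_hi] + centers_rot[j_lo]) / 2
  } else {
    tstar <- centers_rot[j_hi] + w / 2
  }
  if (method == "sigmoid") {
    # logistic fit over a wider window around the falling flank
    flank <- seq(max(first, j_hi - 10L), min(n, j_lo + 6L))
    df <- data.frame(x = centers_rot[flank], y = rc[flank])
    fit <- tryCatch(
      stats::nls(y ~ A / (1 + exp((x - x0) / s)), data = df,
                 start = list(A = plateau, x0 = tstar, s = w),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) tstar <- stats::coef(fit)[["x0"]]
  }
  as.numeric(tstar + rot * w + spectrum$bin_edges[1]) %% t_b
}

# smallest signed difference a - b modulo T, mapped into (-T/2, T/2]
.wrapped_diff <- function(a, b, t_bunch) {
  d <- (a - b) %% t_bunch
  if (d > t_bunch / 2) d <- d - t_bunch
  d
}

# --- edge shift and depth conversion ---------------------------------------

# dt/dz used to convert a trailing-edge time shift into a range shift: the
# transit-time part is evaluated at the depth where the perturbation sits
# (z_shift), the time-of-flight part at the reference range, because a
# heterogeneity at depth f delays all later emission by dz/v(E(f)) while the
# stopping point itself moves by dz.
.edge_time_derivative <- function(phantom, beam, detector, z_shift, R) {
  E_s <- energy_at_depth(phantom, beam$E0, min(z_shift, R * (1 - 1e-9)))
  E_s <- max(E_s, .E_FLOOR)
  pos <- .detector_position(detector, phantom)
  zed <- min(R, phantom$length * (1 - 1e-12))
  Ddist <- sqrt(pos[1]^2 + pos[2]^2 + (pos[3] - zed)^2)
  1 / velocity(E_s) + (zed - pos[3]) / (Ddist * .const$c)
}

#' Trailing-edge shift between two spectra, converted to a range shift
#'
#' `delta_t` is the wrapped difference of the [trailing_edge()] positions;
#' `delta_z` divides it by the local derivative of arrival time with respect
#' to a range perturbation. When `phantom_test` is supplied, the perturbation
#' depth is auto-located with [first_divergence()]; otherwise `z_shift`
#' (default: the reference range) is used. A percentile bootstrap CI is
#' computed by Poisson-resampling both histograms.
#'
#' @param reference,test Two [pgt_spectrum()] objects with identical binning.
#' @param phantom Reference [layered_phantom()].
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()].
#' @param phantom_test Optional test phantom used to locate the perturbation
#'   depth.
#' @param z_shift Optional explicit perturbation depth in mm.
#' @param n_boot Bootstrap replicates (default 200); 0 disables the CI.
#' @param seed Seed for the bootstrap resampling.
#' @param method Edge estimator passed to [trailing_edge()].
#' @return A list of class `pgt_shift`: `delta_t` (ns), `delta_z` (mm),
#'   `ci_low`, `ci_high` (mm), `n_protons`.
#' @export
edge_shift <- function(reference, test, phantom, beam, detector,
                       phantom_test = NULL, z_shift = NULL, n_boot = 200,
                       seed = 1, method = "crossing") {
  if (length(reference$counts) != length(test$counts) ||
      abs(.bin_width(reference) - .bin_width(test)) > 1e-9)
    stop("reference and test spectra must share binning")
  t_b <- reference$meta$t_bunch %||%
    (max(reference$bin_edges) - min(reference$bin_edges))
  R <- csda_range(phantom, beam$E0)
  if (is.null(z_shift)) {
    z_shift <- if (!is.null(phantom_test))
      (first_divergence(phantom, phantom_test) %||% R) else R
  }
  deriv <- .edge_time_derivative(phantom, beam, detector, z_shift, R)
  one <- function(rc, tc) {
    r <- reference; r$counts <- rc
    t <- test; t$counts <- tc
    .wrapped_diff(trailing_edge(t, method), trailing_edge(r, method), t_b) / deriv
  }
  delta_t <- .wrapped_diff(trailing_edge(test, method),
                           trailing_edge(reference, method), t_b)
  delta_z <- delta_t / deriv
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    bz <- vapply(seq_len(n_boot), function(i) {
      tryCatch(one(stats::rpois(length(reference$counts), reference$counts),
                   stats::rpois(length(test$counts), test$counts)),
               error = function(e) NA_real_)
    }, numeric(1))
    bz <- bz[is.finite(bz)]
    if (length(bz) >= 10)
      ci <- unname(stats::quantile(bz, c(0.025, 0.975)))
  }
  structure(list(delta_t = delta_t, delta_z = delta_z,
                 ci_low = min(ci[1], delta_z), ci_high = max(ci[2], delta_z),
                 n_protons = reference$meta$n_protons %||% NA_real_,
                 z_shift = z_shift, deriv = deriv),
            class = "pgt_shift")
}

#' @export
print.pgt_shift <- function(x, ...) {
  cat(sprintf("<edge shift: delta_t = %.4g ns, delta_z = %.3g mm [%.3g, %.3g]>\n",
              x$delta_t, x$delta_z, x$ci_low, x$ci_high))
  invisible(x)
}

# --- time-to-depth conversion ----------------------------------------------

#' Convert a PGT spectrum into a depth profile
#'
#' Inverts the arrival-time map: for each depth bin, the background-
#' subtracted count density at t(z) is corrected for the detector solid
#' angle w(z) and the Jacobian of the time-depth map, recovering the
#' emission density eps(z) up to a global scale in the small-resolution
#' limit.
#'
#' @param spectrum A [pgt_spectrum()].
#' @param phantom,beam,detector Scene description (see [expected_spectrum()]).
#' @param dz Depth bin width in mm (default 2).
#' @param background Either `"auto"` (pedestal from off-signal bins),
#'   a numeric pedestal per bin, or `NULL` for none.
#' @param forward Optional precomputed [forward_model()].
#' @return A list of class `pgt_depth_profile`: `z_bin_edges` (mm),
#'   `intensity` (relative emission density), `meta`.
#' @export
time_to_depth <- function(spectrum, phantom, beam, detector, dz = 2,
                          background = "auto", forward = NULL) {
  fw <- forward %||% forward_model(phantom, beam, detector)
  if (any(diff(fw$t_arr) <= 0))
    stop("unsupported geometry: arrival time is not monotone in depth")
  counts <- spectrum$counts
  ped <- 0
  if (identical(background, "auto")) {
    sw <- .signal_window(counts)
    off <- if (is.null(sw)) seq_along(counts) else setdiff(seq_along(counts), sw$idx)
    ped <- if (length(off)) mean(counts[off]) else 0
  } else if (is.numeric(background)) ped <- background
  cs <- pmax(counts - ped, 0)
  w_t <- .bin_width(spectrum)
  dens <- stats::approxfun(bin_centers(spectrum), cs / w_t, rule = 2)
  edges_z <- seq(0, fw$range, by = dz)
  if (edges_z[length(edges_z)] < fw$range) edges_z <- c(edges_z, fw$range)
  zc <- (edges_z[-1] + edges_z[-length(edges_z)]) / 2
  t_z <- fw$t_of_z(zc)
  t_b <- fw$t_bunch
  # Jacobian dt/dz and sensitivity on the depth grid
  dtdz <- stats::approxfun(fw$z, c(diff(fw$t_arr) / diff(fw$z),
                                   utils::tail(diff(fw$t_arr) / diff(fw$z), 1)),
                           rule = 2)(zc)
  w_z <- stats::approxfun(fw$z, fw$w, rule = 2)(zc)
  intensity <- dens(t_z %% t_b) * dtdz / w_z
  intensity[!is.finite(intensity) | intensity < 0] <- 0
  structure(list(z_bin_edges = edges_z, intensity = intensity,
                 meta = list(corrections = c("background", "sensitivity",
                                             "jacobian"),
                             pedestal = ped, range = fw$range)),
            class = "pgt_depth_profile")
}

#' @export
print.pgt_depth_profile <- function(x, ...) {
  cat(sprintf("<depth profile: %d bins over [0, %.4g] mm>\n",
              length(x$intensity), max(x$z_bin_edges)))
  invisible(x)
}

# --- detectability ----------------------------------------------------------

#' Range-shift detectability versus proton statistics
#'
#' For each proton count in `n_grid`, simulates `replicates` independent
#' reference/test spectrum pairs with [sample_events()], measures the
#' converted edge shift of each pair, and reports the replicate mean with a
#' bootstrap percentile CI of the mean.
#'
#' @param phantom_ref,phantom_test Reference and perturbed phantoms.
#' @param beam,detector Scene description.
#' @param n_grid Numeric vector of proton counts.
#' @param replicates Replicate pairs per grid point (>= 30 recommended).
#' @param seed Global seed (fanned out per replicate with [derive_seed()]).
#' @param bins Spectrum binning.
#' @param background_frac Flat background fraction.
#' @param n_boot Bootstrap resamples of the replicate mean (default 1000).
#' @return Data frame with one row per `n_grid` entry: `n_protons`,
#'   `delta_t` (mean ns), `delta_z` (mean mm), `ci_low`, `ci_high` (mm),
#'   `sd_rep` (replicate spread, mm), `replicates`.
#' @export
detectability_curve <- function(phantom_ref, phantom_test, beam, detector,
                                n_grid, replicates = 30, seed = 1,
                                bins = 100, background_frac = 0.05,
                                n_boot = 1000) {
  if (replicates < 2) stop("need at least 2 replicates")
  R <- csda_range(phantom_ref, beam$E0)
  z_s <- first_divergence(phantom_ref, phantom_test) %||% R
  rows <- lapply(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    beam_n <- beam; beam_n$n_protons <- n
    fw_ref <- forward_model(phantom_ref, beam_n, detector)
    fw_tst <- forward_model(phantom_test, beam_n, detector)
    dz_rep <- numeric(0); dt_rep <- numeric(0)
    for (r in seq_len(replicates)) {
      s1 <- derive_seed(seed, gi * 10000L + 2L * r)
      s2 <- derive_seed(seed, gi * 10000L + 2L * r + 1L)
      ref <- sample_events(phantom_ref, beam_n, detector, seed = s1,
                           bins = bins, background_frac = background_frac,
                           forward = fw_ref)$spectrum
      tst <- sample_events(phantom_test, beam_n, detector, seed = s2,
                           bins = bins, background_frac = background_frac,
                           forward = fw_tst)$spectrum
      sh <- tryCatch(edge_shift(ref, tst, phantom_ref, beam_n, detector,
                                z_shift = z_s, n_boot = 0),
                     error = function(e) NULL)
      if (!is.null(sh)) { dz_rep <- c(dz_rep, sh$delta_z); dt_rep <- c(dt_rep, sh$delta_t) }
    }
    if (!length(dz_rep)) stop("edge finding failed for all replicates")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(seed, gi))
    bmeans <- vapply(seq_len(n_boot), function(i)
      mean(sample(dz_rep, replace = TRUE)), numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    ci <- unname(stats::quantile(bmeans, c(0.025, 0.975)))
    data.frame(n_protons = n, delta_t = mean(dt_rep), delta_z = mean(dz_rep),
               ci_low = ci[1], ci_high = ci[2],
               sd_rep = stats::sd(dz_rep), replicates = length(dz_rep))
  })
  do.call(rbind, rows)
}
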