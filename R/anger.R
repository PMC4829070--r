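# Anger logic for four-PMT block detectors and flood-map simulation.

#' Anger-logic block position from four PMT light shares
#'
#' Convention: PMT1 lower-left, PMT2 lower-right, PMT3 upper-left, PMT4
#' upper-right, so `X = (p2 + p4) / sum`, `Y = (p3 + p4) / sum`, both in
#' `[0, 1]`. A different physical cabling is expressed through `layout`, a
#' permutation giving which input channel sits at each of the four corners.
#'
#' @param p1,p2,p3,p4 Non-negative light shares (vectorized).
#' @param layout Integer permutation of 1:4 mapping corner position to input
#'   channel (default `1:4`, i.e. the documented convention).
#' @return List with `X` and `Y` in `[0, 1]`.
#' @examples
#' anger_position(1, 1, 1, 1)  # centre (0.5, 0.5)
#' @export
anger_position <- function(p1, p2, p3, p4, layout = 1:4) {
  p <- cbind(p1, p2, p3, p4)
  if (any(p < 0)) stop("light shares must be >= 0")
  tot <- rowSums(p)
  if (any(tot <= 0)) stop("zero total light")
  stopifnot(length(layout) == 4, all(sort(layout) == 1:4))
  q <- p[, layout, drop = FALSE]  # q[,k] = share at corner position k
  list(X = as.numeric((q[, 2] + q[, 4]) / tot),
       Y = as.numeric((q[, 3] + q[, 4]) / tot))
}

#' Simulate a block-detector flood map
#'
#' Events hit pixel centres of an `n_pixels x n_pixels` crystal array
#' uniformly; the four PMT light shares follow the bilinear light-sharing
#' model `p1 = (1-x)(1-y)`, `p2 = x(1-y)`, `p3 = (1-x)y`, `p4 = xy` with
#' multiplicative Gaussian noise whose relative width scales with the
#' photon-counting resolution [energy_resolution()] at energy `E` -- so
#' pixel spots sharpen with increasing gamma energy.
#'
#' @param n_pixels Pixels per side (>= 2).
#' @param E Gamma energy in MeV.
#' @param fit A [resolution_fit()] (or preset name).
#' @param n_events Number of events.
#' @param seed Integer seed.
#' @param n_bins Flood-map histogram bins per axis (default 128).
#' @return List of class `pgt_flood_map`: `map` (n_bins x n_bins matrix),
#'   `X`, `Y` (event positions), `pixel` (true pixel index per event),
#'   `n_pixels`, `E`.
#' @export
simulate_flood_map <- function(n_pixels, E, fit = "LSO2", n_events = 2e4,
                               seed = 1, n_bins = 128) {
  if (n_pixels < 2) stop("n_pixels must be >= 2")
  if (is.character(fit)) fit <- resolution_fit(fit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  px <- sample.int(n_pixels^2, n_events, replace = TRUE)
  ix <- (px - 1) %% n_pixels
  iy <- (px - 1) %/% n_pixels
  x <- (ix + 0.5) / n_pixels
  y <- (iy + 0.5) / n_pixels
  shares <- cbind((1 - x) * (1 - y), x * (1 - y), (1 - x) * y, x * y)
  sdrel <- energy_resolution(fit, E) / 100 / .FWHM
  noisy <- pmax(shares * (1 + matrix(stats::rnorm(4 * n_events, 0, sdrel),
                                     ncol = 4)), 0)
  bad <- rowSums(noisy) <= 0
  noisy[bad, ] <- shares[bad, ]
  pos <- anger_position(noisy[, 1], noisy[, 2], noisy[, 3], noisy[, 4])
  brk <- seq(0, 1, length.out = n_bins + 1)
  bx <- pmin(pmax(findInterval(pos$X, brk, rightmost.closed = TRUE), 1), n_bins)
  by <- pmin(pmax(findInterval(pos$Y, brk, rightmost.closed = TRUE), 1), n_bins)
  map <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bx, 1:n_bins), factor(by, 1:n_bins))
  map[] <- as.numeric(tab)
  structure(list(map = map, X = pos$X, Y = pos$Y, pixel = px,
                 n_pixels = n_pixels, E = E),
            class = "pgt_flood_map")
}

#' Mean spot FWHM of a simulated flood map
#'
#' Pools the per-pixel standard deviation of reconstructed X positions
#' (interior pixels only, to avoid edge clipping) and converts to FWHM;
#' used to quantify pixel discrimination power versus energy.
#'
#' @param fm A [simulate_flood_map()] result.
#' @return FWHM in block units.
#' @export
flood_spot_fwhm <- function(fm) {
  np <- fm$n_pixels
  ix <- (fm$pixel - 1) %% np
  iy <- (fm$pixel - 1) %/% np
  interior <- ix > 0 & ix < np - 1 & iy > 0 & iy < np - 1
  sds <- tapply(fm$X[interior], fm$pixel[interior], stats::sd)
  .FWHM * mean(sds, na.rm = TRUE)
}
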