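# Compton-camera primitives: kinematics, cones of response, backprojection,
# and a forward event generator used as an independent oracle.

#' Compton scattering angle from the two energy deposits
#'
#' With E_gamma = L_s + L_a and E_gamma' = L_a, the Compton relation gives
#' cos(theta) = 1 - m_e c^2 (1/E_gamma' - 1/E_gamma). Events whose cosine
#' falls outside `[-1, 1]` are kinematically forbidden (e.g. an absorber
#' deposit below the backscatter minimum) and flagged invalid.
#'
#' @param L_s Energy deposited in the scatterer (MeV, > 0); vectorized.
#' @param L_a Energy deposited in the absorber (MeV, > 0); vectorized.
#' @return List with `cos_theta` (numeric) and `valid` (logical).
#' @examples
#' compton_cos_theta(3.9422, 0.4578)$cos_theta  # ~0: a 90-degree scatter
#' @export
compton_cos_theta <- function(L_s, L_a) {
  if (any(L_s <= 0) || any(L_a <= 0))
    stop("invalid event: both energy deposits must be > 0")
  E <- L_s + L_a
  ct <- 1 - .const$m_e_c2 * (1 / L_a - 1 / E)
  list(cos_theta = ct, valid = ct >= -1 & ct <= 1)
}

#' Construct a two-plane Compton event
#'
#' @param r_s Scatterer interaction position (mm, length-3).
#' @param r_a Absorber interaction position (mm, length-3, distinct from
#'   `r_s`).
#' @param L_s,L_a Energy deposits in MeV (> 0).
#' @return An object of class `pgt_compton_event`.
#' @export
compton_event <- function(r_s, r_a, L_s, L_a) {
  stopifnot(length(r_s) == 3, length(r_a) == 3)
  if (L_s <= 0 || L_a <= 0) stop("invalid event: deposits must be > 0")
  if (sqrt(sum((r_s - r_a)^2)) < 1e-12)
    stop("invalid event: coincident interaction positions")
  structure(list(r_s = as.numeric(r_s), r_a = as.numeric(r_a),
                 L_s = L_s, L_a = L_a), class = "pgt_compton_event")
}

#' Cone of response of a Compton event
#'
#' Vertex at the scatter point; axis along the line from the absorber hit
#' through the scatter hit (anti-parallel to the scattered photon), so the
#' source lies on the cone's opening side; half-angle from
#' [compton_cos_theta()].
#'
#' @param event A [compton_event()].
#' @return An object of class `pgt_cone` with `vertex`, `axis` (unit) and
#'   `half_angle` (rad).
#' @export
cone_from_event <- function(event) {
  stopifnot(inherits(event, "pgt_compton_event"))
  k <- compton_cos_theta(event$L_s, event$L_a)
  if (!k$valid) stop("kinematically forbidden event (|cos theta| > 1)")
  ax <- event$r_s - event$r_a
  ax <- ax / sqrt(sum(ax^2))
  th <- acos(k$cos_theta)
  if (th <= 0 || th >= pi) stop("degenerate cone half-angle")
  structure(list(vertex = event$r_s, axis = ax, half_angle = th),
            class = "pgt_cone")
}

#' Rectangular backprojection grid
#'
#' A plane (2D) or box (3D) lattice of points at which cone intersections are
#' accumulated.
#'
#' @param xlim,ylim,zlim Coordinate ranges in mm; give `zlim = z0` (scalar)
#'   for a 2D plane at fixed z.
#' @param n Points per axis (scalar or per-axis vector).
#' @return List with `points` (matrix n_pts x 3), `dim`, and per-axis centre
#'   vectors.
#' @export
backprojection_grid <- function(xlim, ylim, zlim = 0, n = 51) {
  n <- rep(n, length.out = 3)
  ax <- function(lim, k) if (length(lim) == 1) lim else seq(lim[1], lim[2], length.out = k)
  xs <- ax(xlim, n[1]); ys <- ax(ylim, n[2]); zs <- ax(zlim, n[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  list(points = as.matrix(g), dim = c(length(xs), length(ys), length(zs)),
       x = xs, y = ys, z = zs)
}

#' Backproject Compton cones onto a grid
#'
#' Each grid point accumulates the number of cones for which the angle
#' between vertex-to-point direction and the cone axis lies within
#' `angular_tolerance` of the cone half-angle (hard angular binning).
#' Noiseless events from a point source maximize the map at the source.
#'
#' @param cones List of [cone_from_event()] objects (>= 1).
#' @param grid A [backprojection_grid()].
#' @param angular_tolerance Half-width of the angular acceptance window in
#'   radians (default 0.05).
#' @return Intensity array with dimensions `grid$dim` (trailing singleton
#'   dimensions dropped).
#' @export
backproject <- function(cones, grid, angular_tolerance = 0.05) {
  if (length(cones) < 1) stop("need at least one cone")
  if (is.null(grid$points) || nrow(grid$points) == 0) stop("empty grid")
  pts <- grid$points
  acc <- numeric(nrow(pts))
  for (cn in cones) {
    d <- sweep(pts, 2, cn$vertex)
    nrm <- sqrt(rowSums(d^2))
    ok <- nrm > 1e-9
    ang <- rep(Inf, nrow(pts))
    ang[ok] <- acos(pmin(1, pmax(-1, (d[ok, , drop = FALSE] %*% cn$axis) / nrm[ok])))
    acc <- acc + (abs(ang - cn$half_angle) <= angular_tolerance)
  }
  dm <- grid$dim[grid$dim > 1]
  if (length(dm) >= 2) array(acc, dm) else acc
}

#' Forward-simulate Compton events from a point source
#'
#' Independent oracle for cone reconstruction: photons of energy `E_gamma`
#' leave the `source`, scatter at random positions on a scatterer plane
#' through angles drawn uniformly in `theta_range`, and are absorbed at
#' distance `absorber_dist` along the scattered direction. Energies follow
#' the Compton relation exactly, optionally smeared with a
#' [resolution_fit()].
#'
#' @param source Source position (mm, length-3).
#' @param E_gamma Photon energy in MeV.
#' @param n Number of events.
#' @param seed Integer seed.
#' @param scatter_z z-coordinate of the scatterer plane (mm).
#' @param scatter_radius Radius of the illuminated scatterer area (mm).
#' @param absorber_dist Path length from scatter to absorption (mm).
#' @param theta_range Scattering-angle range in radians.
#' @param fit Optional [resolution_fit()] smearing both deposits (Gaussian,
#'   relative FWHM from [energy_resolution()]).
#' @return List of [compton_event()] objects with attribute `"theta"` (true
#'   scattering angles).
#' @export
simulate_compton_events <- function(source, E_gamma, n, seed = 1,
                                    scatter_z = -100, scatter_radius = 30,
                                    absorber_dist = 50,
                                    theta_range = c(0.2, 1.2), fit = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  me <- .const$m_e_c2
  events <- vector("list", n)
  thetas <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      r <- scatter_radius * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      r_s <- c(r * cos(phi), r * sin(phi), scatter_z)
      u <- r_s - source
      u <- u / sqrt(sum(u^2))
      th <- stats::runif(1, theta_range[1], theta_range[2])
      # scattered direction at angle th around u
      a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      psi <- stats::runif(1, 0, 2 * pi)
      w <- cos(th) * u + sin(th) * (cos(psi) * e1 + sin(psi) * e2)
      r_a <- r_s + absorber_dist * w
      Ep <- E_gamma / (1 + E_gamma / me * (1 - cos(th)))
      L_s <- E_gamma - Ep; L_a <- Ep
      if (!is.null(fit)) {
        sdrel <- energy_resolution(fit, c(L_s, L_a)) / 100 / .FWHM
        L_s <- L_s * (1 + stats::rnorm(1, 0, sdrel[1]))
        L_a <- L_a * (1 + stats::rnorm(1, 0, sdrel[2]))
      }
      if (L_s > 0 && L_a > 0) break
    }
    events[[i]] <- compton_event(r_s, r_a, L_s, L_a)
    thetas[i] <- th
  }
  attr(events, "theta") <- thetas
  events
}
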