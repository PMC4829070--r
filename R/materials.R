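# Materials and stopping power.
#
# The range-energy relation is the Bragg-Kleeman law R(E) = bk_alpha * E^bk_p,
# calibrated in water so that R(230 MeV) = 330 mm with p = 1.77. Other
# materials are water-referenced: their bk_alpha is the water coefficient
# divided by the linear relative stopping power (RSP), so that the residual
# range in any material follows the same power law. Air uses the water mass
# stopping power at its true (small) density.

.BK_P_WATER <- 1.77
.BK_ALPHA_WATER <- 330 / 230^1.77  # mm * MeV^(-1.77)

#' Define a material for proton transport and gamma emission
#'
#' @param name Identifier string.
#' @param rho Mass density in g/cm^3 (must be > 0; air uses its true small
#'   density, never zero).
#' @param bk_alpha Bragg-Kleeman coefficient in mm/MeV^`bk_p` for this
#'   material, i.e. the CSDA range of a proton of energy E in a homogeneous
#'   block of the material is `bk_alpha * E^bk_p`.
#' @param bk_p Bragg-Kleeman exponent, dimensionless, in (1, 2.2).
#' @param yield_factor Relative prompt-gamma emission per unit mass path
#'   (dimensionless, default 1): the emission density is
#'   `rho * yield_factor` per mm.
#' @param stopping_table Optional data frame with columns `E` (MeV) and `S`
#'   (mass stopping power, MeV cm^2/g) overriding the analytic model;
#'   interpolated log-log.
#' @return An object of class `pgt_material`.
#' @seealso [pgt_material()] for the built-in registry.
#' @export
material <- function(name, rho, bk_alpha, bk_p, yield_factor = 1,
                     stopping_table = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(rho) || rho <= 0)
    stop("material density 'rho' must be > 0 (use the true density of air, not zero)")
  if (!is.numeric(bk_p) || bk_p <= 1 || bk_p >= 2.2)
    stop("Bragg-Kleeman exponent 'bk_p' must lie in (1, 2.2)")
  if (bk_alpha <= 0) stop("'bk_alpha' must be > 0")
  if (yield_factor < 0) stop("'yield_factor' must be >= 0")
  if (!is.null(stopping_table)) {
    stopifnot(is.data.frame(stopping_table),
              all(c("E", "S") %in% names(stopping_table)))
    if (is.unsorted(stopping_table$E, strictly = TRUE))
      stop("stopping table energies must be strictly increasing")
    if (any(stopping_table$S <= 0)) stop("stopping table values must be > 0")
  }
  structure(list(name = name, rho = rho, bk_alpha = bk_alpha, bk_p = bk_p,
                 yield_factor = yield_factor, stopping_table = stopping_table),
            class = "pgt_material")
}

#' @export
print.pgt_material <- function(x, ...) {
  cat(sprintf("<material %s: rho = %g g/cm^3, R(E) = %.4g E^%.3g mm%s>\n",
              x$name, x$rho, x$bk_alpha, x$bk_p,
              if (is.null(x$stopping_table)) "" else ", tabulated S(E)"))
  invisible(x)
}

# registry of built-in materials; linear RSP values: PMMA 1.16, cortical
# bone 1.57, air = water mass stopping power at rho_air.
.material_registry <- function() {
  aw <- .BK_ALPHA_WATER
  p <- .BK_P_WATER
  list(
    water         = material("water", 1.000, aw, p),
    pmma          = material("pmma", 1.19, aw / 1.16, p),
    air           = material("air", 1.204e-3, aw / 1.204e-3, p),
    cortical_bone = material("cortical_bone", 1.85, aw / 1.57, p)
  )
}

#' Look up a built-in material
#'
#' Built-ins: `water`, `pmma`, `air` and `cortical_bone`.
#'
#' @param name Material name (case-insensitive).
#' @param registry Optional named list of extra [material()] objects searched
#'   first, so phantom files can reference user-defined materials.
#' @return A `pgt_material`.
#' @examples
#' pgt_material("pmma")$rho
#' @export
pgt_material <- function(name, registry = NULL) {
  if (inherits(name, "pgt_material")) return(name)
  key <- tolower(name)
  if (!is.null(registry) && key %in% tolower(names(registry)))
    return(registry[[match(key, tolower(names(registry)))]])
  reg <- .material_registry()
  if (!key %in% names(reg))
    stop(sprintf("unknown material '%s'; built-ins: %s", name,
                 paste(names(reg), collapse = ", ")))
  reg[[key]]
}

#' Mass stopping power of a material
#'
#' From the Bragg-Kleeman law, S(E) = (dR/dE)^-1 / rho converted to
#' MeV cm^2/g, or log-log interpolation of an attached stopping table.
#'
#' @param material A [material()] object or built-in name.
#' @param E Kinetic energy in MeV (> 0); vectorized.
#' @return Mass stopping power in MeV cm^2/g.
#' @examples
#' stopping_power("water", 100)  # about 7.5 MeV cm^2/g
#' @export
stopping_power <- function(material, E) {
  m <- pgt_material(material)
  if (any(E <= 0)) stop("stopping power requires E > 0")
  if (!is.null(m$stopping_table)) {
    tab <- m$stopping_table
    if (any(E < min(tab$E)) || any(E > max(tab$E)))
      stop("energy outside the stopping table range")
    return(exp(stats::approx(log(tab$E), log(tab$S), xout = log(E))$y))
  }
  # linear stopping in MeV/mm is 1/(alpha p E^(p-1)); 10 converts /mm -> /cm
  10 / (m$rho * m$bk_alpha * m$bk_p * E^(m$bk_p - 1))
}

# linear stopping power dE/dz in MeV/mm (internal)
.linear_stopping <- function(m, E) m$rho * stopping_power(m, E) / 10
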