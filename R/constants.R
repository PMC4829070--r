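#' Physical constants used throughout the package
#'
#' Speed of light in mm/ns (so that times are naturally in nanoseconds and
#' lengths in millimetres), proton rest energy and electron rest energy in MeV.
#'
#' @return A named list with components `c` (mm/ns), `m_p_c2` (MeV) and
#'   `m_e_c2` (MeV).
#' @examples
#' pgt_constants()$c
#' @export
pgt_constants <- function() {
  list(c = 299.792458, m_p_c2 = 938.272, m_e_c2 = 0.511)
}

# internal shortcut (constants are immutable)
.const <- list(c = 299.792458, m_p_c2 = 938.272, m_e_c2 = 0.511)

# energy floor (MeV) below which a proton is considered stopped; the
# range error introduced by this cutoff is < 0.03 mm in water.
.E_FLOOR <- 1

# FWHM of a Gaussian = 2 sqrt(2 log 2) * sd
.FWHM <- 2 * sqrt(2 * log(2))
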