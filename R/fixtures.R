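# Canned experimental geometries: a cyclotron beam (106-MHz bunch structure)
# on a 400-mm PMMA cylinder with optional air-cavity or bone inserts, viewed
# by a 2-inch detector at 90 degrees and 300 mm.

.fixture_names <- c("wpe_homogeneous_230", "wpe_cavity_5mm", "wpe_bone_20mm",
                    "wpe_cavity_10mm")

#' Named experimental presets
#'
#' * `wpe_homogeneous_230`: full 400-mm PMMA target, 230-MeV protons,
#'   106-MHz bunches, 1e8 protons per spot, 0.16 gammas/proton.
#' * `wpe_cavity_5mm`: the same with a 5-mm air cavity at f = 169 mm.
#' * `wpe_cavity_10mm`: a 10-mm air cavity at f = 169 mm.
#' * `wpe_bone_20mm`: a 20-mm cortical-bone insert at f = 169 mm.
#'
#' All share the detector: alpha = 90 deg, d = 300 mm, 25.4-mm radius,
#' intrinsic efficiency 0.5, 0.3-ns FWHM timing resolution, ring centred at
#' the phantom mid-length.
#'
#' @param name Preset name (see above).
#' @param seed Optional integer seed; when given, a sampled spectrum is
#'   included.
#' @return List with `phantom`, `beam`, `detector` and (with a seed)
#'   `spectrum`.
#' @examples
#' fx <- make_fixture("wpe_cavity_5mm")
#' phantom_length(fx$phantom)
#' @export
make_fixture <- function(name, seed = NULL) {
  if (!name %in% .fixture_names)
    stop("unknown fixture '", name, "'; catalog: ",
         paste(.fixture_names, collapse = ", "))
  beam <- beam_spec(E0 = 230, f_bunch = 106, n_protons = 1e8,
                    gamma_yield = 0.16)
  detector <- detector_spec(alpha = 90, d = 300, z_ref = 200, radius = 25.4,
                            eff = 0.5, sigma_det = 0.3)
  phantom <- switch(name,
    wpe_homogeneous_230 = phantom_homogeneous("pmma", 400),
    wpe_cavity_5mm = phantom_with_insert("pmma", 400, "air", f = 169, h = 5),
    wpe_cavity_10mm = phantom_with_insert("pmma", 400, "air", f = 169, h = 10),
    wpe_bone_20mm = phantom_with_insert("pmma", 400, "cortical_bone",
                                        f = 169, h = 20))
  out <- list(phantom = phantom, beam = beam, detector = detector)
  if (!is.null(seed))
    out$spectrum <- sample_events(phantom, beam, detector, seed = seed)$spectrum
  out
}

#' Names of the available fixtures
#' @export
fixture_catalog <- function() .fixture_names
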