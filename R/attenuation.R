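# Photon attenuation: bundled total mass-attenuation grids with log-log
# interpolation, mean free path and slab attenuation fractions.

#' Load a photon attenuation table
#'
#' Bundled presets: `"Pb"`, `"CsI"` and `"water"` (total mass attenuation
#' coefficients on a 0.1-10 MeV grid; the CsI grid is an approximate
#' synthetic transcription, see the file header). A custom table can be read
#' from a two-column whitespace-separated file (`E_MeV`,
#' `mu_over_rho_cm2_g`) with an optional `# density_g_cm3=` header.
#'
#' @param material Preset name or path to a table file.
#' @param density Override density in g/cm^3 (required if the file header
#'   has none).
#' @return An object of class `pgt_attenuation` with fields `material`,
#'   `density`, `E`, `mu_rho`.
#' @export
attenuation_table <- function(material, density = NULL) {
  presets <- c(pb = "pb.tsv", csi = "csi.tsv", water = "water.tsv")
  key <- tolower(material)
  path <- if (key %in% names(presets)) {
    system.file("extdata", "attenuation", presets[[key]], package = "pgtsim",
                mustWork = TRUE)
  } else material
  if (!file.exists(path)) stop("no such attenuation preset or file: ", material)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("density_g_cm3=[0-9.eE+-]+", hdr))
  m <- unlist(m)
  if (is.null(density)) {
    if (!length(m)) stop("table has no density header; pass 'density'")
    density <- as.numeric(sub("density_g_cm3=", "", m[1]))
  }
  df <- utils::read.table(text = lines, header = TRUE, comment.char = "#")
  if (is.unsorted(df[[1]], strictly = TRUE))
    stop("table energies must be strictly increasing")
  if (any(df[[2]] <= 0)) stop("attenuation coefficients must be > 0")
  structure(list(material = material, density = density,
                 E = df[[1]], mu_rho = df[[2]]),
            class = "pgt_attenuation")
}

# log-log interpolated mass attenuation coefficient (cm^2/g)
.mu_rho_at <- function(table, E) {
  if (any(E < min(table$E)) || any(E > max(table$E)))
    stop(sprintf("energy outside the attenuation table range [%g, %g] MeV",
                 min(table$E), max(table$E)))
  exp(stats::approx(log(table$E), log(table$mu_rho), xout = log(E))$y)
}

#' Photon mean free path in a material
#'
#' lambda = 1 / (mu/rho * rho), with the mass attenuation coefficient
#' interpolated log-log.
#'
#' @param table A [attenuation_table()] (or preset name).
#' @param E Photon energy in MeV (within the table grid); vectorized.
#' @return Mean free path in cm.
#' @examples
#' mean_free_path("Pb", 4) > mean_free_path("Pb", 0.14)
#' @export
mean_free_path <- function(table, E) {
  if (is.character(table)) table <- attenuation_table(table)
  1 / (.mu_rho_at(table, E) * table$density)
}

#' Attenuation power of a slab
#'
#' 100 * (1 - exp(-thickness / lambda)): the percentage of photons of energy
#' `E` removed from the beam by a slab of the given thickness.
#'
#' @inheritParams mean_free_path
#' @param thickness Slab thickness in cm (>= 0).
#' @return Attenuation in percent.
#' @examples
#' attenuation_fraction("Pb", 0.2, 0.140)  # >= 99 for a 2-mm lead slab
#' @export
attenuation_fraction <- function(table, thickness, E) {
  if (is.character(table)) table <- attenuation_table(table)
  if (any(thickness < 0)) stop("thickness must be >= 0")
  100 * (1 - exp(-thickness / mean_free_path(table, E)))
}
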