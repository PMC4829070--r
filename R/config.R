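# Run configuration: a minimal YAML-style `key: value` format with one level
# of nesting (two-space indentation), `#` comments, validated against a fixed
# schema with defaults filled in.

.config_schema <- list(
  beam = c("energy_mev", "f_bunch_mhz", "n_protons", "gamma_yield",
           "sigma_bunch_ns"),
  detector = c("alpha_deg", "distance_mm", "z_ref_mm", "radius_mm", "eff",
               "sigma_det_ns"),
  top = c("phantom", "binning", "background", "seed", "output")
)

.parse_scalar <- function(s) {
  s <- trimws(s)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) num else s
}

#' Load and validate a run configuration file
#'
#' Format: flat `key: value` pairs plus optional `beam:` / `detector:`
#' sections with two-space-indented fields; `#` starts a comment. Unknown
#' keys are rejected by name. Defaults: `binning = 100`,
#' `background = 0.05`, beam and detector fields per [beam_spec()] /
#' [detector_spec()].
#'
#' @param path Config file path.
#' @return A validated list of class `pgt_config` with `beam`
#'   ([beam_spec()]), `detector` ([detector_spec()]), `phantom` (path or
#'   preset name or NULL), `binning`, `background`, `seed`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  raw <- list()
  section <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    indented <- grepl("^[[:space:]]", ln)
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!indented && !nzchar(val)) { section <- key; raw[[section]] <- list(); next }
    if (indented) {
      if (is.null(section)) stop("indented key '", key, "' outside a section")
      raw[[section]][[key]] <- .parse_scalar(val)
    } else {
      section <- NULL
      raw[[key]] <- .parse_scalar(val)
    }
  }
  # validate keys
  for (nm in names(raw)) {
    if (nm %in% c("beam", "detector")) {
      bad <- setdiff(names(raw[[nm]]), .config_schema[[nm]])
      if (length(bad))
        stop("unknown config key '", nm, ".", bad[1], "'")
    } else if (!nm %in% .config_schema$top) {
      stop("unknown config key '", nm, "'")
    }
  }
  b <- raw$beam %||% list()
  if (is.null(b$energy_mev)) stop("config must set beam.energy_mev")
  beam <- beam_spec(E0 = b$energy_mev,
                    f_bunch = b$f_bunch_mhz %||% 106,
                    n_protons = b$n_protons %||% 1e8,
                    gamma_yield = b$gamma_yield %||% 0.16,
                    sigma_bunch = b$sigma_bunch_ns)
  d <- raw$detector %||% list()
  detector <- detector_spec(alpha = d$alpha_deg %||% 90,
                            d = d$distance_mm %||% 300,
                            z_ref = d$z_ref_mm,
                            radius = d$radius_mm %||% 25.4,
                            eff = d$eff %||% 0.5,
                            sigma_det = d$sigma_det_ns %||% 0.3)
  structure(list(beam = beam, detector = detector,
                 phantom = raw$phantom,
                 binning = raw$binning %||% 100,
                 background = raw$background %||% 0.05,
                 seed = raw$seed %||% 1,
                 output = raw$output),
            class = "pgt_config")
}

#' Write a configuration file that [load_config()] round-trips
#'
#' @param config A `pgt_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  b <- config$beam; d <- config$detector
  fmt <- function(x) format(x, digits = 17)
  lines <- c(
    "beam:",
    paste0("  energy_mev: ", fmt(b$E0)),
    paste0("  f_bunch_mhz: ", fmt(b$f_bunch)),
    paste0("  n_protons: ", fmt(b$n_protons)),
    paste0("  gamma_yield: ", fmt(b$gamma_yield)),
    if (!is.null(b$sigma_bunch)) paste0("  sigma_bunch_ns: ", fmt(b$sigma_bunch)),
    "detector:",
    paste0("  alpha_deg: ", fmt(d$alpha)),
    paste0("  distance_mm: ", fmt(d$d)),
    if (!is.null(d$z_ref)) paste0("  z_ref_mm: ", fmt(d$z_ref)),
    paste0("  radius_mm: ", fmt(d$radius)),
    paste0("  eff: ", fmt(d$eff)),
    paste0("  sigma_det_ns: ", fmt(d$sigma_det)),
    if (!is.null(config$phantom)) paste0("phantom: ", config$phantom),
    paste0("binning: ", fmt(config$binning)),
    paste0("background: ", fmt(config$background)),
    paste0("seed: ", fmt(config$seed)),
    if (!is.null(config$output)) paste0("output: ", config$output))
  writeLines(lines, path)
  invisible(path)
}
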