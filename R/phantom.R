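# Layered phantoms: ordered material slices along the beam axis.
# Convention: the beam enters at z = 0 (front face) and z increases along the
# beam axis; slice i occupies the half-open interval [z_i, z_{i+1}).

#' Create a phantom slice
#'
#' @param material A [material()] object or built-in name.
#' @param thickness Slice thickness in mm (> 0).
#' @return An object of class `pgt_slice`.
#' @export
slice <- function(material, thickness) {
  m <- pgt_material(material)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("slice thickness must be > 0 mm")
  structure(list(material = m, thickness = thickness), class = "pgt_slice")
}

#' Create a layered phantom from ordered slices
#'
#' @param slices List of [slice()] objects, front to back.
#' @return An object of class `pgt_phantom` with fields `slices`,
#'   `boundaries` (z of slice interfaces, starting at 0) and `length` (mm).
#' @examples
#' ph <- layered_phantom(list(slice("pmma", 169), slice("air", 5),
#'                            slice("pmma", 226)))
#' phantom_length(ph)
#' @export
layered_phantom <- function(slices) {
  if (length(slices) == 0) stop("a phantom needs at least one slice")
  slices <- lapply(slices, function(s) {
    if (!inherits(s, "pgt_slice")) stop("all elements must be slices")
    s
  })
  th <- vapply(slices, function(s) s$thickness, numeric(1))
  structure(list(slices = slices, boundaries = c(0, cumsum(th)),
                 length = sum(th)),
            class = "pgt_phantom")
}

#' @export
print.pgt_phantom <- function(x, ...) {
  cat(sprintf("<layered phantom, %d slice(s), %g mm>\n",
              length(x$slices), x$length))
  for (s in x$slices)
    cat(sprintf("  %-14s %8.3f mm\n", s$material$name, s$thickness))
  invisible(x)
}

#' Total phantom length along the beam axis (mm)
#' @param phantom A [layered_phantom()].
#' @export
phantom_length <- function(phantom) phantom$length

# slice index at depth z (vectorized, half-open [z_i, z_{i+1}))
.slice_index <- function(phantom, z) {
  if (any(z < 0 | z >= phantom$length))
    stop("depth z outside [0, phantom length)")
  pmin(findInterval(z, phantom$boundaries), length(phantom$slices))
}

#' Material at a given depth
#'
#' @param phantom A [layered_phantom()].
#' @param z Depth in mm, in `[0, length)`; slice boundaries belong to the
#'   downstream slice (half-open convention).
#' @return The `pgt_material` at depth `z` (first element if `z` is vector;
#'   use [material_name_at()] for the vectorized name lookup).
#' @export
material_at <- function(phantom, z) {
  phantom$slices[[.slice_index(phantom, z[1])]]$material
}

#' Vectorized material name at depths
#' @inheritParams material_at
#' @return Character vector of material names.
#' @export
material_name_at <- function(phantom, z) {
  idx <- .slice_index(phantom, z)
  vapply(phantom$slices, function(s) s$material$name, character(1))[idx]
}

#' Homogeneous phantom of one material
#' @param material Material or name.
#' @param length Total length in mm.
#' @export
phantom_homogeneous <- function(material, length) {
  layered_phantom(list(slice(material, length)))
}

#' Phantom with a single heterogeneous insert
#'
#' A base material with an insert of thickness `h` whose front face sits at
#' depth `f` (the geometry used for cavity/bone experiments).
#'
#' @param base Base material (e.g. `"pmma"`).
#' @param length Total length in mm.
#' @param insert Insert material (e.g. `"air"` or `"cortical_bone"`).
#' @param f Depth of the insert front face from the phantom front face (mm).
#' @param h Insert thickness (mm).
#' @export
phantom_with_insert <- function(base, length, insert, f, h) {
  if (f < 0 || h <= 0 || f + h > length)
    stop("insert must satisfy 0 <= f, h > 0, f + h <= length")
  sl <- list()
  if (f > 0) sl <- c(sl, list(slice(base, f)))
  sl <- c(sl, list(slice(insert, h)))
  if (f + h < length) sl <- c(sl, list(slice(base, length - f - h)))
  layered_phantom(sl)
}

#' Read a phantom specification file
#'
#' Plain-text format: one slice per line, `material thickness_mm`, with `#`
#' starting a comment. Material names are resolved against the built-in
#' registry plus an optional user registry.
#'
#' @param path File path.
#' @param registry Optional named list of extra [material()] objects.
#' @return A `pgt_phantom`.
#' @export
read_phantom <- function(path, registry = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("phantom file contains no slices: ", path)
  sl <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) != 2) stop("bad phantom line: '", ln, "'")
    th <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(th)) stop("bad thickness in phantom line: '", ln, "'")
    slice(pgt_material(tok[1], registry), th)
  })
  layered_phantom(sl)
}

#' Write a phantom specification file
#' @param phantom A `pgt_phantom`.
#' @param path Output path.
#' @export
write_phantom <- function(phantom, path) {
  lines <- c("# phantom: material thickness_mm",
             vapply(phantom$slices, function(s)
               sprintf("%s %.17g", s$material$name, s$thickness), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Depth at which two phantoms first differ
#'
#' Scans the union of slice boundaries and returns the smallest depth where
#' the material sequences of the two phantoms diverge, or `NULL` if they are
#' identical over the common length. Used to locate a heterogeneity (e.g. a
#' cavity front face) when converting a timing shift to a range shift.
#'
#' @param a,b Two `pgt_phantom` objects.
#' @return Depth in mm, or `NULL`.
#' @export
first_divergence <- function(a, b) {
  L <- min(a$length, b$length)
  bounds <- sort(unique(c(a$boundaries, b$boundaries)))
  bounds <- bounds[bounds < L]
  for (z0 in bounds) {
    if (!identical(material_at(a, z0)$name, material_at(b, z0)$name))
      return(z0)
  }
  if (a$length != b$length) return(L)
  NULL
}
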