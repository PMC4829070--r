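# PGT spectra: binned detection-time (phase) histograms with metadata.

#' Construct a PGT spectrum
#'
#' @param bin_edges Uniform, increasing bin edges in ns (length
#'   `length(counts) + 1`).
#' @param counts Per-bin counts or expected intensities (>= 0).
#' @param meta Named list of metadata; conventional entries: `n_protons`,
#'   `seed`, `t_bunch`, `wrapped`.
#' @return An object of class `pgt_spectrum`.
#' @export
pgt_spectrum <- function(bin_edges, counts, meta = list()) {
  if (length(bin_edges) != length(counts) + 1)
    stop("length(bin_edges) must be length(counts) + 1")
  w <- diff(bin_edges)
  if (any(w <= 0)) stop("bin edges must be increasing")
  if (max(w) - min(w) > 1e-9 * mean(w)) stop("bins must be uniform")
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts), meta = meta),
            class = "pgt_spectrum")
}

#' @export
print.pgt_spectrum <- function(x, ...) {
  cat(sprintf("<PGT spectrum: %d bins over [%.4g, %.4g] ns, total %.4g counts>\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts)))
  invisible(x)
}

#' Bin centres of a spectrum (ns)
#' @param spectrum A [pgt_spectrum()].
#' @export
bin_centers <- function(spectrum) {
  e <- spectrum$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

# bin width (uniform)
.bin_width <- function(spectrum) diff(spectrum$bin_edges[1:2])

#' Write a spectrum to a TSV file
#'
#' Two columns (`bin_left_ns`, `counts`) preceded by one `#` header line
#' carrying the metadata as `key=value` pairs; [read_spectrum()] round-trips
#' exactly.
#'
#' @param spectrum A [pgt_spectrum()].
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  meta <- spectrum$meta
  meta$t_bunch <- meta$t_bunch %||% (max(spectrum$bin_edges) - min(spectrum$bin_edges))
  hdr <- paste0("# ", paste(sprintf("%s=%s", names(meta),
                                    vapply(meta, function(v)
                                      format(v, digits = 17), character(1))),
                            collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(bin_left_ns = format(spectrum$bin_edges[-length(spectrum$bin_edges)],
                                    digits = 17),
               counts = format(spectrum$counts, digits = 17)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path File path.
#' @return A [pgt_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  if (startsWith(lines[1], "#")) {
    toks <- strsplit(trimws(sub("^#", "", lines[1])), "[[:space:]]+")[[1]]
    for (tk in toks) {
      kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) {
        num <- suppressWarnings(as.numeric(kv[2]))
        meta[[kv[1]]] <- if (is.na(num)) kv[2] else num
      }
    }
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          comment.char = "#")
  left <- df$bin_left_ns
  width <- left[2] - left[1]
  pgt_spectrum(c(left, left[length(left)] + width), df$counts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
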