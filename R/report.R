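# Result serialization: JSON-lines for shift results, TSV for profiles and
# tables; full numeric precision, tool version and seed included.

#' Write an analysis report
#'
#' * A list of edge-shift results (`pgt_shift`) becomes JSON lines, one per
#'   entry.
#' * A `pgt_depth_profile` becomes a two-column TSV (`z_left_mm`,
#'   `intensity`).
#' * A data frame (e.g. a detectability table) becomes a TSV.
#'
#' @param results Non-empty result object as above.
#' @param path Output path.
#' @param seed Seed to record in the report metadata.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL) {
  version <- as.character(utils::packageVersion("pgtsim"))
  if (inherits(results, "pgt_shift")) results <- list(results)
  if (is.list(results) && length(results) &&
      all(vapply(results, inherits, logical(1), "pgt_shift"))) {
    lines <- vapply(results, function(r) {
      jsonlite::toJSON(c(unclass(r)[c("delta_t", "delta_z", "ci_low",
                                      "ci_high", "n_protons")],
                         list(tool_version = version, seed = seed)),
                       auto_unbox = TRUE, digits = NA, null = "null")
    }, character(1))
    writeLines(lines, path)
  } else if (inherits(results, "pgt_depth_profile")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# pgtsim %s seed=%s", version,
                       format(seed %||% "NA")), con)
    utils::write.table(
      data.frame(z_left_mm = format(results$z_bin_edges[-length(results$z_bin_edges)],
                                    digits = 17),
                 intensity = format(results$intensity, digits = 17)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(results)) {
    if (nrow(results) == 0) stop("empty results")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# pgtsim %s seed=%s", version,
                       format(seed %||% "NA")), con)
    utils::write.table(format(results, digits = 17), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (length(results) == 0) {
    stop("empty results")
  } else {
    stop("unsupported results type")
  }
  invisible(path)
}
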