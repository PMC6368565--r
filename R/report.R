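#' Write an analysis report as JSON
#'
#' Serializes a named list of results with a schema version, the RNG seed
#' used, threshold settings and optional input checksums, so that runs are
#' auditable and reproducible from the report alone.
#'
#' @param results named list of results (must be JSON-serializable).
#' @param path output path.
#' @param seed RNG seed echoed into the report.
#' @param thresholds a [thresholds()] object echoed into the report.
#' @param inputs optional character vector of input file paths; their md5
#'   checksums are recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL,
                         thresholds = clonalshift::thresholds(),
                         inputs = NULL) {
  payload <- list(
    schema_version = "1.0",
    generated_by = "clonalshift",
    seed = seed,
    thresholds = unclass(thresholds),
    results = results)
  if (!is.null(inputs))
    payload$input_checksums <- as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path report path.
#' @return the deserialized report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
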