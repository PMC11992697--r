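#' Write a run manifest
#'
#' Every analysis stage records a small JSON manifest next to its outputs:
#' the seed, the stage configuration, MD5 digests of the input files it
#' consumed, record counts in and out, and the package version -- enough to
#' re-run the stage and to audit the filtering trail.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param seed Integer seed used by the stage (or `NA`).
#' @param config A list of stage parameters (must be JSON-serialisable).
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param counts Named list/vector of record counts (in/out and any
#'   intermediate filters).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, seed = NA_integer_, config = list(),
                           inputs = character(0), counts = list()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(stage = stage, seed = seed,
                   package_version = as.character(utils::packageVersion("idrbench")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   config = config, input_digests = digests,
                   counts = as.list(counts))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
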