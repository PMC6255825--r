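#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seed(s), package version, and SHA-256-free
#' content hashes (via [tools::md5sum()]) of input and output files next to
#' the outputs of a run, as JSON.
#'
#' @param path Manifest destination (`.json`).
#' @param config Named list describing the run configuration.
#' @param seed Integer seed(s) used by the run.
#' @param inputs,outputs Character vectors of file paths to hash.
#'
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(path, config = list(), seed = NULL,
                         inputs = character(), outputs = character()) {
  hash <- function(files) {
    files <- files[file.exists(files)]
    if (!length(files)) return(list())
    as.list(tools::md5sum(files))
  }
  m <- list(
    package = "chloridyn",
    version = as.character(utils::packageVersion("chloridyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_hashes = hash(inputs),
    output_hashes = hash(outputs)
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(m)
}
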