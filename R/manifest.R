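#' Ground truth of a simulated object
#'
#' Every `simulate_*` generator attaches a `ground_truth` attribute
#' recording the parameters and seed it was called with; this accessor
#' retrieves it.
#'
#' @param x An object returned by a generator.
#' @return Named list, or `NULL` if `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Write and read a run manifest
#'
#' A run manifest is a JSON record of the ground truths (parameters and
#' seeds) of every simulated input of an analysis run, so that any output
#' can be regenerated exactly.
#'
#' @param truths Named list of ground-truth records (see [ground_truth()]).
#' @param path JSON output path.
#' @return `write_run_manifest()` returns `path` invisibly;
#'   `read_run_manifest()` returns the named list.
#' @export
write_run_manifest <- function(truths, path) {
  jsonlite::write_json(truths, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
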