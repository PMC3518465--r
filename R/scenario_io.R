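#' Read / write scenario files
#'
#' Scenarios are stored as structured plain text (YAML), one named block per
#' condition, so a study configuration can live beside the data it
#' generated. The round trip is lossless.
#'
#' @param specs named list of [scenario_spec()] objects.
#' @param path file path.
#' @return `read_scenario_file` returns a named list of scenario specs;
#'   `write_scenario_file` returns `specs` invisibly.
#' @export
write_scenario_file <- function(specs, path) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "scenario_spec")))
  names(specs) <- vapply(specs, function(s) s$condition_name, character(1))
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(specs)
}

#' @rdname write_scenario_file
#' @export
read_scenario_file <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(fields) {
    if (identical(fields$selective_onset_ms, ".inf") ||
        identical(fields$selective_onset_ms, "Inf"))
      fields$selective_onset_ms <- Inf
    do.call(scenario_spec, fields[setdiff(names(fields), "condition_name")] |>
              c(list(condition_name = fields$condition_name)))
  })
}
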