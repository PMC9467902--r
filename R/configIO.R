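#' Read and write study configurations
#'
#' JSON serialization of [StudyConfig-class]: a flat key-value file whose
#' keys match the slot names. Missing keys take the [defaultStudyConfig()]
#' values, so a config file only needs the fields it changes.
#'
#' @param path file path.
#' @param config a [StudyConfig-class] (for writing).
#' @return \code{readStudyConfig} returns a [StudyConfig-class];
#'   \code{writeStudyConfig} returns the path invisibly.
#' @export
readStudyConfig <- function(path) {
  raw <- jsonlite::fromJSON(path)
  args <- formals(defaultStudyConfig)
  known <- intersect(names(raw), names(args))
  unknown <- setdiff(names(raw), names(args))
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(defaultStudyConfig, raw[known])
}

#' @rdname readStudyConfig
#' @export
writeStudyConfig <- function(config, path) {
  stopifnot(is(config, "StudyConfig"))
  x <- sapply(slotNames(config), function(s) slot(config, s),
              simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a simulation truth record as JSON
#'
#' Serializes a [SimTruth-class] — kinetics parameters, per-catheter true
#' recoveries/statuses, closed-form NCA table and seed — to a structured
#' JSON file sufficient to recompute every simulated observable.
#'
#' @param truth a [SimTruth-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  kin <- lapply(truth@kinetics, function(k)
    list(compartment = k@compartment, amplitude = k@amplitude,
         k_uptake = k@kUptake, k_elim = k@kElim))
  jsonlite::write_json(
    list(seed = truth@seed, kinetics = kin,
         catheter_states = truth@catheterStates,
         closed_form_nca = truth@closedForm),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
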