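#' Run configuration for reproducible analyses
#'
#' Bundles everything that determines an analysis run: model-parameter
#' overrides, solver settings, classifier settings, an optional conductance
#' grid and the seed.  Unknown top-level keys are rejected so a typo cannot
#' silently change a run.
#'
#' @param parameters named list of model-parameter overrides.
#' @param solver named list: `duration_s`, `discard_s`, `dt_out_ms`,
#'   `rtol`, `atol`.
#' @param classifier named list of [classifier_config()] overrides.
#' @param grid named list: `gnap_values`, `gcan_values`.
#' @param seed integer seed for all randomness of the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(parameters = list(), solver = list(),
                       classifier = list(), grid = list(), seed = 1L) {
  allowed_solver <- c("duration_s", "discard_s", "dt_out_ms", "rtol", "atol")
  bad <- setdiff(names(solver), allowed_solver)
  if (length(bad)) stop("unknown solver setting(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(grid), c("gnap_values", "gcan_values"))
  if (length(bad)) stop("unknown grid setting(s): ", paste(bad, collapse = ", "))
  # delegate validation of the nested blocks to their constructors
  do.call(model_parameters, parameters)
  do.call(classifier_config, classifier)
  structure(list(parameters = parameters, solver = solver,
                 classifier = classifier, grid = grid,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a reproducibility manifest for an output directory
#'
#' Serializes the full configuration (dotted flat keys), the seed and the
#' package version into `manifest.txt` inside `dir`, so any result
#' directory carries everything needed to reproduce it.
#'
#' @param cfg a `run_config`.
#' @param dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(cfg, dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- unlist(cfg)
  lines <- c(sprintf("package_version = %s",
                     as.character(utils::packageVersion("prebotsim"))),
             sprintf("%s = %s", names(flat), as.character(flat)))
  path <- file.path(dir, "manifest.txt")
  writeLines(lines, path)
  invisible(path)
}
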