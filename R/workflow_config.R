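#' Load a workflow definition from a YAML/JSON config file
#'
#' A workflow config is an ordered list of stages, each naming a plugin id
#' with optional settings overrides — the scriptable mirror of arranging
#' plugins in a workflow list:
#'
#' ```yaml
#' name: case-study
#' stages:
#'   - plugin: core/read_file
#'     settings: {file_pattern: "*.tsv"}
#'   - plugin: core/interpolate_gaps
#'     settings: {max_gap: 5, method: linear}
#' ```
#'
#' Every stage is instantiated (so settings are validated on load) and
#' appended to the study's workflow in file order.
#'
#' @param study a [ts_study()]; must be unlocked.
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @param store optional [settings_store()] for named settings sets
#'   referenced via `settings_name`.
#' @return the study with the workflow appended.
#' @export
load_workflow <- function(study, path, store = NULL) {
  assert_unlocked(study, "load a workflow into")
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  stages <- cfg$stages
  if (is.null(stages) || !length(stages)) {
    pf_error(sprintf("workflow config '%s' defines no stages", path),
             "pf_config_error")
  }
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.null(st$plugin)) {
      pf_error(sprintf("stage %d has no 'plugin' field", i),
               "pf_config_error")
    }
    inst <- instantiate(st$plugin,
                        settings_name = st$settings_name %||% "default",
                        overrides = st$settings %||% list(),
                        store = store)
    study <- workflow_append(study, inst)
  }
  study
}

#' Path of a workflow config shipped with the package
#' @param which `"case_study"` (the five processing stages) or
#'   `"case_study_bootstrap"` (the same five plus the group bootstrap
#'   stage).
#' @return file path.
#' @export
shipped_workflow <- function(which = c("case_study",
                                       "case_study_bootstrap")) {
  which <- match.arg(which)
  system.file("extdata", paste0("workflow_", which, ".yaml"),
              package = "pupilflow", mustWork = TRUE)
}
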