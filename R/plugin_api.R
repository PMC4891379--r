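# Package-level plugin registry. Built-in plugins are registered on load;
# bundle imports compile their embedded sources into run-local registries
# instead, so nothing global is ever shadowed.
.registry <- new.env(parent = emptyenv())

#' Declare one plugin setting
#'
#' Helpers building the typed settings schema of a plugin: each setting has
#' a type, a default, and (where meaningful) a range or a set of choices.
#' Any settings mapping either validates against the schema or yields a
#' violation naming the offending key.
#'
#' @param default default value (every setting must have one).
#' @param min,max inclusive bounds for numeric settings.
#' @param choices allowed values for a choice setting.
#' @param doc one-line description.
#' @return a setting descriptor (plain list).
#' @name plugin_settings
NULL

#' @rdname plugin_settings
#' @export
setting_num <- function(default, min = -Inf, max = Inf, doc = "") {
  list(type = "number", default = as.numeric(default), min = min, max = max,
       doc = doc)
}

#' @rdname plugin_settings
#' @export
setting_int <- function(default, min = -Inf, max = Inf, doc = "") {
  list(type = "integer", default = as.integer(default), min = min, max = max,
       doc = doc)
}

#' @rdname plugin_settings
#' @export
setting_text <- function(default, doc = "") {
  list(type = "text", default = as.character(default), doc = doc)
}

#' @rdname plugin_settings
#' @export
setting_flag <- function(default, doc = "") {
  list(type = "flag", default = isTRUE(default), doc = doc)
}

#' @rdname plugin_settings
#' @export
setting_choice <- function(default, choices, doc = "") {
  stopifnot(default %in% choices)
  list(type = "choice", default = default, choices = choices, doc = doc)
}

#' Describe a plugin
#'
#' The self-description a plugin's `declare` entry point returns: identity,
#' menu category, execution scope and the settings schema.
#'
#' @param plugin_id unique id, `"<type>/<name>"` (e.g.
#'   `"core/interpolate_gaps"`, `"test/bootstrap"`).
#' @param category menu path, e.g. `"core"` or `"custom/test"`.
#' @param title one-line human name.
#' @param scope `"subject"` (run once per selected subject) or `"group"`
#'   (run once over all selected subjects, e.g. for group statistics).
#' @param settings named list of setting descriptors
#'   (see [plugin_settings]).
#' @param doc free-text help.
#' @return an object of class `plugin_spec`.
#' @export
plugin_spec <- function(plugin_id, category, title = plugin_id,
                        scope = c("subject", "group"), settings = list(),
                        doc = "") {
  scope <- match.arg(scope)
  stopifnot(is_string(plugin_id), is_string(category), is_string(title))
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*/[A-Za-z][A-Za-z0-9_]*$", plugin_id)) {
    pf_error(sprintf("invalid plugin id '%s' (want '<type>/<name>')",
                     plugin_id), "pf_plugin_error")
  }
  if (length(settings) && is.null(names(settings))) {
    pf_error("settings schema must be a named list", "pf_plugin_error")
  }
  for (k in names(settings)) {
    if (is.null(settings[[k]]$default)) {
      pf_error(sprintf("setting '%s' has no default", k), "pf_plugin_error")
    }
  }
  structure(list(plugin_id = plugin_id, category = category, title = title,
                 scope = scope, settings = settings, doc = doc),
            class = "plugin_spec")
}

#' Validate a settings mapping against a plugin's schema
#'
#' Validation is total: any mapping either passes or yields violations, each
#' naming the key concerned (unknown key, type mismatch, out-of-range value,
#' disallowed choice).
#'
#' @param spec a [plugin_spec()].
#' @param settings named list of proposed values.
#' @return character vector of violations; empty if the mapping validates.
#' @export
validate_settings <- function(spec, settings) {
  v <- character()
  schema <- spec$settings
  unknown <- setdiff(names(settings), names(schema))
  if (length(unknown)) {
    v <- c(v, sprintf("unknown setting '%s' for plugin '%s'", unknown,
                      spec$plugin_id))
  }
  for (k in intersect(names(settings), names(schema))) {
    sk <- schema[[k]]
    val <- settings[[k]]
    bad <- function(msg) v <<- c(v, sprintf("setting '%s': %s", k, msg))
    switch(sk$type,
      number = ,
      integer = {
        if (!is_num1(val)) { bad("expected a single number"); next }
        if (sk$type == "integer" && val != trunc(val)) {
          bad("expected an integer"); next
        }
        if (val < sk$min || val > sk$max) {
          bad(sprintf("value %g outside allowed range [%g, %g]", val,
                      sk$min, sk$max))
        }
      },
      text = if (!is_string(val)) bad("expected a single string"),
      flag = if (!(is.logical(val) && length(val) == 1L && !is.na(val)))
        bad("expected TRUE or FALSE"),
      choice = if (!is_string(val) || !(val %in% sk$choices))
        bad(sprintf("value must be one of: %s",
                    paste(sk$choices, collapse = ", "))),
      bad(sprintf("unknown schema type '%s'", sk$type))
    )
  }
  v
}

normalize_settings <- function(spec, settings) {
  for (k in names(settings)) {
    sk <- spec$settings[[k]]
    if (!is.null(sk)) {
      settings[[k]] <- switch(sk$type,
        integer = as.integer(settings[[k]]),
        number = as.numeric(settings[[k]]),
        text = ,
        choice = as.character(settings[[k]]),
        flag = isTRUE(settings[[k]]),
        settings[[k]])
    }
  }
  settings
}

default_settings <- function(spec) {
  lapply(spec$settings, `[[`, "default")
}

# A registry entry: spec + the three entry points + a source snapshot.
make_entry <- function(declare, configure, process, source) {
  spec <- declare()
  if (!inherits(spec, "plugin_spec")) {
    pf_error("'declare' must return a plugin_spec", "pf_plugin_error")
  }
  if (is.null(source)) source <- builtin_source(declare, configure, process)
  list(spec = spec, declare = declare, configure = configure,
       process = process, source = source)
}

# Canonical source snapshot of a plugin given its three entry points; the
# snapshot is itself compilable by compile_plugin_source().
builtin_source <- function(declare, configure, process) {
  paste(c(
    "declare <- ", deparse(declare), "",
    "configure <- ", deparse(configure), "",
    "process <- ", deparse(process), ""
  ), collapse = "\n")
}

#' Register a plugin
#'
#' A plugin is three mandatory entry points: `declare()` returns its
#' [plugin_spec()]; `configure(settings, spec)` validates and normalizes a
#' settings mapping (the default implementation is schema validation);
#' `process(study, subjects, settings, ctx)` does the work and returns the
#' (possibly modified) study, or `list(study =, outputs =)`. All three must
#' be supplied; a missing one is a contract error naming it.
#'
#' @param declare,configure,process the three entry points.
#' @param source source snapshot text embedded into studies for
#'   reproduction; derived from the functions if omitted.
#' @param overwrite replace an existing registration with the same id.
#' @param registry target environment (default: the package registry).
#' @return the plugin id, invisibly.
#' @export
register_plugin <- function(declare = NULL, configure = NULL, process = NULL,
                            source = NULL, overwrite = FALSE,
                            registry = .registry) {
  missing_ep <- c("declare", "configure", "process")[c(is.null(declare),
                  is.null(configure), is.null(process))]
  if (length(missing_ep)) {
    pf_error(sprintf("plugin contract violated: missing entry point(s): %s",
                     paste(missing_ep, collapse = ", ")), "pf_contract_error")
  }
  stopifnot(is.function(declare), is.function(configure),
            is.function(process))
  entry <- make_entry(declare, configure, process, source)
  id <- entry$spec$plugin_id
  if (!overwrite && !is.null(registry[[id]])) {
    pf_error(sprintf("plugin '%s' is already registered", id),
             "pf_duplicate_error")
  }
  registry[[id]] <- entry
  invisible(id)
}

#' Register a plugin from source text
#'
#' Evaluates the source in a fresh environment (with access to this
#' package's functions) and registers the `declare` / `configure` /
#' `process` entry points it defines. This is how plugin sources embedded
#' in bundles are brought back to life.
#'
#' @param source plugin source text, or a file path via `file =`.
#' @param file path to a plugin source file.
#' @inheritParams register_plugin
#' @return the plugin id, invisibly.
#' @export
register_plugin_source <- function(source = NULL, file = NULL,
                                   overwrite = FALSE, registry = .registry) {
  if (is.null(source)) {
    stopifnot(!is.null(file), file.exists(file))
    source <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  entry <- compile_plugin_source(source)
  id <- entry$spec$plugin_id
  if (!overwrite && !is.null(registry[[id]])) {
    pf_error(sprintf("plugin '%s' is already registered", id),
             "pf_duplicate_error")
  }
  registry[[id]] <- entry
  invisible(id)
}

compile_plugin_source <- function(source) {
  env <- new.env(parent = asNamespace("pupilflow"))
  eval(parse(text = source), envir = env)
  eps <- c("declare", "configure", "process")
  have <- vapply(eps, function(e) exists(e, envir = env, inherits = FALSE) &&
                   is.function(get(e, envir = env)), logical(1))
  if (!all(have)) {
    pf_error(sprintf("plugin contract violated: source defines no %s",
                     paste(eps[!have], collapse = ", ")), "pf_contract_error")
  }
  make_entry(get("declare", env), get("configure", env),
             get("process", env), source)
}

registry_get <- function(plugin_id, registry = .registry) {
  e <- registry[[plugin_id]]
  if (is.null(e)) {
    pf_error(sprintf("plugin '%s' is not registered", plugin_id),
             "pf_unknown_plugin_error")
  }
  e
}

#' List registered plugins
#' @param category restrict to a category prefix (e.g. `"core"`).
#' @param registry registry environment.
#' @return data frame with columns `plugin_id`, `category`, `title`, `scope`.
#' @export
registered_plugins <- function(category = NULL, registry = .registry) {
  ids <- sort(ls(registry))
  rows <- lapply(ids, function(id) {
    sp <- registry[[id]]$spec
    data.frame(plugin_id = sp$plugin_id, category = sp$category,
               title = sp$title, scope = sp$scope, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(plugin_id = character(), category = character(),
                      title = character(), scope = character())
  }
  if (!is.null(category)) {
    out <- out[startsWith(out$category, category), , drop = FALSE]
  }
  out
}

# ---- named settings store ---------------------------------------------------

#' On-disk store of named settings sets
#'
#' The same plugin is often used with different parameters; a settings store
#' persists each named set as one plain-text YAML mapping per
#' (plugin, name), so stored configurations are diff-able and shareable.
#' `"default"` always resolves for a registered plugin (to the schema
#' defaults) even when nothing has been saved.
#'
#' @param dir directory holding the settings files (created if needed).
#' @return an object of class `settings_store`.
#' @export
settings_store <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(dir = normalizePath(dir)), class = "settings_store")
}

settings_path <- function(store, plugin_id, name) {
  file.path(store$dir, paste0(gsub("/", "__", plugin_id, fixed = TRUE),
                              "--", name, ".yaml"))
}

#' Save a named settings set
#' @param store a [settings_store()].
#' @param plugin_id plugin id the settings belong to.
#' @param name settings-set name (e.g. `"default"`, `"noName"`).
#' @param settings named list of values, validated against the plugin's
#'   schema if it is registered.
#' @return the file path, invisibly.
#' @export
save_settings <- function(store, plugin_id, name, settings) {
  stopifnot(inherits(store, "settings_store"), is_string(name))
  if (!is.null(.registry[[plugin_id]])) {
    v <- validate_settings(.registry[[plugin_id]]$spec, settings)
    if (length(v)) pf_error(paste(v, collapse = "; "), "pf_settings_error")
  }
  path <- settings_path(store, plugin_id, name)
  yaml::write_yaml(settings, path)
  invisible(path)
}

#' Load a named settings set
#' @inheritParams save_settings
#' @param must_exist error (rather than `NULL`) when the set is missing.
#' @return named list of values, or `NULL`.
#' @export
load_settings <- function(store, plugin_id, name, must_exist = FALSE) {
  path <- settings_path(store, plugin_id, name)
  if (!file.exists(path)) {
    if (must_exist) {
      pf_error(sprintf("no stored settings '%s' for plugin '%s'", name,
                       plugin_id), "pf_settings_error")
    }
    return(NULL)
  }
  yaml::read_yaml(path)
}

# ---- instantiation ----------------------------------------------------------

#' Create a configured plugin instance
#'
#' The instance's settings are the schema defaults, overlaid with the stored
#' named set (if a store is given or the name is not `"default"`), overlaid
#' with `overrides` — then validated by the plugin's `configure` entry
#' point. Validation failures name the offending key.
#'
#' @param plugin_id a registered plugin id.
#' @param settings_name name of a stored settings set; `"default"` means
#'   the schema defaults.
#' @param overrides named list of settings values taking precedence.
#' @param store optional [settings_store()] to resolve `settings_name` in.
#' @param registry registry environment.
#' @return an object of class `plugin_instance` with fields `plugin_id`,
#'   `settings_name`, `settings`, `source_ref`.
#' @examples
#' inst <- instantiate("core/filter_moving_average", "default",
#'                     list(halfwidth = 5, statistic = "median"))
#' inst$settings$halfwidth  # 11-sample effective window
#' @export
instantiate <- function(plugin_id, settings_name = "default",
                        overrides = list(), store = NULL,
                        registry = .registry) {
  entry <- registry_get(plugin_id, registry)
  spec <- entry$spec
  settings <- default_settings(spec)
  stored <- if (!is.null(store)) {
    load_settings(store, plugin_id, settings_name,
                  must_exist = !identical(settings_name, "default"))
  } else if (!identical(settings_name, "default")) {
    pf_error(sprintf("settings set '%s' requested but no settings store given",
                     settings_name), "pf_settings_error")
  }
  if (!is.null(stored)) settings <- utils::modifyList(settings, stored)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      pf_error("overrides must be a fully named list", "pf_settings_error")
    }
    settings <- utils::modifyList(settings, overrides)
  }
  settings <- entry$configure(settings, spec)
  structure(list(plugin_id = plugin_id, settings_name = settings_name,
                 settings = settings, source_ref = plugin_id),
            class = "plugin_instance")
}

#' Default `configure` entry point: schema validation + type normalization
#'
#' Errors (naming each offending key) if the mapping does not validate;
#' otherwise returns the mapping with values coerced to their declared
#' types. Custom plugins normally call this and add cross-field checks.
#'
#' @param settings named list of proposed values.
#' @param spec the plugin's [plugin_spec()].
#' @return the normalized settings mapping.
#' @export
configure_by_schema <- function(settings, spec) {
  v <- validate_settings(spec, settings)
  if (length(v)) {
    pf_error(paste(v, collapse = "; "), "pf_settings_error")
  }
  normalize_settings(spec, settings)
}

#' @export
print.plugin_instance <- function(x, ...) {
  cat(sprintf("<plugin_instance %s (settings '%s')>\n", x$plugin_id,
              x$settings_name))
  for (k in names(x$settings)) {
    cat(sprintf("  %s = %s\n", k,
                paste(format(x$settings[[k]]), collapse = ", ")))
  }
  invisible(x)
}

# ---- template generation ----------------------------------------------------

#' Generate a custom-plugin source template
#'
#' Writes a ready-to-register plugin skeleton: all three mandatory entry
#' points, an example settings schema (two numeric boxes, a dropdown and a
#' checkbox), and a marked region where the processing code goes. The
#' generated file registers as a runnable no-op, and generation is
#' deterministic: identical inputs give byte-identical output.
#'
#' @param category plugin type, e.g. `"test"`.
#' @param name plugin name, e.g. `"bootstrap"`; must be a valid identifier.
#' @param template_kind `"basic-group"` (process all selected subjects at
#'   once — the right scope for group statistics) or `"basic-subject"`.
#' @param dir directory to write `<category>_<name>.R` into; `NULL` returns
#'   the source text only.
#' @return the source text, invisibly if written to a file.
#' @export
generate_plugin_template <- function(category, name,
                                     template_kind = "basic-group",
                                     dir = NULL) {
  ok_id <- function(x) is_string(x) && grepl("^[A-Za-z][A-Za-z0-9_]*$", x)
  if (!ok_id(category) || !ok_id(name)) {
    pf_error("category and name must be valid identifiers (letters, digits, '_')",
             "pf_template_error")
  }
  if (!template_kind %in% c("basic-group", "basic-subject")) {
    pf_error(sprintf("unknown template kind '%s'", template_kind),
             "pf_template_error")
  }
  scope <- if (template_kind == "basic-group") "group" else "subject"
  id <- paste0(category, "/", name)
  cat_path <- paste0("custom/", category)
  src <- sprintf(
'# Plugin "%s" (%s template)
# Entry points: declare() describes the plugin and its settings;
# configure() validates a settings mapping; process() does the work.

declare <- function() {
  pupilflow::plugin_spec(
    plugin_id = "%s",
    category = "%s",
    title = "%s",
    scope = "%s",
    settings = list(
      # example controls: two numeric boxes, a dropdown and a checkbox
      threshold = pupilflow::setting_num(0, doc = "example numeric input"),
      window_s = pupilflow::setting_num(1, min = 0,
                                        doc = "example numeric input"),
      method = pupilflow::setting_choice("a", c("a", "b", "c"),
                                         doc = "example dropdown"),
      verbose = pupilflow::setting_flag(FALSE, doc = "example checkbox")
    ),
    doc = "Describe what this plugin computes."
  )
}

configure <- function(settings, spec) {
  # add cross-field checks here; schema validation covers single fields
  pupilflow::configure_by_schema(settings, spec)
}

process <- function(study, subjects, settings, ctx) {
  # -- Your code for plugin processing should start here --

  # -- and end here; return the study (plus optional outputs) --
  list(study = study, outputs = NULL)
}
', id, template_kind, id, cat_path, name, scope)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(category, "_", name, ".R"))
    writeLines(src, path, sep = "")
    return(invisible(src))
  }
  src
}
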