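#' Run selected workflow stages over selected subjects
#'
#' Executes the selected plugins in workflow order (never in selection
#' order), each over the selected subjects; unselected subjects' data are
#' untouched. Re-running a stage overwrites that stage's derived outputs
#' for the selected subjects. One provenance record is appended per plugin
#' execution. Progress is reported as the fraction of
#' (plugins x subjects) units completed.
#'
#' Plugin sources embedded in the study (e.g. after a bundle import) take
#' precedence over globally registered plugins of the same id, and are
#' compiled into a run-local registry, so imported workflows reproduce
#' with exactly the code they shipped, shadowing nothing global. After a
#' run, the study carries a source snapshot for every executed plugin.
#'
#' A single top-level `seed` drives all stochastic stages: each
#' (plugin, subject-set) execution receives a substream derived from the
#' seed, the plugin id and the subject names, so results do not depend on
#' selection order. Identical study, selections, settings and seed give
#' bit-identical derived data.
#'
#' Running a workflow is reproduction, not editing, so it is permitted on
#' locked studies: stages recompute channels and derived results
#' deterministically from the attached raw data, and the provenance log is
#' append-only by design. Editing operations (settings changes, workflow
#' or subject changes) remain rejected on locked studies.
#'
#' @param study a [ts_study()].
#' @param subjects indices of subjects to process (default: all).
#' @param plugins indices into the workflow (default: all stages).
#' @param seed integer seed for stochastic plugins.
#' @param error_policy `"abort"` (stop on the first failing
#'   (plugin, subject) pair) or `"continue"` (record the failure, keep the
#'   subject's prior data intact, move on).
#' @param output_dir directory where stages write tables and figures;
#'   `NULL` disables file outputs.
#' @param progress print textual progress and per-stage log lines.
#' @return list of class `run_report`:
#' \describe{
#'   \item{study}{the updated study (derived data, provenance, sources).}
#'   \item{report}{data frame: stage, plugin_id, subject, status, seconds,
#'     message.}
#'   \item{outputs}{named list of per-stage outputs (tables, figures,
#'     test results).}
#' }
#' @export
run_workflow <- function(study, subjects = seq_along(study$subjects),
                         plugins = seq_along(study$workflow), seed = NULL,
                         error_policy = c("abort", "continue"),
                         output_dir = NULL, progress = FALSE) {
  stopifnot(inherits(study, "ts_study"))
  error_policy <- match.arg(error_policy)
  subjects <- validate_selection(subjects, length(study$subjects),
                                 "subject")
  plugins <- validate_selection(plugins, length(study$workflow), "plugin")
  plugins <- sort(plugins)  # workflow order is significant
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  local_reg <- build_run_registry(study)
  rows <- list()
  outputs <- list()
  total <- length(plugins) * max(1L, length(subjects))
  done_units <- 0L
  log_line <- function(...) if (progress) message(sprintf(...))
  for (pi in plugins) {
    inst <- study$workflow[[pi]]
    entry <- resolve_plugin(inst, local_reg)
    scope <- entry$spec$scope
    sub_names <- subject_names(study)[subjects]
    stage_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, inst$plugin_id, paste(sub_names, collapse = ","))
    before <- data_fingerprint(study, subjects)
    stage_key <- sprintf("stage%02d_%s", pi,
                         gsub("/", "_", inst$plugin_id, fixed = TRUE))
    run_one <- function(sel, unit_label, unit_seed) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        ctx <- list(seed = unit_seed, output_dir = output_dir,
                    stage = pi, study_name = study$name,
                    engine_version = study$engine_version)
        out <- entry$process(study, sel, inst$settings, ctx)
        if (inherits(out, "ts_study")) out <- list(study = out)
        if (!is.list(out) || !inherits(out$study, "ts_study")) {
          pf_error("plugin process() must return a ts_study or list(study =, ...)",
                   "pf_plugin_error")
        }
        out
      }, error = function(e) e)
      secs <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        msg <- conditionMessage(res)
        rows[[length(rows) + 1L]] <<- report_row(pi, inst$plugin_id,
                                                 unit_label, "error", secs,
                                                 msg)
        log_line("[%s] %s | %s: ERROR %s", stage_key, inst$plugin_id,
                 unit_label, msg)
        if (error_policy == "abort") {
          pf_error(sprintf("plugin '%s' failed on %s: %s", inst$plugin_id,
                           unit_label, msg), "pf_run_error")
        }
      } else {
        study <<- res$study
        if (!is.null(res$outputs)) outputs[[stage_key]] <<- res$outputs
        rows[[length(rows) + 1L]] <<- report_row(pi, inst$plugin_id,
                                                 unit_label, "ok", secs, "")
        log_line("[%s] %s | %s: ok (%.2fs)", stage_key, inst$plugin_id,
                 unit_label, secs)
      }
    }
    if (scope == "subject") {
      for (si in subjects) {
        nm <- study$subjects[[si]]$name
        unit_seed <- if (is.null(seed)) NULL else
          derive_seed(seed, inst$plugin_id, nm)
        run_one(si, nm, unit_seed)
        done_units <- done_units + 1L
        if (progress) report_progress(done_units, total)
      }
    } else {
      run_one(subjects, sprintf("group[%s]",
                                paste(sub_names, collapse = ",")),
              stage_seed)
      done_units <- done_units + length(subjects)
      if (progress) report_progress(done_units, total)
    }
    # snapshot the executed plugin's source into the study
    if (is.null(study$plugin_sources[[inst$source_ref]])) {
      study$plugin_sources[[inst$source_ref]] <- entry$source
    }
    study$provenance[[length(study$provenance) + 1L]] <- structure(
      list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
           plugin_id = inst$plugin_id,
           settings_hash = hash_object(inst$settings),
           subjects = sub_names,
           engine_version = study$engine_version,
           input_hash = before,
           output_hash = data_fingerprint(study, subjects)),
      class = "provenance_record")
  }
  report <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    report_row(integer(0), character(0), character(0), character(0),
               numeric(0), character(0))
  }
  structure(list(study = study, report = report, outputs = outputs),
            class = "run_report")
}

report_row <- function(stage, plugin_id, subject, status, seconds,
                       message) {
  data.frame(stage = stage, plugin_id = plugin_id, subject = subject,
             status = status, seconds = seconds, message = message,
             stringsAsFactors = FALSE)
}

validate_selection <- function(sel, n, what) {
  if (length(sel) == 0L) return(integer(0))
  sel <- as.integer(sel)
  if (anyNA(sel) || any(sel < 1L | sel > n) || anyDuplicated(sel)) {
    pf_error(sprintf("invalid %s selection (valid indices: 1..%d)", what,
                     n), "pf_run_error")
  }
  sel
}

report_progress <- function(done, total) {
  message(sprintf("progress: %d/%d (%.0f%%)", done, total,
                  100 * done / max(1L, total)))
}

# Compile the study's embedded plugin sources into a run-local registry.
build_run_registry <- function(study) {
  reg <- new.env(parent = emptyenv())
  for (id in names(study$plugin_sources)) {
    entry <- tryCatch(compile_plugin_source(study$plugin_sources[[id]]),
                      error = function(e) {
                        pf_error(sprintf("embedded source for plugin '%s' does not compile: %s",
                                         id, conditionMessage(e)),
                                 "pf_plugin_error")
                      })
    reg[[id]] <- entry
  }
  reg
}

resolve_plugin <- function(inst, local_reg) {
  e <- local_reg[[inst$source_ref]]
  if (!is.null(e)) return(e)
  registry_get(inst$plugin_id)
}

#' Write a run report as a tab-separated text table
#' @param report a `run_report` (from [run_workflow()]) or its `report`
#'   data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  df <- if (inherits(report, "run_report")) report$report else report
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  n_ok <- sum(x$report$status == "ok")
  n_err <- sum(x$report$status == "error")
  cat(sprintf("<run_report> %d unit(s) ok, %d failed, %.2f s total\n",
              n_ok, n_err, sum(x$report$seconds)))
  if (n_err) {
    bad <- x$report[x$report$status == "error", ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  FAILED stage %d %s | %s: %s\n", bad$stage[i],
                  bad$plugin_id[i], bad$subject[i], bad$message[i]))
    }
  }
  invisible(x)
}
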