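BUNDLE_FORMAT_VERSION <- 1L

#' Compute a study's content-derived workflow identifier
#'
#' The identifier has the form `ts-XXX-XXX` (two lowercase base-36
#' triplets) and is derived deterministically from a content hash over the
#' study name, the subjects' raw-file contents, the ordered workflow
#' (plugin ids, settings names and settings values) and the embedded
#' plugin sources. Identical content always yields the same identifier;
#' changing a single settings value changes it. Identifiers are computed
#' locally, so determinism substitutes for central uniqueness.
#'
#' @param study a [ts_study()].
#' @return the identifier string.
#' @export
compute_uwid <- function(study) {
  stopifnot(inherits(study, "ts_study"))
  content <- list(
    name = study$name,
    subjects = lapply(study$subjects, function(s) {
      list(name = s$name,
           files = lapply(s$raw_files, hash_raw))
    }),
    workflow = lapply(study$workflow, function(inst) {
      list(plugin_id = inst$plugin_id,
           settings_name = inst$settings_name,
           settings = inst$settings)
    }),
    plugin_sources = study$plugin_sources
  )
  h <- hash_object(content)
  n1 <- strtoi(substr(h, 1, 6), 16L) %% 46656L
  n2 <- strtoi(substr(h, 7, 12), 16L) %% 46656L
  sprintf("ts-%s-%s", base36(n1, 3L), base36(n2, 3L))
}

#' Assign the content-derived identifier to a study
#'
#' Computes [compute_uwid()] and stores it on the study. The study must
#' validate cleanly. Assigning is idempotent for identical content;
#' changing content after assignment invalidates the stored identifier
#' (export refreshes it).
#'
#' @param study a [ts_study()].
#' @return the study with `uwid` set.
#' @export
assign_uwid <- function(study) {
  study <- snapshot_sources(study)
  v <- validate_study(study)
  if (length(v)) {
    pf_error(paste0("study does not validate: ", paste(v, collapse = "; ")),
             "pf_bundle_error")
  }
  study$uwid <- compute_uwid(study)
  study
}

#' Lock a study for archival
#'
#' After publication a study is locked: the lock flag is set and all
#' editing operations refuse to touch the study from then on. Locking
#' requires a clean validation and an assigned identifier; a locked study
#' exported to a bundle stays locked when re-imported. The lock is
#' enforced in software (mutators check the flag); it is archival, not
#' cryptographic.
#'
#' @param study a [ts_study()] with a uwid assigned.
#' @return the locked study.
#' @export
lock_study <- function(study) {
  stopifnot(inherits(study, "ts_study"))
  if (isTRUE(study$locked)) {
    pf_error("study is already locked", "pf_bundle_error")
  }
  if (is.null(study$uwid)) {
    pf_error("assign a uwid before locking (see assign_uwid())",
             "pf_bundle_error")
  }
  study <- snapshot_sources(study)
  v <- validate_study(study)
  if (length(v)) {
    pf_error(paste0("study does not validate: ", paste(v, collapse = "; ")),
             "pf_bundle_error")
  }
  study$locked <- TRUE
  study
}

# Ensure every workflow stage has an embedded source snapshot (taken from
# the registry for plugins that have not run yet).
snapshot_sources <- function(study) {
  for (inst in study$workflow) {
    if (is.null(study$plugin_sources[[inst$source_ref]])) {
      entry <- registry_get(inst$plugin_id)
      study$plugin_sources[[inst$source_ref]] <- entry$source
    }
  }
  study
}

#' Export a study as a self-contained bundle
#'
#' Writes a single archive (uncompressed tar with a JSON manifest) holding
#' everything needed to reproduce the analysis on another machine: study
#' metadata (engine version, lock state, identifier), every raw file
#' byte-exact, all measured and derived data, the ordered workflow with
#' its settings, the source snapshot of every referenced plugin, and the
#' provenance log. If no identifier is assigned yet, one is computed and
#' embedded. Numeric data are stored in an exact text encoding, so a
#' bundle round-trip reproduces the study field-by-field, bit for bit.
#'
#' @param study a [ts_study()] that validates cleanly.
#' @param path output file path (conventionally `.tsb`).
#' @return the study as exported (sources snapshotted, uwid assigned),
#'   invisibly.
#' @export
export_bundle <- function(study, path) {
  stopifnot(inherits(study, "ts_study"))
  study <- snapshot_sources(study)
  v <- validate_study(study)
  if (length(v)) {
    pf_error(paste0("study does not validate: ", paste(v, collapse = "; ")),
             "pf_bundle_error")
  }
  if (is.null(study$uwid)) study$uwid <- compute_uwid(study)
  stage <- tempfile("pfbundle")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  subj_entries <- list()
  for (i in seq_along(study$subjects)) {
    s <- study$subjects[[i]]
    sdir <- sprintf("data/subject%03d", i)
    dir.create(file.path(stage, sdir, "files"), recursive = TRUE,
               showWarnings = FALSE)
    files <- list()
    for (fn in names(s$raw_files)) {
      rel <- file.path(sdir, "files", fn)
      writeBin(s$raw_files[[fn]], file.path(stage, rel))
      files[[length(files) + 1L]] <- list(name = fn, path = rel,
                                          md5 = hash_raw(s$raw_files[[fn]]))
    }
    mods <- list()
    for (mn in names(s$modalities)) {
      rel <- file.path(sdir, paste0("modality_", mn, ".json"))
      jsonlite::write_json(encode_payload(s$modalities[[mn]]),
                           file.path(stage, rel), auto_unbox = TRUE,
                           null = "null", digits = NA)
      mods[[length(mods) + 1L]] <- list(name = mn, path = rel)
    }
    subj_entries[[i]] <- list(name = s$name, files = files,
                              modalities = mods)
  }
  dir.create(file.path(stage, "plugins"), showWarnings = FALSE)
  src_entries <- list()
  for (id in names(study$plugin_sources)) {
    rel <- file.path("plugins",
                     paste0(gsub("/", "__", id, fixed = TRUE), ".R"))
    # byte-exact: sources must round-trip identically for uwid stability
    writeBin(charToRaw(enc2utf8(study$plugin_sources[[id]])),
             file.path(stage, rel))
    src_entries[[length(src_entries) + 1L]] <- list(plugin_id = id,
                                                    path = rel)
  }
  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    name = study$name,
    uwid = study$uwid,
    locked = isTRUE(study$locked),
    engine_version = study$engine_version,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    subjects = subj_entries,
    workflow = lapply(study$workflow, function(inst) {
      list(plugin_id = inst$plugin_id,
           settings_name = inst$settings_name,
           source_ref = inst$source_ref,
           settings = encode_payload(inst$settings))
    }),
    plugin_sources = src_entries,
    provenance = encode_payload(lapply(study$provenance, unclass))
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out_path <- file.path(normalizePath(dirname(path)), basename(path))
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE)
  files <- list.files(".", recursive = TRUE, all.files = TRUE,
                      no.. = TRUE)
  utils::tar(out_path, files = files, tar = "internal")
  setwd(old)
  invisible(study)
}

manifest_field <- function(manifest, field, type_check, type_desc) {
  val <- manifest[[field]]
  if (is.null(val) || !type_check(val)) {
    pf_error(sprintf("bundle manifest invalid: field '%s' missing or not %s",
                     field, type_desc), "pf_manifest_error")
  }
  val
}

#' Import a study bundle
#'
#' Reconstructs the exported study field-by-field, raw bytes included.
#' The embedded plugin sources stay embedded in the returned study — the
#' engine compiles them into a run-local registry when the workflow runs,
#' so imported plugins shadow nothing globally registered. Manifest
#' problems are reported naming the offending field; a bundle written by
#' an incompatible engine is reported with both versions named.
#'
#' @param path bundle file path.
#' @return the reconstructed [ts_study()].
#' @export
import_bundle <- function(path) {
  stopifnot(file.exists(path))
  stage <- tempfile("pfimport")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  ok <- tryCatch({
    utils::untar(path, exdir = stage, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  mf_path <- file.path(stage, "manifest.json")
  if (!ok || !file.exists(mf_path)) {
    pf_error(sprintf("'%s' is not a readable study bundle (corrupt archive or missing manifest)",
                     path), "pf_bundle_error")
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  fv <- manifest_field(manifest, "format_version",
                       function(x) is.numeric(x) && length(x) == 1L,
                       "a number")
  if (fv > BUNDLE_FORMAT_VERSION) {
    pf_error(sprintf("bundle format version %s is newer than this engine supports (%s; engine %s)",
                     fv, BUNDLE_FORMAT_VERSION, engine_version()),
             "pf_version_error")
  }
  name <- manifest_field(manifest, "name", is_string, "a string")
  locked <- manifest_field(manifest, "locked",
                           function(x) is.logical(x) && length(x) == 1L,
                           "a boolean")
  eng <- manifest_field(manifest, "engine_version", is_string, "a string")
  subjects_m <- manifest_field(manifest, "subjects", is.list, "a list")
  workflow_m <- manifest_field(manifest, "workflow", is.list, "a list")
  sources_m <- manifest_field(manifest, "plugin_sources", is.list,
                              "a list")
  study <- ts_study(name)
  study$engine_version <- eng
  study$uwid <- manifest$uwid
  for (se in subjects_m) {
    nm <- manifest_field(se, "name", is_string, "a string")
    subj <- ts_subject(nm)
    for (fe in se$files %||% list()) {
      fp <- file.path(stage, fe$path)
      if (!file.exists(fp)) {
        pf_error(sprintf("bundle manifest invalid: raw file '%s' listed but absent",
                         fe$path), "pf_manifest_error")
      }
      bytes <- readBin(fp, "raw", file.size(fp))
      if (!is.null(fe$md5) && !identical(hash_raw(bytes), fe$md5)) {
        pf_error(sprintf("raw file '%s' fails its checksum", fe$name),
                 "pf_bundle_error")
      }
      subj$raw_files[[fe$name]] <- bytes
    }
    for (me in se$modalities %||% list()) {
      enc <- jsonlite::read_json(file.path(stage, me$path),
                                 simplifyVector = FALSE)
      subj$modalities[[me$name]] <- decode_payload(enc)
    }
    study$subjects[[length(study$subjects) + 1L]] <- subj
  }
  for (we in workflow_m) {
    inst <- structure(list(
      plugin_id = manifest_field(we, "plugin_id", is_string, "a string"),
      settings_name = we$settings_name %||% "default",
      settings = decode_payload(we$settings),
      source_ref = we$source_ref %||% we$plugin_id),
      class = "plugin_instance")
    study$workflow[[length(study$workflow) + 1L]] <- inst
  }
  for (pe in sources_m) {
    sp <- file.path(stage, pe$path)
    if (!file.exists(sp)) {
      pf_error(sprintf("bundle manifest invalid: plugin source '%s' listed but absent",
                       pe$path), "pf_manifest_error")
    }
    study$plugin_sources[[pe$plugin_id]] <-
      rawToChar(readBin(sp, "raw", file.size(sp)))
  }
  if (!is.null(manifest$provenance)) {
    study$provenance <- lapply(decode_payload(manifest$provenance),
                               function(r) structure(r,
                                 class = "provenance_record"))
  }
  study$locked <- locked
  study
}
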