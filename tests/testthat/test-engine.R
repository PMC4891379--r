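interp_inst <- function(max_gap = 5, method = "linear")
  instantiate("core/interpolate_gaps",
              overrides = list(max_gap = max_gap, method = method,
                               channels = "pupil"))
filter_inst <- function(halfwidth = 1, statistic = "median")
  instantiate("core/filter_moving_average",
              overrides = list(halfwidth = halfwidth,
                               statistic = statistic))

test_that("an empty plugin selection is a no-op with an empty report", {
  study <- toy_study()
  study <- workflow_append(study, interp_inst())
  res <- run_workflow(study, plugins = integer(0))
  expect_identical(fingerprint(res$study), fingerprint(study))
  expect_identical(nrow(res$report), 0L)
  expect_length(res$study$provenance, 0)
})

test_that("a two-stage workflow equals the manual composition of the operations", {
  v <- c(1, NA, 3, 4, 100, 6, 7, NA, NA, 10)
  study <- toy_study(values = v)
  study <- workflow_append(study, interp_inst())
  study <- workflow_append(study, filter_inst())
  res <- run_workflow(study)
  manual <- moving_filter(interpolate_gaps(toy_channel(v), 5, "linear"),
                          1, "median")
  expect_identical(toy_pupil(res$study), manual$values)
})

test_that("plugins run in workflow order even when selected in reverse", {
  v <- c(1, NA, 3, 4, 100, 6, 7)
  study <- toy_study(values = v)
  study <- workflow_append(study, interp_inst())
  study <- workflow_append(study, filter_inst())
  res <- run_workflow(study, plugins = c(2, 1))
  manual <- moving_filter(interpolate_gaps(toy_channel(v), 5, "linear"),
                          1, "median")
  expect_identical(toy_pupil(res$study), manual$values)
})

test_that("swapping non-commuting stages changes the output", {
  # median filtering before interpolation leaves different values than
  # interpolating first: the filter sees the gap, interpolation sees
  # filtered flanks
  v <- c(0, 0, 0, NA, NA, 10, 10, 10)
  s1 <- toy_study(values = v)
  s1 <- workflow_append(s1, interp_inst())
  s1 <- workflow_append(s1, filter_inst())
  s2 <- toy_study(values = v)
  s2 <- workflow_append(s2, filter_inst())
  s2 <- workflow_append(s2, interp_inst())
  r1 <- run_workflow(s1)
  r2 <- run_workflow(s2)
  expect_false(identical(toy_pupil(r1$study), toy_pupil(r2$study)))
})

test_that("identical inputs and seed give bit-identical derived data and report", {
  study <- small_case_study(seed = 6, bootstrap = TRUE)
  r1 <- run_workflow(study, seed = 17)
  r2 <- run_workflow(study, seed = 17)
  expect_identical(fingerprint(r1$study), fingerprint(r2$study))
  expect_identical(r1$report[c("stage", "plugin_id", "subject", "status")],
                   r2$report[c("stage", "plugin_id", "subject", "status")])
  expect_identical(r1$outputs$stage06_test_bootstrap$bootstrap$p_value,
                   r2$outputs$stage06_test_bootstrap$bootstrap$p_value)
  r3 <- run_workflow(study, seed = 18)
  expect_false(identical(
    r1$outputs$stage06_test_bootstrap$bootstrap$p_value,
    r3$outputs$stage06_test_bootstrap$bootstrap$p_value))
})

test_that("unselected subjects are untouched", {
  study <- small_case_study(seed = 7)
  res <- run_workflow(study, subjects = 1)
  expect_identical(fingerprint(res$study, 2), fingerprint(study, 2))
  expect_false(identical(fingerprint(res$study, 1), fingerprint(study, 1)))
})

test_that("a failing plugin aborts by default but continues per subject on request", {
  fail_src <- paste(
    'declare <- function() pupilflow::plugin_spec("check/fail",',
    '  "custom/check", scope = "subject")',
    'configure <- function(settings, spec)',
    '  pupilflow::configure_by_schema(settings, spec)',
    'process <- function(study, subjects, settings, ctx) {',
    '  nm <- study$subjects[[subjects]]$name',
    '  if (nm == "S01") stop("deliberate failure") else study',
    '}', sep = "\n")
  reg <- new.env()
  register_plugin_source(fail_src, registry = reg)
  study <- toy_study()
  s2 <- ts_subject("S02")
  s2$modalities$eyetracking <- ts_modality(
    channels = list(pupil = toy_channel(c(5, NA, 7))))
  study <- add_subject(study, s2)
  study <- workflow_append(study, interp_inst())
  study <- workflow_append(study, instantiate("check/fail", registry = reg))
  study$plugin_sources[["check/fail"]] <- fail_src

  err <- expect_error(run_workflow(study), class = "pf_run_error")
  expect_match(conditionMessage(err), "check/fail")
  expect_match(conditionMessage(err), "S01")

  res <- run_workflow(study, error_policy = "continue")
  bad <- res$report[res$report$status == "error", ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$subject, "S01")
  # the prior stage's output on the failing subject is intact
  expect_identical(toy_pupil(res$study, 1),
                   interpolate_gaps(toy_channel(c(1, NA, 3, 4, 100, 6, 7)),
                                    5, "linear")$values)
})

test_that("progress covers plugins x subjects and provenance is appended per plugin", {
  study <- small_case_study(seed = 8)
  msgs <- capture_messages(res <- run_workflow(study, progress = TRUE))
  expect_true(any(grepl("progress: 10/10", msgs)))
  expect_length(res$study$provenance, 5)
  pv <- res$study$provenance[[3]]
  expect_identical(pv$plugin_id, "core/interpolate_gaps")
  expect_identical(pv$engine_version, engine_version())
  expect_identical(pv$subjects, c("S01", "S02"))
  # rerunning appends records identical except timestamps
  res2 <- run_workflow(res$study)
  pv2 <- res2$study$provenance[[8]]
  a <- pv; a$timestamp <- NULL; a$input_hash <- NULL; a$output_hash <- NULL
  b <- pv2; b$timestamp <- NULL; b$input_hash <- NULL; b$output_hash <- NULL
  expect_identical(unclass(a), unclass(b))
})

test_that("a run snapshots executed plugin sources into the study", {
  study <- small_case_study(seed = 9)
  expect_length(study$plugin_sources, 0)
  res <- run_workflow(study)
  expect_setequal(names(res$study$plugin_sources),
                  vapply(study$workflow, `[[`, character(1), "plugin_id"))
})

test_that("embedded sources shadow the global registration for reproduction", {
  # a study carrying a modified interpolation source must use it
  entry <- pupilflow:::registry_get("core/interpolate_gaps")
  hacked <- sub("interpolate_gaps\\(", "identity_stub(", entry$source)
  hacked <- paste("identity_stub <- function(ch, ...) ch", hacked,
                  sep = "\n")
  study <- toy_study(values = c(1, NA, 3))
  study <- workflow_append(study, interp_inst())
  study$plugin_sources[["core/interpolate_gaps"]] <- hacked
  res <- run_workflow(study)
  expect_identical(toy_pupil(res$study), c(1, NA, 3))  # stub did nothing
})

test_that("invalid selections are rejected", {
  study <- toy_study()
  study <- workflow_append(study, interp_inst())
  expect_error(run_workflow(study, subjects = 2), class = "pf_run_error")
  expect_error(run_workflow(study, plugins = 99), class = "pf_run_error")
})
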