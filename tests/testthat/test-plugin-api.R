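noop_spec <- function(id = "check/noop", scope = "group") {
  function() plugin_spec(id, "custom/check", scope = scope,
                         settings = list(k = setting_int(1, min = 0)))
}
noop_process <- function(study, subjects, settings, ctx) study

test_that("registration requires all three entry points, named when absent", {
  reg <- new.env()
  err <- expect_error(
    register_plugin(declare = noop_spec(), process = noop_process,
                    registry = reg),
    class = "pf_contract_error")
  expect_match(conditionMessage(err), "configure")
  err2 <- expect_error(register_plugin(declare = noop_spec(),
                                       registry = reg),
                       class = "pf_contract_error")
  expect_match(conditionMessage(err2), "configure")
  expect_match(conditionMessage(err2), "process")
})

test_that("duplicate plugin ids are rejected", {
  reg <- new.env()
  register_plugin(noop_spec(), configure_by_schema, noop_process,
                  registry = reg)
  expect_error(register_plugin(noop_spec(), configure_by_schema,
                               noop_process, registry = reg),
               class = "pf_duplicate_error")
})

test_that("the built-in registry lists the five core stages and the custom test plugin", {
  core <- registered_plugins("core")
  expect_setequal(core$plugin_id,
                  c("core/read_file", "core/modify_events",
                    "core/interpolate_gaps", "core/filter_moving_average",
                    "core/event_related_data_extraction"))
  custom <- registered_plugins("custom/test")
  expect_true("test/bootstrap" %in% custom$plugin_id)
})

test_that("instantiate merges defaults, stored sets and overrides in order", {
  # defaults only
  inst0 <- instantiate("core/filter_moving_average")
  expect_identical(inst0$settings$halfwidth, 5L)
  expect_identical(inst0$settings$statistic, "mean")
  # overrides win; an 11-sample effective window at halfwidth 5
  inst <- instantiate("core/filter_moving_average", "default",
                      list(halfwidth = 5, statistic = "median"))
  expect_identical(2L * inst$settings$halfwidth + 1L, 11L)
  expect_identical(inst$settings$statistic, "median")
  # stored named set sits between defaults and overrides
  store <- settings_store(tempfile("store"))
  save_settings(store, "core/filter_moving_average", "noName",
                list(halfwidth = 3, statistic = "median"))
  inst2 <- instantiate("core/filter_moving_average", "noName",
                       overrides = list(halfwidth = 7), store = store)
  expect_identical(inst2$settings$halfwidth, 7L)
  expect_identical(inst2$settings$statistic, "median")
})

test_that("settings validation is total and names the offending key", {
  err <- expect_error(
    instantiate("core/filter_moving_average", "default",
                list(halfwidth = -1)),
    class = "pf_settings_error")
  expect_match(conditionMessage(err), "halfwidth")
  err2 <- expect_error(
    instantiate("core/filter_moving_average", "default",
                list(nonsense = 1)),
    class = "pf_settings_error")
  expect_match(conditionMessage(err2), "nonsense")
  err3 <- expect_error(
    instantiate("core/filter_moving_average", "default",
                list(statistic = "mode")),
    class = "pf_settings_error")
  expect_match(conditionMessage(err3), "statistic")
})

test_that("named settings round-trip through the store", {
  store <- settings_store(tempfile("store"))
  s <- list(halfwidth = 2, statistic = "median", channels = "pupil")
  save_settings(store, "core/filter_moving_average", "smooth", s)
  expect_identical(load_settings(store, "core/filter_moving_average",
                                 "smooth"), s)
  inst <- instantiate("core/filter_moving_average", "smooth",
                      store = store)
  expect_identical(inst$settings$halfwidth, 2L)
  expect_error(load_settings(store, "core/filter_moving_average", "gone",
                             must_exist = TRUE),
               class = "pf_settings_error")
})

test_that("generated templates are deterministic, registrable and runnable no-ops", {
  src1 <- generate_plugin_template("check", "tmpl")
  src2 <- generate_plugin_template("check", "tmpl")
  expect_identical(src1, src2)   # byte-identical generation
  reg <- new.env()
  register_plugin_source(src1, registry = reg)
  inst <- instantiate("check/tmpl", registry = reg)
  expect_identical(inst$settings$method, "a")
  # a template runs unmodified on an empty study without error
  study <- ts_study("empty")
  study$workflow <- list(inst)
  study$plugin_sources[["check/tmpl"]] <- src1
  res <- run_workflow(study)
  expect_identical(res$report$status, "ok")
  # written form lands in <category>_<name>.R and still registers
  d <- tempfile("plugdir")
  generate_plugin_template("check", "tmpl2", dir = d)
  f <- file.path(d, "check_tmpl2.R")
  expect_true(file.exists(f))
  reg2 <- new.env()
  expect_identical(register_plugin_source(file = f, registry = reg2),
                   "check/tmpl2")
})

test_that("template generation rejects bad identifiers and unknown kinds", {
  expect_error(generate_plugin_template("a b", "x"),
               class = "pf_template_error")
  expect_error(generate_plugin_template("test", "1bad"),
               class = "pf_template_error")
  expect_error(generate_plugin_template("test", "ok",
                                        template_kind = "fancy"),
               class = "pf_template_error")
})

test_that("any registered plugin instantiates with defaults and runs on an empty study", {
  ids <- registered_plugins()$plugin_id
  study <- ts_study("empty")
  for (id in ids) study <- workflow_append(study, instantiate(id))
  res <- run_workflow(study, seed = 1)
  expect_true(all(res$report$status == "ok"))
  expect_identical(fingerprint(res$study), fingerprint(study))
})
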