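test_that("the hand-computed 10 Hz example extracts exactly", {
  ch <- toy_channel(1:10, rate = 10)
  ev <- event_list("a", 0)
  res <- extract_event_related(ch, ev, "a", trial_window = c(0, 1),
                               baseline_window = c(0, 0.5),
                               measure_window = c(0, 1),
                               measures = c("mean", "median", "min", "max",
                                            "latency_to_min",
                                            "latency_to_max", "range"))
  tr <- res$data$conditions$a$trials
  # baseline mean of samples 1..5 is 3; corrected trial is -2..7
  expect_equal(as.vector(tr), as.numeric(-2:7))
  m <- res$measures
  val <- function(which) m$value[m$measure == which]
  expect_equal(val("mean"), 2.5)
  expect_equal(val("median"), 2.5)
  expect_equal(val("min"), -2)
  expect_equal(val("max"), 7)
  expect_equal(val("latency_to_min"), 0)
  expect_equal(val("latency_to_max"), 0.9)
  expect_equal(val("range"), 9)
  expect_identical(res$dropped, 0L)
})

test_that("an identically-zero channel yields all-zero trials and measures", {
  ch <- toy_channel(rep(0, 100), rate = 10)
  ev <- event_list(c("a", "a"), c(1, 4))
  res <- extract_event_related(ch, ev, "a", trial_window = c(0, 2),
                               baseline_window = c(0, 1),
                               measure_window = c(1, 2),
                               measures = c("mean", "median", "min", "max",
                                            "range"))
  expect_true(all(res$data$conditions$a$trials == 0))
  expect_true(all(res$measures$value[res$measures$measure != "latency"]
                  == 0))
})

test_that("baseline means are zero after correction", {
  set.seed(11)
  ch <- toy_channel(3 + cumsum(rnorm(2000, 0, 0.1)), rate = 50)
  ev <- event_list(rep(c("x", "y"), 3), c(2, 7, 13, 19, 25, 31))
  res <- extract_event_related(ch, ev, c("x", "y"),
                               trial_window = c(0, 5),
                               baseline_window = c(0, 2),
                               measure_window = c(3, 4))
  for (cn in c("x", "y")) {
    tr <- res$data$conditions[[cn]]$trials
    bsel <- 1:100  # [0,2) at 50 Hz
    scale <- max(1, max(abs(tr)))
    expect_lt(max(abs(rowMeans(tr[, bsel]))), 1e-9 * scale)
  }
})

test_that("trial count equals matching events fully inside the recording", {
  ch <- toy_channel(rep(1, 100), rate = 10)   # 10 s of data
  ev <- event_list(c("a", "a", "a", "b"), c(0, 4, 8.5, 2))
  res <- extract_event_related(ch, ev, "a", trial_window = c(0, 2),
                               baseline_window = c(0, 1),
                               measure_window = c(1, 2))
  # the 8.5 s event needs samples up to 10.4 s: dropped
  expect_identical(nrow(res$data$conditions$a$trials), 2L)
  expect_identical(res$dropped, 1L)
})

test_that("half-open windows do not share boundary samples", {
  ch <- toy_channel(1:20, rate = 10)
  res <- extract_event_related(ch, event_list("a", 0),
                               "a", trial_window = c(0, 2),
                               baseline_window = c(0, 1),
                               measure_window = c(1, 2))
  # baseline [0,1) covers samples 1..10, measure [1,2) covers 11..20
  tr <- as.vector(res$data$conditions$a$trials)
  expect_equal(mean(tr[1:10]), 0)
  expect_equal(res$measures$value[res$measures$measure == "mean"],
               mean(tr[11:20]))
})

test_that("window ordering and unknown measures are rejected", {
  ch <- toy_channel(1:100, rate = 10)
  ev <- event_list("a", 1)
  expect_error(extract_event_related(ch, ev, "a", c(0, 2), c(-1, 1),
                                     c(1, 2)),
               class = "pf_op_error")
  expect_error(extract_event_related(ch, ev, "a", c(0, 2), c(0, 1),
                                     c(1, 3)),
               class = "pf_op_error")
  expect_error(extract_event_related(ch, ev, "a", c(0, 2), c(0, 1),
                                     c(1, 2), measures = "mode"),
               class = "pf_op_error")
  expect_error(extract_event_related(ch, ev, "missing", c(0, 2), c(0, 1),
                                     c(1, 2)),
               class = "pf_op_error")
})

test_that("confidence bands are mean +/- z * SE across trials", {
  set.seed(5)
  ch <- toy_channel(rnorm(100), rate = 10)
  ev <- event_list(rep("a", 4), c(0, 1, 2, 3))
  res <- extract_event_related(ch, ev, "a", c(0, 1), c(0, 0.5), c(0.5, 1),
                               conf_level = 0.95)
  cv <- res$curves
  i <- 3
  tr <- res$data$conditions$a$trials[, i]
  se <- sd(tr) / sqrt(length(tr))
  expect_equal(cv$lo[i], mean(tr) - qnorm(0.975) * se)
  expect_equal(cv$hi[i], mean(tr) + qnorm(0.975) * se)
})

test_that("per-subject condition means ignore missing and flag absent conditions", {
  # single-trial conditions pass trial values through; NA is ignored
  study <- small_case_study(seed = 2)
  res <- run_workflow(study, seed = 1)
  study2 <- res$study
  # inject a missing trial value and recompute
  erd <- study2$subjects[[1]]$modalities$eyetracking$derived$eventrelateddata
  tv <- erd$conditions$easy$trialvalues
  erd$conditions$easy$trialvalues <- c(tv, NA)
  study2$subjects[[1]]$modalities$eyetracking$derived$eventrelateddata <- erd
  mat <- summarize_per_subject(study2, c("easy", "medium", "difficult"))
  expect_equal(mat["easy", 1], mean(tv))
  expect_error(summarize_per_subject(study2, "impossible"),
               class = "pf_op_error")
})

test_that("missing-ignoring mean matches the hand example", {
  study <- toy_study(values = rep(0, 10))
  erd <- structure(list(conditions = list(easy = list(
    trialvalues = c(1, 2, NA)))), class = "event_related_data")
  study$subjects[[1]]$modalities$eyetracking$derived$eventrelateddata <- erd
  mat <- summarize_per_subject(study, "easy")
  expect_identical(as.vector(mat), 1.5)
})
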