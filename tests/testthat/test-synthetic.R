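test_that("the trial schedule places multiplicand at +2 s and multiplier at +4 s", {
  cfg <- small_sim_config()
  rec <- simulate_recording(cfg, "S01", seed = 4)
  ev <- rec$modality$events
  for (k in seq_len(nrow(rec$schedule))) {
    on <- rec$schedule$onset[k]
    onset_names <- ev$name[ev$time == on]
    expect_match(onset_names, "^mmult_")
    expect_true("multiplicand" %in% ev$name[ev$time == on + 2])
    expect_true("multiplier" %in% ev$name[ev$time == on + 4])
  }
})

test_that("operand pairs respect the per-condition ranges", {
  cfg <- simulation_config(n_subjects = 1, trials_per_condition = 20)
  rec <- simulate_recording(cfg, "S01", seed = 9)
  sch <- rec$schedule
  rng <- list(easy = 1:9, medium = 6:14, difficult = 11:19)
  for (cn in names(rng)) {
    rows <- sch[sch$condition == cn, ]
    expect_identical(nrow(rows), 20L)
    expect_true(all(rows$multiplicand %in% rng[[cn]]))
    expect_true(all(rows$multiplier %in% rng[[cn]]))
  }
  # trigger names carry the operand pair
  expect_true(all(grepl("^mmult_(easy|medium|difficult)_\\d{2}x\\d{2}$",
                        rec$modality$events$name[
                          startsWith(rec$modality$events$name, "mmult")])))
})

test_that("a null configuration yields a constant pupil at baseline with events intact", {
  cfg <- simulation_config(n_subjects = 1, trials_per_condition = 2,
                           noise_sd = 0, blink_rate = 0, outlier_rate = 0,
                           baseline_sd_between = 0, amplitude_jitter = 0,
                           amplitudes = c(easy = 0, medium = 0,
                                          difficult = 0))
  rec <- simulate_recording(cfg, "S01", seed = 2)
  expect_true(all(rec$modality$channels$pupil$values == cfg$baseline_pupil))
  expect_identical(nrow(rec$modality$events), 3L * nrow(rec$schedule))
})

test_that("noiseless dilation over [6,7) matches the kernel-mean oracle", {
  cfg <- simulation_config(n_subjects = 1, trials_per_condition = 3,
                           noise_sd = 0, blink_rate = 0, outlier_rate = 0,
                           baseline_sd_between = 0, amplitude_jitter = 0,
                           iti = 20,   # long gaps: no cross-trial bleed
                           amplitudes = c(easy = 0, medium = 0,
                                          difficult = 0.3))
  rec <- simulate_recording(cfg, "S01", seed = 6)
  ch <- rec$modality$channels$pupil
  # numerical-evaluation oracle: amplitude times the mean kernel value at
  # the sample offsets of the [6,7) s window
  oracle <- 0.3 * mean(pupil_kernel((300:349) / 50, cfg$kernel_peak,
                                    cfg$kernel_width))
  sch <- rec$schedule[rec$schedule$condition == "difficult", ]
  for (on in sch$onset) {
    i0 <- round(on * 50)
    got <- mean(ch$values[(i0 + 301):(i0 + 350)]) - cfg$baseline_pupil
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("combined-file export round-trips exactly and has one row per sample", {
  cfg <- small_sim_config()
  rec <- simulate_recording(cfg, "S01", seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_clearview_file(rec$modality, f)
  n_expected <- as.integer((cfg$lead_in +
    3 * cfg$trials_per_condition * (cfg$epoch + cfg$iti)) *
    cfg$sample_rate)
  expect_identical(length(readLines(f)) - 1L, n_expected)
  m2 <- read_columnar_file(file = f, map = clearview_column_map())
  for (cn in names(rec$modality$channels)) {
    expect_identical(m2$channels[[cn]]$values,
                     rec$modality$channels[[cn]]$values)
  }
  expect_identical(as.data.frame(m2$events),
                   as.data.frame(rec$modality$events))
  # gaze, pupil and events all live in the same file
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header, c("Timestamp", "GazepointX", "GazepointY",
                             "Pupil", "Event"))
})

test_that("blink-gap lengths follow the configured shifted-Poisson distribution", {
  cfg <- simulation_config(n_subjects = 1, trials_per_condition = 12,
                           blink_rate = 30, blink_gap_mean = 8)
  lens <- unlist(lapply(1:8, function(i) {
    simulate_recording(cfg, "S", seed = 100 + i)$gap_lengths
  }))
  expect_gt(length(lens), 300)
  k <- 0:25
  p <- dpois(k, cfg$blink_gap_mean - 2)
  obs <- tabulate(factor(lens - 2L, levels = k), nbins = length(k))
  keep <- p * length(lens) >= 5   # merge sparse tail bins
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], 1 - sum(p[keep]))
  gof <- suppressWarnings(chisq.test(obs2, p = p2, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("equal amplitudes leave no systematic condition separation", {
  cfg <- simulation_config(n_subjects = 6, trials_per_condition = 6,
                           amplitudes = c(easy = 0.15, medium = 0.15,
                                          difficult = 0.15))
  study <- simulate_study(cfg, seed = 21)
  study <- load_workflow(study, shipped_workflow("case_study"))
  out <- run_workflow(study, seed = 21)
  mat <- summarize_per_subject(out$study, c("easy", "medium", "difficult"))
  m <- rowMeans(mat)
  se <- apply(mat, 1, sd) / sqrt(ncol(mat))
  expect_lt(max(m) - min(m), 2 * max(se) + 2 * mean(se))
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(sample_rate = 0))
  expect_error(simulation_config(amplitudes = c(easy = -1, medium = 0,
                                                difficult = 0)))
  expect_error(simulation_config(blink_rate = -1))
})
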