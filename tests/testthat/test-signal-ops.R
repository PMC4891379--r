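# ---- gap interpolation ------------------------------------------------------

test_that("a channel without missing samples passes through identically", {
  ch <- toy_channel(c(1, 2, 3, 4))
  expect_identical(interpolate_gaps(ch, 5)$values, c(1, 2, 3, 4))
})

test_that("linear interpolation fills interior gaps as hand-computed", {
  expect_identical(interpolate_gaps(toy_channel(c(1, NA, 3)), 5,
                                    "linear")$values, c(1, 2, 3))
  # len-4 gap between 1 and 6: fills 2,3,4,5
  expect_equal(interpolate_gaps(toy_channel(c(1, NA, NA, NA, NA, 6)), 5,
                                "linear")$values, 1:6)
})

test_that("the gap-length threshold is strict: length < max_gap fills, = max_gap does not", {
  gap5 <- c(1, rep(NA, 5), 7)
  gap4 <- c(1, rep(NA, 4), 6)
  expect_identical(interpolate_gaps(toy_channel(gap5), 5)$values, gap5)
  expect_identical(interpolate_gaps(toy_channel(gap4), 5)$values,
                   as.numeric(1:6))
})

test_that("edge gaps are never filled", {
  left <- c(NA, NA, 3, 4)
  right <- c(1, 2, NA, NA)
  expect_identical(interpolate_gaps(toy_channel(left), 10)$values, left)
  expect_identical(interpolate_gaps(toy_channel(right), 10)$values, right)
})

test_that("the jump criterion excludes gaps with discordant flanks", {
  v <- c(0, NA, 10)
  expect_identical(interpolate_gaps(toy_channel(v), 5, max_jump = 5)$values,
                   v)
  expect_identical(interpolate_gaps(toy_channel(v), 5,
                                    max_jump = 10)$values, c(0, 5, 10))
})

test_that("the valid-range criterion excludes out-of-range insertions", {
  v <- c(0, NA, 10)
  expect_identical(interpolate_gaps(toy_channel(v), 5,
                                    valid_range = c(0, 4))$values, v)
  expect_identical(interpolate_gaps(toy_channel(v), 5,
                                    valid_range = c(0, 10))$values,
                   c(0, 5, 10))
})

test_that("nearest-neighbour filling takes the closer flank, earlier on ties", {
  out <- interpolate_gaps(toy_channel(c(1, NA, NA, NA, 9)), 5,
                          "nearest")$values
  expect_identical(out, c(1, 1, 1, 9, 9))
})

test_that("linear interpolation is exact on gaps punched into a linear signal", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 60
    line <- 0.3 + 0.07 * (0:(n - 1))
    v <- line
    holes <- sample(2:(n - 1), 12)
    v[holes] <- NA
    out <- interpolate_gaps(toy_channel(v), max_gap = n, "linear")$values
    expect_equal(out, line, tolerance = 1e-12)
  }
})

test_that("gap filling never modifies an originally valid sample (bitwise)", {
  set.seed(42)
  for (rep in 1:10) {
    v <- rnorm(200)
    v[sample(200, 40)] <- NA
    keep <- !is.na(v)
    for (meth in c("nearest", "linear", "cubic")) {
      out <- interpolate_gaps(toy_channel(v), 6, meth)$values
      expect_identical(out[keep], v[keep])
    }
  }
})

test_that("interpolation rejects bad arguments", {
  ch <- toy_channel(c(1, NA, 3))
  expect_error(interpolate_gaps(ch, 0), class = "pf_op_error")
  expect_error(interpolate_gaps(ch, 5, "quartic"))
  expect_error(interpolate_gaps(ch, 5, valid_range = c(2, 1)),
               class = "pf_op_error")
})

# ---- moving filter ----------------------------------------------------------

test_that("constant channels are fixed points of both statistics", {
  v <- rep(3.3, 25)
  expect_equal(moving_filter(toy_channel(v), 5, "mean")$values, v)
  expect_equal(moving_filter(toy_channel(v), 5, "median")$values, v)
})

test_that("median filter removes an isolated outlier (hand-computed)", {
  expect_identical(moving_filter(toy_channel(c(0, 0, 10, 0, 0)), 1,
                                 "median")$values, rep(0, 5))
  expect_equal(moving_filter(toy_channel(c(1, 2, 3)), 1, "mean")$values,
               c(1.5, 2, 2.5))
})

test_that("median filter with halfwidth h removes outlier runs of length <= h", {
  for (h in 1:4) {
    for (runlen in 1:h) {
      v <- rep(5, 30)
      v[15:(14 + runlen)] <- 50
      out <- moving_filter(toy_channel(v), h, "median")$values
      expect_identical(out, rep(5, 30))
    }
  }
})

test_that("filtering preserves symmetry (zero phase shift)", {
  set.seed(7)
  half <- rnorm(20)
  v <- c(half, 1.5, rev(half))   # symmetric about the centre sample
  for (st in c("mean", "median")) {
    out <- moving_filter(toy_channel(v), 3, st)$values
    expect_equal(out, rev(out))
  }
})

test_that("missing samples are ignored within windows; all-missing windows stay missing", {
  v <- c(1, NA, 3)
  expect_equal(moving_filter(toy_channel(v), 1, "mean")$values,
               c(1, 2, 3))
  v2 <- c(1, NA, NA, NA, 5)
  expect_identical(moving_filter(toy_channel(v2), 1, "mean")$values,
                   c(1, 1, NA, 5, 5))
})

test_that("negative halfwidth is rejected", {
  expect_error(moving_filter(toy_channel(1:5), -1), class = "pf_op_error")
})

# ---- event renaming ---------------------------------------------------------

test_that("an empty rule list is the identity", {
  ev <- event_list(c("A", "B"), c(1, 2))
  expect_identical(modify_events(ev, character()), ev)
})

test_that("rules rename by first match, preserving times and count", {
  ev <- event_list(c("A", "B", "C"), c(1, 2, 3))
  out <- modify_events(ev, c(A = "X", B = "X"))
  expect_identical(out$name, c("X", "X", "C"))
  expect_identical(out$time, ev$time)
  expect_identical(nrow(out), nrow(ev))
  # first matching rule wins
  out2 <- modify_events(event_list("AB", 1), c("A*" = "X", AB = "Y"))
  expect_identical(out2$name, "X")
})

test_that("wildcard rules group operand-carrying triggers into conditions", {
  ev <- event_list(c("mmult_easy_03x07", "mmult_difficult_12x19",
                     "multiplicand", "mmult_medium_08x11"),
                   c(2, 14, 4, 26))
  rules <- pupilflow:::parse_event_rules(
    "mmult_easy_* -> easy; mmult_medium_* -> medium; mmult_difficult_* -> difficult")
  out <- modify_events(ev, rules)
  expect_identical(out$name, c("easy", "multiplicand", "difficult",
                               "medium"))
})
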