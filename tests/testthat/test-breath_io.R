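test_that("two-column files infer the sampling rate from the time step", {
  fs <- 20
  flow <- sin(2 * pi * 0.25 * seq(0, 9.95, by = 0.05))
  path <- write_flow_csv(flow, fs)
  sig <- load_flow_signal(path)
  expect_s3_class(sig, "flow_signal")
  expect_equal(sig$sampling_rate, fs, tolerance = 1e-9)
  expect_equal(length(sig$samples), 200L)

  # headerless variant parses identically
  path2 <- write_flow_csv(flow, fs, header = FALSE)
  expect_equal(load_flow_signal(path2)$samples, sig$samples)
})

test_that("flow-only files pass samples through and require a rate", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("flow", sprintf("%.6f", rnorm(50))), path)
  sig <- load_flow_signal(path, format = "flow-only", sampling_rate = 20)
  expect_equal(length(sig$samples), 50L)
  expect_equal(sig$sampling_rate, 20)
  expect_error(load_flow_signal(path, format = "flow-only"),
               "sampling_rate")
})

test_that("malformed rows are rejected with the offending line", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time,flow", "0.00,0.5", "0.05,NaN", "0.10,0.7"), path)
  expect_error(load_flow_signal(path), "line 3")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("0.5", "abc", "0.7"), path2)
  expect_error(load_flow_signal(path2, format = "flow-only", sampling_rate = 20),
               "line 2")
  expect_error(load_flow_signal(tempfile(), format = "flow-only",
                                sampling_rate = 20), "does not exist")
})

test_that("irregular time grids beyond 1% are rejected", {
  path <- tempfile(fileext = ".csv")
  tm <- c(0, 0.05, 0.1, 0.18, 0.2, 0.25)
  writeLines(c("time,flow", paste(tm, rnorm(6), sep = ",")), path)
  expect_error(load_flow_signal(path), "non-uniform")
})

test_that("flow_signal validates its invariants", {
  expect_error(flow_signal(numeric(0), 20), "non-empty")
  expect_error(flow_signal(c(1, NA), 20), "finite")
  expect_error(flow_signal(1:5, -1), "positive")
})

test_that("low-pass filter passes DC and the respiratory band, kills noise", {
  fs <- 20
  const <- flow_signal(rep(3, 200), fs)
  expect_equal(lowpass_filter(const)$samples, rep(3, 200), tolerance = 1e-4)

  t <- seq(0, 30, by = 1 / fs)
  mid <- 200:400
  slow <- flow_signal(sin(2 * pi * 0.3 * t), fs)
  ratio_slow <- max(abs(lowpass_filter(slow)$samples[mid])) /
    max(abs(slow$samples[mid]))
  expect_gt(ratio_slow, 0.95)

  fast <- flow_signal(sin(2 * pi * 8 * t), fs)
  ratio_fast <- max(abs(lowpass_filter(fast)$samples[mid])) /
    max(abs(fast$samples[mid]))
  expect_lt(ratio_fast, 0.10)

  expect_error(lowpass_filter(const, cutoff = 10), "Nyquist")
  expect_error(lowpass_filter(const, cutoff = 12), "Nyquist")
})

test_that("filtering is idempotent for signals already band-limited", {
  fs <- 20
  t <- seq(0, 30, by = 1 / fs)
  sig <- flow_signal(sin(2 * pi * 0.4 * t) + 0.5 * sin(2 * pi * 0.8 * t), fs)
  once <- lowpass_filter(sig)
  twice <- lowpass_filter(once)
  expect_equal(twice$samples, once$samples, tolerance = 1e-3)
})

test_that("square-wave segmentation finds exact positive runs", {
  fs <- 20
  flow <- rep(c(rep(1, 10), rep(-1, 10)), 5)
  brs <- segment_inspirations(flow_signal(flow, fs), min_duration = 0.5)
  expect_length(brs, 5L)
  expect_true(all(vapply(brs, function(b) length(b$samples), integer(1)) == 10L))
  expect_equal(vapply(brs, function(b) b$start_index, numeric(1)),
               seq(0, 80, by = 20))
  # half-open spans: samples length equals end - start
  expect_true(all(vapply(brs, function(b)
    b$end_index - b$start_index == length(b$samples), logical(1))))
})

test_that("a 0.25 Hz sine yields one breath per positive half-cycle", {
  fs <- 20
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  brs <- segment_inspirations(flow_signal(sin(2 * pi * 0.25 * t), fs))
  expect_length(brs, 15L)  # positive half-cycles of a 4 s period over 60 s
  lens <- vapply(brs, function(b) length(b$samples), integer(1))
  # each ~2 s; grid-edge zeros can shift a crossing by a sample or two
  expect_true(all(abs(lens / fs - 2) <= 2 / fs))
})

test_that("segmentation returns an empty list when flow never turns positive", {
  expect_length(segment_inspirations(flow_signal(rep(-1, 100), 20)), 0L)
  # sub-threshold blips are discarded
  flow <- c(rep(-1, 50), rep(1, 3), rep(-1, 50))
  expect_length(segment_inspirations(flow_signal(flow, 20)), 0L)
})

test_that("segmented breaths are disjoint, ordered and positive", {
  set.seed(11)
  for (rep in 1:20) {
    flow <- as.numeric(stats::filter(rnorm(600), rep(1 / 8, 8), sides = 2))
    flow[is.na(flow)] <- 0
    sig <- flow_signal(flow, 20)
    brs <- segment_inspirations(sig, min_duration = 0.2)
    if (length(brs) > 1L) {
      starts <- vapply(brs, function(b) b$start_index, numeric(1))
      ends <- vapply(brs, function(b) b$end_index, numeric(1))
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1] >= ends[-length(ends)]))
    }
    for (b in brs) expect_true(all(b$samples > 0))
  }
})

test_that("normalization maps any admissible breath onto the unit square", {
  nb <- normalize_breath(half_sine(40))
  expect_length(nb$values, 100L)
  expect_equal(min(nb$values), 0)
  expect_equal(max(nb$values), 1)
  expect_lt(abs(which.max(nb$values) - 50.5), 2.5)  # peak stays central

  # already-normalized input is a fixed point
  v <- normalize_breath(half_sine(100))$values
  expect_equal(normalize_breath(v)$values, v, tolerance = 1e-12)
})

test_that("a linear ramp normalizes to the grid itself", {
  nb <- normalize_breath(seq(3, 10, length.out = 25))
  expect_equal(nb$values, grid100, tolerance = 1e-12)
})

test_that("normalization rejects degenerate breaths", {
  expect_error(normalize_breath(rep(2, 30)), "constant")
  expect_error(normalize_breath(c(1, 2, 3)), "4 samples")
})

test_that("normalization is invariant to amplitude gain and time dilation", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:300, 1)
    v <- cumsum(rnorm(n)) + half_sine(n, amp = 3)
    if (max(v) == min(v)) next
    base <- normalize_breath(v)$values
    expect_equal(normalize_breath(4.2 * v - 7)$values, base, tolerance = 1e-9)
    # integer upsampling reproduces the same piecewise-linear function
    v2 <- stats::approx(seq_len(n), v, n = 2 * (n - 1) + 1)$y
    expect_equal(normalize_breath(v2)$values, base, tolerance = 1e-9)
  }
})

test_that("breath_table reports spans in seconds", {
  brs <- segment_inspirations(
    flow_signal(rep(c(rep(1, 10), rep(-1, 10)), 2), 20))
  tab <- breath_table(brs, 20)
  expect_equal(tab$start_time_s, c(0, 1))
  expect_equal(tab$end_time_s, c(0.5, 1.5))
  expect_equal(tab$n_samples, c(10L, 10L))
})
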