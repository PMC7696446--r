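test_that("framing spec derives horizon and history and validates inputs", {
  fs <- framing_spec()
  expect_identical(fs$lookback, 7L)
  expect_identical(fs$delay, 6L)
  expect_identical(fs$step, 1L)
  expect_equal(fs$horizon_minutes, 30)
  expect_equal(fs$history_minutes, 35)
  expect_error(framing_spec(lookback = 0), "lookback")
  expect_error(framing_spec(delay = 0), "lookback")
})

test_that("gap-free sample counts follow N - lookback - delay + 1", {
  fs <- framing_spec()
  week <- constant_trace(2016)
  expect_identical(n_samples(suppressWarnings(frame_samples(week, fs))), 2004L)

  boundary <- glucose_trace("B", 100 + 1:13)
  s1 <- frame_samples(boundary, fs)
  expect_identical(n_samples(s1), 1L)
  expect_equal(s1$targets, 113)               # the last point
  expect_equal(s1$inputs[1, ], as.numeric(101:107))
  expect_identical(s1$target_index, 12L)

  too_short <- glucose_trace("B", 100 + 1:12)
  expect_warning(s0 <- frame_samples(too_short, fs), "too short")
  expect_identical(n_samples(s0), 0L)
})

test_that("framing matches brute-force enumeration on random gap patterns", {
  set.seed(31)
  fs_list <- list(framing_spec(), framing_spec(lookback = 4, delay = 2),
                  framing_spec(lookback = 7, delay = 6, step = 3))
  for (rep in 1:200) {
    n <- sample(30:500, 1)
    tr <- random_gappy_trace(n, gap_fraction = runif(1, 0, 0.3))
    fs <- fs_list[[sample.int(3, 1)]]
    got <- suppressWarnings(frame_samples(tr, fs))
    expect_identical(n_samples(got),
                     oracle_frame_count(tr$index, fs$lookback, fs$delay, fs$step))
  }
})

test_that("no sample references a missing slot and targets increase", {
  set.seed(32)
  fs <- framing_spec()
  for (rep in 1:25) {
    tr <- random_gappy_trace(300, gap_fraction = 0.2)
    ss <- suppressWarnings(frame_samples(tr, fs))
    if (!n_samples(ss)) next
    expect_true(all(diff(ss$target_index) > 0))
    lookup <- stats::setNames(tr$glucose, tr$index)
    for (i in seq_len(n_samples(ss))) {
      start <- ss$target_index[i] - (fs$lookback - 1L + fs$delay)
      window_idx <- start + 0:(fs$lookback - 1L)
      expect_true(all(as.character(window_idx) %in% names(lookup)))
      expect_identical(unname(lookup[as.character(window_idx)]), ss$inputs[i, ])
      expect_identical(unname(lookup[as.character(ss$target_index[i])]),
                       ss$targets[i])
    }
  }
})

test_that("increasing delay by one drops exactly one sample on gap-free traces", {
  tr <- constant_trace(120)
  for (d in 1:10) {
    a <- n_samples(suppressWarnings(frame_samples(tr, framing_spec(delay = d))))
    b <- n_samples(suppressWarnings(frame_samples(tr, framing_spec(delay = d + 1L))))
    expect_identical(a - b, 1L)
  }
})

test_that("chronological split cuts the raw series before framing", {
  fs <- framing_spec()
  tr <- glucose_trace("S", 100 + seq_len(100))
  sp <- chronological_split(tr, 0.7, fs)
  expect_identical(n_samples(sp$train), 58L)   # 70 - 7 - 6 + 1
  expect_identical(n_samples(sp$test), 18L)    # 30 - 7 - 6 + 1
  expect_identical(sp$cut_index, 70L)
  expect_true(max(sp$train$target_index) < min(sp$test$target_index))
  # no test window reaches back across the cut
  starts <- sp$test$target_index - (fs$lookback - 1L + fs$delay)
  expect_true(all(starts >= sp$cut_index))

  even <- chronological_split(glucose_trace("S", 100 + 1:100), 0.5, fs)
  expect_identical(n_samples(even$train), n_samples(even$test))
})

test_that("split ordering holds on gappy traces and errors name the segment", {
  set.seed(33)
  fs <- framing_spec()
  for (rep in 1:20) {
    tr <- random_gappy_trace(400, gap_fraction = 0.2)
    sp <- tryCatch(chronological_split(tr, runif(1, 0.3, 0.7), fs),
                   error = function(e) NULL)
    if (is.null(sp)) next
    expect_true(all(sp$train$target_index < min(sp$test$target_index)))
  }
  short <- glucose_trace("SHORT", 100 + 1:20)
  expect_error(chronological_split(short, 0.5, fs), "training segment|test segment")
  expect_error(chronological_split(short, 1.0, fs), "train_fraction")
})

test_that("scaling a sample set transforms inputs and targets consistently", {
  tr <- glucose_trace("S", 100 + seq_len(60))
  ss <- suppressWarnings(frame_samples(tr, framing_spec()))
  sc <- fit_scaler(tr$glucose, "zscore")
  scaled <- scale_samples(ss, sc)
  expect_equal(invert_scaler(sc, scaled$targets), ss$targets, tolerance = 1e-12)
  expect_equal(invert_scaler(sc, scaled$inputs[3, ]), ss$inputs[3, ],
               tolerance = 1e-12)
  expect_true(scaled$scaled)
})
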