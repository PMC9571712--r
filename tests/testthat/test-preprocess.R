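test_that("bandpass rejects DC and passes in-band sines", {
  rate <- 200
  t <- seq(0, 10, by = 1 / rate)
  dc <- rep(1, length(t))
  out <- butter_filter(dc, "bandpass", c(1, 45), 3, rate = rate)
  expect_lt(max(abs(out[1000:1001])), 0.01)
  sine <- sin(2 * pi * 10 * t)
  outs <- butter_filter(sine, "bandpass", c(1, 45), 3, rate = rate)
  mid <- outs[500:1500]
  expect_lt(abs(max(mid) - 1), 0.05)
})

test_that("single-pass Butterworth magnitude at the cutoff is 1/sqrt(2)", {
  rate <- 200
  fc <- 20
  bf <- signal::butter(3, fc / (rate / 2), type = "low")
  z <- exp(-1i * 2 * pi * fc / rate)
  H <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
    sum(bf$a * z^(0:(length(bf$a) - 1)))
  expect_lt(abs(Mod(H) - 1 / sqrt(2)), 0.01)
})

test_that("filtering is zero-phase and near-idempotent in band", {
  rate <- 100
  set.seed(1)
  x <- rnorm(2000)
  f1 <- butter_filter(x, "bandpass", c(5, 20), 3, rate = rate)
  f2 <- rev(butter_filter(rev(x), "bandpass", c(5, 20), 3, rate = rate))
  expect_lt(max(abs(f1 - f2)), 1e-8)
  # in-band sine: double application changes amplitude < 10%
  t <- seq(0, 20, by = 1 / rate)
  s <- sin(2 * pi * 10 * t)
  a1 <- butter_filter(s, "bandpass", c(5, 20), 3, rate = rate)
  a2 <- butter_filter(a1, "bandpass", c(5, 20), 3, rate = rate)
  mid <- 500:1500
  expect_lt(abs(max(a2[mid]) / max(a1[mid]) - 1), 0.1)
})

test_that("filter edge validation", {
  expect_error(butter_filter(rnorm(100), "bandpass", c(1, 60), 3, rate = 100),
               "Nyquist")
  expect_error(butter_filter(rnorm(100), "lowpass", 50, 3, rate = 100),
               "Nyquist")
  expect_error(butter_filter(rnorm(100), "lowpass", 10, 0, rate = 100),
               "order")
})

test_that("resampling preserves duration and waveform", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 5 * t)
  y <- resample_recording(x, 200, rate = rate)
  expect_equal(length(y), round(10 * 200))
  t2 <- seq(0, 10 - 1 / 200, by = 1 / 200)
  ref <- sin(2 * pi * 5 * t2)
  expect_gt(cor(y, ref), 0.999)
  # identity path
  r <- recording(matrix(rnorm(200), 1), 200, "eeg", "Cz")
  expect_identical(resample_recording(r, 200), r)
  expect_error(resample_recording(x, -1, rate = rate), "positive")
})

test_that("mBLL inverts the forward optical-density model", {
  set.seed(2)
  hbo_true <- matrix(rnorm(300), 3, 100)
  hbr_true <- matrix(rnorm(300), 3, 100)
  ext <- matrix(c(0.1486, 0.3843, 0.2526, 0.1798), 2, byrow = TRUE)
  d <- 3; dpf <- c(6, 6)
  od1 <- (ext[1, 1] * hbo_true + ext[1, 2] * hbr_true) * d * dpf[1]
  od2 <- (ext[2, 1] * hbo_true + ext[2, 2] * hbr_true) * d * dpf[2]
  out <- mbll(od1, od2, extinction = ext, distance = d, dpf = dpf)
  expect_lt(max(abs(out$hbo - hbo_true)) / max(abs(hbo_true)), 1e-10)
  expect_lt(max(abs(out$hbr - hbr_true)) / max(abs(hbr_true)), 1e-10)
  # adjugate closed form, element-wise
  A <- ext * d * dpf
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  hbo_adj <- (A[2, 2] * od1 - A[1, 2] * od2) / det_a
  expect_equal(out$hbo, hbo_adj, tolerance = 1e-12)
  # zero optical density maps to zero concentrations
  z <- mbll(matrix(0, 2, 5), matrix(0, 2, 5))
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  expect_error(mbll(od1, od2, extinction = matrix(1, 2, 2)), "singular")
})

test_that("median baseline correction is robust and idempotent at zero", {
  rec <- recording(rbind(c(rep(1, 50), rep(5, 50)),
                         c(1, 1, 100, rep(0, 97))),
                   rate = 10, "hbo", c("a", "b"))
  seg <- segment(rec$data[, 51:60], 10, 0, 1, "0-back", 1, 1, 1,
                 channels = c("a", "b"))
  # channel a: baseline median 1 over [-5,0)s; channel b: median of
  # [1,1,100,0...] window is 0
  out <- baseline_correct(seg, rec, task_onset = 5,
                          baseline_interval = c(-5, 0))
  expect_equal(out$data[1, ], rep(4, 10))
  # explicit outlier-robustness: median of c(1, 1, 100) is 1
  rec2 <- recording(matrix(c(1, 1, 100, 7, 7), 1), 1, "hbo", "a")
  seg2 <- segment(rec2$data[, 4:5, drop = FALSE], 1, 0, 2, "0-back",
                  1, 1, 1, "a")
  out2 <- baseline_correct(seg2, rec2, 3, c(-3, 0))
  expect_equal(out2$data[1, ], c(6, 6))
  # already-centred baseline leaves the segment unchanged
  rec3 <- recording(matrix(c(-1, 0, 1, 5, 5), 1), 1, "hbo", "a")
  seg3 <- segment(rec3$data[, 4:5, drop = FALSE], 1, 0, 2, "0-back",
                  1, 1, 1, "a")
  expect_equal(baseline_correct(seg3, rec3, 3, c(-3, 0))$data[1, ], c(5, 5))
  expect_error(baseline_correct(seg2, rec2, 3, c(0, 0)), "empty")
})

test_that("sliding segmentation yields the expected window grid", {
  rec <- recording(matrix(seq_len(2 * 500), 2, byrow = TRUE), 10, "hbo",
                   c("a", "b"))
  ev <- data.frame(participant = 1, session = 1, series = 1,
                   label = "0-back", onset = 2, duration = 40)
  segs <- sliding_segments(rec, ev, win_len = 5, step = 1,
                           offset_range = c(0, 35))
  expect_length(segs, 36)
  # data conservation: segments are exact slices
  s7 <- segs[[7]]  # start offset 6 s
  i0 <- round((2 + 6) * 10) + 1
  expect_identical(s7$data, rec$data[, i0:(i0 + 49)])
  # single full-task window
  segs40 <- sliding_segments(rec, ev, win_len = 40, step = 1,
                             offset_range = c(0, 0))
  expect_length(segs40, 1)
  # windows that run past the recording end are skipped with a warning
  ev2 <- rbind(ev, data.frame(participant = 1, session = 1, series = 1,
                              label = "2-back", onset = 48, duration = 40))
  expect_warning(
    out <- sliding_segments(rec, ev2, win_len = 5, step = 1,
                            offset_range = c(0, 0)),
    "skipped")
  expect_length(out, 1)
})

test_that("artifact-removal hook passes recordings through", {
  r <- recording(matrix(rnorm(100), 2), 10, "eeg", c("a", "b"))
  expect_identical(remove_artifacts(r), r)
  flip <- function(rec) { rec$data <- -rec$data; rec }
  expect_equal(remove_artifacts(r, flip)$data, -r$data)
  expect_error(remove_artifacts(r, "wasobi"), "unknown")
})
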