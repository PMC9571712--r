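test_that("default cohort layout yields 702 balanced task rows", {
  cf <- sim_config()
  ev <- simulate_events(cf)
  expect_equal(nrow(ev), 702)
  expect_true(all(table(ev$label) == 234))
  # within each session: exactly n_sets tasks per label, onsets increasing
  by_sess <- split(ev, paste(ev$participant, ev$session))
  for (s in by_sess) {
    expect_true(all(table(s$label) == cf$n_sets_per_session))
    expect_true(all(diff(s$onset) > 0))
  }
})

test_that("session recordings cover the full block timeline", {
  cf <- tiny_config()
  s <- simulate_session(cf, 1, 1)
  n_tasks <- 3 * cf$n_sets_per_session
  expect_equal(rec_duration(s$eeg), n_tasks * 63)
  expect_equal(rec_duration(s$hbo), n_tasks * 63)
  expect_equal(nrow(s$eeg$data), 30)
  expect_equal(nrow(s$hbo$data), 36)
  expect_equal(s$eeg$rate, 200)
  expect_equal(s$hbo$rate, 10)
})

test_that("identical seeds reproduce recordings bit for bit", {
  cf <- tiny_config(seed = 42)
  a <- simulate_session(cf, 2, 1)
  b <- simulate_session(cf, 2, 1)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$hbr$data, b$hbr$data)
  expect_identical(a$events, b$events)
  # and the stand-alone event generator agrees with the session's events
  ev <- simulate_events(cf)
  expect_equal(ev[ev$participant == 2 & ev$session == 1, ], a$events,
               ignore_attr = TRUE)
  # a different seed diverges
  d <- simulate_session(tiny_config(seed = 43), 2, 1)
  expect_false(identical(a$eeg$data, d$eeg$data))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(eeg_rate = 0), "rates")
  expect_error(sim_config(block_layout = c(2, -40, 1, 20)), "positive")
  expect_error(sim_config(alpha_suppression = -0.1), ">= 0")
  expect_error(sim_config(hrf_peak_delay = 0), "positive")
  expect_error(sim_config(n_participants = 0), "positive integers")
})

test_that("hemodynamic response peaks at the configured delay", {
  expect_equal(hrf(0, 6), 0)
  tg <- seq(0, 30, by = 0.1)
  expect_lt(abs(tg[which.max(hrf(tg, 6))] - 6), 0.25 + 1e-9)
  expect_lt(abs(tg[which.max(hrf(tg, 5))] - 5), 0.25 + 1e-9)
  # trapezoid quadrature of the response is positive
  h <- hrf(tg, 6)
  expect_gt(sum((h[-1] + h[-length(h)]) / 2) * 0.1, 0)
  expect_error(hrf(1, 0), "positive")
  expect_error(hrf(-1, 6), "t >= 0")
})

test_that("posterior alpha power decreases monotonically with load", {
  alpha <- band_spec("alpha", 8, 15)
  pw <- matrix(0, 20, 3)
  cf <- sim_config(n_participants = 20, n_sessions = 1,
                   n_sets_per_session = 1, seed = 7)
  for (p in 1:20) {
    ss <- simulate_session(cf, p, 1)
    ev <- ss$events
    for (li in 1:3) {
      lb <- c("0-back", "2-back", "3-back")[li]
      ti <- which(ev$label == lb)
      i0 <- round(ev$onset[ti] * 200) + 1
      pw[p, li] <- mean(band_power(
        ss$eeg$data[cf$truth$posterior_channels, i0:(i0 + 8000 - 1)],
        alpha, rate = 200))
    }
  }
  m <- colMeans(pw)
  expect_true(all(diff(m) < 0))
})

test_that("effect-free cohorts cannot be classified above chance", {
  # leakage-free protocol: fold-nested selection and normalisation with
  # subject-wise folds (block-balanced labels make sample-wise CV
  # exploitable through within-participant label composition)
  accs <- vapply(1:10, function(s) {
    cfn <- sim_config(n_participants = 4, n_sessions = 1,
                      alpha_suppression = 0, frontal_coupling_gain = 0,
                      hbr_effect = 0, seed = 600 + s)
    dsn <- simulate_dataset(cfn, 1:4, 1)
    fmn <- workload_features(dsn, estimators = character(0))
    hybrid_pipeline(fmn, c("0-back", "3-back"), eeg_pool = "psd_only",
                    nested_selection = TRUE, folds = "participant",
                    seed = s)$accuracy
  }, 0)
  expect_lte(mean(accs), 55)
})
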