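alpha <- band_spec("alpha", 8, 15)
delta <- band_spec("delta", 0.5, 4)

test_that("band power concentrates at the tone frequency and obeys Parseval", {
  rate <- 200
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  x <- matrix(sin(2 * pi * 10 * t), 1)
  expect_gt(band_power(x, alpha, rate = rate) /
              band_power(x, delta, rate = rate), 100)
  expect_equal(unname(band_power(matrix(0, 1, 2000), alpha, rate = rate)), 0)
  # white-noise total power ~ variance
  set.seed(3)
  w <- matrix(rnorm(4000), 1)
  tot <- band_power(w, band_spec("all", 0.5, rate / 2 - 1e-9), rate = rate)
  expect_lt(abs(tot / var(as.vector(w)) - 1), 0.1)
  expect_error(band_power(matrix(rnorm(100), 1), delta, rate = rate),
               "too short")
})

test_that("pcc matches the direct correlation definition", {
  x <- c(1, 2, 3)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, c(1, 3, 2)), 0.5)
  expect_error(pcc(x, c(1, 1, 1)), "constant")
  expect_error(pcc(x, c(1, 2)), "equal length")
})

test_that("coherence hits its limiting cases", {
  rate <- 100
  band <- band_spec("mid", 5, 20)
  x <- bl_noise(4000, rate, 2, 40, seed = 4)
  expect_equal(msc(x, x, rate, band, n_segments = 8), 1, tolerance = 1e-9)
  set.seed(5)
  y <- rnorm(4000)
  x2 <- rnorm(4000)
  expect_lt(msc(x2, y, rate, band, n_segments = 8), 0.3)
  # pure delay leaves coherence magnitude unchanged
  xd <- c(tail(x, -3), head(x, 3))
  expect_gt(msc(x, xd, rate, band, n_segments = 8), 0.95)
  expect_error(msc(x, y, rate, band, n_segments = 1), "2 averaging")
})

test_that("mutual information equals entropy identities and the brute-force oracle", {
  # uniform 4-symbol self-information: MI(x, x) = H(x) = 2 bits
  x <- rep(c(0.1, 0.4, 0.6, 0.9), each = 25)
  expect_equal(mutual_information(x, x, n_bins = 4), 2)
  # exactly independent joint histogram (outer-product counts)
  xi <- rep(c(0, 1), each = 50)
  yi <- rep(rep(c(0, 1), each = 25), 2)
  expect_lt(abs(mutual_information(xi, yi, n_bins = 2)), 1e-12)
  # H(x)+H(y)-H(x,y) equals H(y)-H(y|x), both from the joint table
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(200); y <- x + rnorm(200)
    nb <- 8
    ix <- fbcfuse:::discretize_series(x, nb)
    iy <- fbcfuse:::discretize_series(y, nb)
    joint <- fbcfuse:::joint_counts(ix, iy, nb)
    hx <- fbcfuse:::entropy_from_counts(rowSums(joint))
    hy <- fbcfuse:::entropy_from_counts(colSums(joint))
    hxy <- fbcfuse:::entropy_from_counts(joint)
    # conditional entropy H(y|x) accumulated row by row
    hygx <- 0
    for (a in seq_len(nb)) {
      na <- sum(joint[a, ])
      if (na == 0) next
      hygx <- hygx + na / 200 * fbcfuse:::entropy_from_counts(joint[a, ])
    }
    expect_lt(abs((hx + hy - hxy) - (hy - hygx)), 1e-10)
    expect_lt(abs(mutual_information(x, y, nb) - mi_bruteforce(x, y, nb)),
              1e-10)
  }
  expect_error(mutual_information(numeric(0), numeric(0)), "non-empty")
  expect_error(mutual_information(rnorm(5), rnorm(5), n_bins = 1), ">= 2")
})

test_that("adding independent noise does not increase median MI", {
  set.seed(7)
  mi_clean <- mi_noisy <- numeric(50)
  for (i in 1:50) {
    x <- rnorm(300)
    y <- x + rnorm(300, 0, 0.5)
    mi_clean[i] <- mutual_information(x, y, 12)
    mi_noisy[i] <- mutual_information(x, y + rnorm(300, 0, 2), 12)
  }
  expect_lt(median(mi_noisy), median(mi_clean))
})

test_that("phase locking hits its limiting cases", {
  rate <- 200
  x <- bl_noise(4000, rate, 8, 15, seed = 8)
  expect_equal(plv(x, x, rate, alpha, filtered = TRUE), 1)
  # constant in-band phase shift keeps PLV at 1
  z <- fbcfuse:::analytic_signal(x)
  y <- Re(z * exp(-1i * pi / 4))
  expect_equal(plv(x, y, rate, alpha, filtered = TRUE), 1, tolerance = 0.02)
  # independent narrowband noise decorrelates
  y2 <- bl_noise(4000, rate, 8, 15, seed = 9)
  expect_lt(plv(x, y2, rate, alpha, filtered = TRUE), 0.2)
  expect_error(plv(x[1:50], x[1:50], rate, alpha), "3 cycles")
})

test_that("estimators are symmetric and respect their ranges", {
  rate <- 100
  band <- band_spec("mid", 5, 20)
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(600); y <- 0.4 * x + rnorm(600)
    expect_equal(pcc(x, y), pcc(y, x), tolerance = 1e-12)
    expect_true(abs(pcc(x, y)) <= 1)
    m1 <- msc(x, y, rate, band, 6); m2 <- msc(y, x, rate, band, 6)
    expect_lt(abs(m1 - m2), 1e-10)
    expect_true(m1 >= 0 && m1 <= 1)
    mi1 <- mutual_information(x, y, 10); mi2 <- mutual_information(y, x, 10)
    expect_lt(abs(mi1 - mi2), 1e-10)
    expect_gte(mi1, 0)
    p1 <- plv(x, y, rate, band); p2 <- plv(y, x, rate, band)
    expect_lt(abs(p1 - p2), 1e-10)
    expect_true(p1 >= 0 && p1 <= 1)
  }
})

test_that("connectivity matrices are symmetric with the right diagonals", {
  set.seed(11)
  rate <- 100
  data <- matrix(rnorm(6 * 1200), 6)
  rownames(data) <- paste0("ch", 1:6)
  data[2, ] <- data[1, ]  # duplicated channel pair
  seg <- segment(data, rate, 0, 12, "0-back", 1, 1, 1)
  band <- band_spec("mid", 5, 20)
  for (est in c("pcc", "msc", "plv")) {
    cm <- connectivity_matrix(seg, est, band)
    expect_identical(cm$values, t(cm$values))
    expect_equal(unname(diag(cm$values)), rep(1, 6), tolerance = 1e-9)
    expect_equal(unname(cm$values[1, 2]), 1, tolerance = 1e-6)
  }
  cm <- connectivity_matrix(seg, "mi", band)
  expect_identical(cm$values, t(cm$values))
  # MI diagonal is the per-channel binned entropy H(x)
  filt <- butter_filter(data, "bandpass", c(5, 20), 3, rate = rate)
  nb <- min(32, ceiling(sqrt(ncol(data))))
  ix <- fbcfuse:::discretize_series(filt[3, ], nb)
  expect_equal(cm$values[3, 3],
               fbcfuse:::entropy_from_counts(tabulate(ix, nb)))
  expect_error(connectivity_matrix(
    segment(data[1, , drop = FALSE], rate, 0, 12, "0-back", 1, 1, 1),
    "pcc", band), "2 channels")
})

test_that("fnirs window feature is the per-channel mean", {
  expect_equal(unname(fnirs_window_feature(matrix(c(0, 1, 2, 3), 1))), 1.5)
  expect_equal(unname(fnirs_window_feature(matrix(7, 2, 5))), c(7, 7))
  expect_error(fnirs_window_feature(matrix(numeric(0), 1, 0)), "empty")
  # window at the response peak beats a pre-onset window
  frate <- 10
  tgrid <- seq(0, 30, by = 1 / frate)
  kern <- hrf(tgrid, 6); kern <- kern / sum(kern)
  box <- c(rep(0, 100), rep(1, 400), rep(0, 100))
  resp <- stats::convolve(box, rev(kern), type = "open")[seq_along(box)]
  peak_win <- matrix(resp[160:210], 1)   # ~6-11 s after onset
  pre_win <- matrix(resp[40:90], 1)
  expect_gt(fnirs_window_feature(peak_win), fnirs_window_feature(pre_win))
})

test_that("assembled columns follow the deterministic descriptor order", {
  vals <- matrix(rnorm(12), 3, 4)
  blocks <- list(
    list(values = vals[, 1:2],
         descriptors = feature_descriptors("fnirs-hbr", channel = c("z", "a"),
                                           window = "w3+5")),
    list(values = vals[, 3:4],
         descriptors = feature_descriptors("eeg-psd", band = "alpha",
                                           channel = c("POz", "Cz"),
                                           window = "w0+40")))
  fm <- assemble_features(blocks, c("0-back", "2-back", "3-back"))
  expect_equal(fm$descriptors$modality, c("eeg-psd", "eeg-psd",
                                          "fnirs-hbr", "fnirs-hbr"))
  expect_equal(fm$descriptors$channel, c("Cz", "POz", "a", "z"))
  # values moved with their descriptors
  expect_equal(fm$values[, 3], vals[, 2])
  expect_error(assemble_features(blocks, c("0-back", "2-back")), "label")
  bad <- blocks
  bad[[2]]$values <- bad[[2]]$values[1:2, ]
  expect_error(assemble_features(bad, c("0-back", "2-back", "3-back")),
               "ragged")
})

test_that("feature pools carry the canonical per-block column structure", {
  cf <- tiny_config(seed = 3)
  s <- simulate_session(cf, 1, 1)
  ext <- extract_session_features(s, estimators = c("pcc", "mi"),
                                  fnirs_win_starts = c(4, 8))
  fm <- assemble_features(ext$blocks, ext$labels, ext$meta)
  cnt <- table(fm$descriptors$modality)
  expect_equal(unname(cnt["eeg-psd"]), 3 * 28)
  expect_equal(unname(cnt["eeg-fbc"]), 3 * 28 * 27 / 2 * 2)
  expect_equal(unname(cnt["fnirs-hbr"]), 2 * 36)
  expect_equal(nrow(fm$values), nrow(s$events))
  # pair descriptors are montage-ordered
  fbcd <- fm$descriptors[fm$descriptors$modality == "eeg-fbc", ]
  mont <- setdiff(cf$eeg_montage$label, c("T7", "T8"))
  expect_true(all(match(fbcd$channel, mont) < match(fbcd$channel_b, mont)))
})
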