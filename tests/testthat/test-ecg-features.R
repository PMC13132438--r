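test_that("Pan-Tompkins detection on clean synthetic signals", {
  tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 60, duration = 10))
  sig <- list(samples = tr$signal, fs = tr$fs)
  pk <- detect_r_peaks(sig)
  expect_true(abs(length(pk) - 10) <= 1)
  err <- vapply(pk, function(t) min(abs(tr$r_peaks - t)), 0)
  expect_lte(max(err), 10)

  tr2 <- gen_ecg_signal(ecg_sim_params(mean_hr = 120, duration = 10,
                                       seed = 2))
  pk2 <- detect_r_peaks(list(samples = tr2$signal, fs = tr2$fs))
  hr <- 60000 / mean(diff(pk2))
  expect_lt(abs(hr - 120), 2)

  expect_warning(out <- detect_r_peaks(list(samples = rep(0, 5000),
                                            fs = 500)))
  expect_length(out, 0)
})

test_that("filter_rr applies the physiological-range rule", {
  # worked example: only the middle beat has both RRs in range
  res <- filter_rr(c(0, 250, 1050, 1850, 3950))
  expect_equal(nrow(res), 1)
  expect_equal(res$rr_prev, 800)
  expect_equal(res$rr_next, 800)
  # uniform train keeps the 8 interior beats
  res2 <- filter_rr(seq(0, 9000, by = 1000))
  expect_equal(nrow(res2), 8)
  # nothing physiological
  res3 <- filter_rr(seq(0, 2000, by = 250))
  expect_equal(nrow(res3), 0)
  expect_error(filter_rr(c(0, 800)), class = "pb_input_error")
})

test_that("filter_rr equals brute-force rule application (property)", {
  set.seed(42)
  for (rep in 1:25) {
    peaks <- sort(sample(0:20000, sample(5:30, 1)))
    got <- filter_rr(peaks)
    rr <- diff(peaks)
    expected <- integer(0)
    for (i in 2:(length(peaks) - 1)) {
      if (rr[i - 1] >= 300 && rr[i - 1] <= 2000 &&
          rr[i] >= 300 && rr[i] <= 2000) expected <- c(expected, i)
    }
    expect_equal(got$peak_time, peaks[expected])
  }
})

test_that("segment_beats aligns windows to the R sample", {
  x <- rep(0, 1000); x[501] <- 1        # impulse at sample 501 = 1000 ms
  sig <- list(samples = x, fs = 500)
  beats <- data.frame(peak_time = 1000, rr_prev = 800, rr_next = 800)
  bs <- segment_beats(sig, beats)
  expect_equal(ncol(bs$segments), 271)   # round(0.540*500)+1
  expect_equal(unname(bs$segments[1, 101]), 1)  # R at index 101 (samples 401..671)
  expect_equal(bs$t_rel[101], 0)
  # window underrun drops the beat
  bs2 <- segment_beats(sig, data.frame(peak_time = 100, rr_prev = 800,
                                       rr_next = 800))
  expect_equal(nrow(bs2$segments), 0)
  # baseline subtraction zeroes planted offsets
  sig3 <- list(samples = rep(0.1, 1000), fs = 500)
  bs3 <- segment_beats(sig3, beats, baseline = 0.1)
  expect_true(all(abs(bs3$segments) < 1e-12))
})

test_that("beat_features recovers planted morphology", {
  tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 60, t_amp = 0.3,
                                      st_offset = -0.05, duration = 10))
  sig <- list(samples = tr$signal, fs = 500)
  beats <- filter_rr(tr$r_peaks)
  bs <- segment_beats(sig, beats)
  bf <- beat_features(bs)
  expect_equal(names(bf), feature_registry())
  expect_length(names(bf), 17)
  expect_true(all(abs(bf$t_amp - 0.3) < 0.02))
  expect_true(all(abs(bf$st_level - (-0.05)) < 0.005))
  expect_true(all(abs(bf$r_amp - 1.0) < 0.1))
  # zero segments give zero amplitudes and NA durations
  bs0 <- bs; bs0$segments[] <- 0
  bf0 <- beat_features(bs0)
  expect_true(all(bf0$t_amp == 0 & bf0$r_amp == 0 & bf0$p_amp == 0))
  expect_true(all(is.na(bf0$qrs_dur)))
})

test_that("beat_features recovers amplitudes across random settings", {
  set.seed(7)
  for (rep in 1:30) {
    ta <- runif(1, 0.1, 0.5); pa <- runif(1, 0.05, 0.3)
    ra <- runif(1, 0.5, 1.5); st <- runif(1, -0.1, 0.1)
    tr <- gen_ecg_signal(ecg_sim_params(
      mean_hr = runif(1, 50, 90), t_amp = ta, p_amp = pa, r_amp = ra,
      st_offset = st, duration = 6, seed = rep))
    beats <- filter_rr(tr$r_peaks)
    bs <- segment_beats(list(samples = tr$signal, fs = 500), beats)
    bf <- beat_features(bs)
    expect_lt(abs(median(bf$t_amp) - ta), 0.1 * ta + 0.005)
    expect_lt(abs(median(bf$p_amp) - pa), 0.1 * pa + 0.005)
    expect_lt(abs(median(bf$r_amp) - ra), 0.1 * ra)
    expect_lt(abs(median(bf$st_level) - st), 0.1 * abs(st) + 0.005)
  }
})

test_that("beat templates: means, SDs and group differences", {
  seg <- matrix(rnorm(50 * 271), 50, 271)
  # identical groups cancel
  tpl <- beat_template(list(a = seg, b = seg))
  expect_true(all(tpl$abs_diff == 0))
  # planted difference shows at the planted sample
  seg2 <- seg; seg2[, 150] <- seg2[, 150] + 0.1
  tpl2 <- beat_template(list(a = seg2, b = seg))
  expect_equal(unname(tpl2$abs_diff[150]), 0.1, tolerance = 1e-9)
  # single beat per group: template is the beat, SD = 0
  tpl3 <- beat_template(list(a = seg[1, , drop = FALSE],
                             b = seg[2, , drop = FALSE]))
  expect_equal(unname(tpl3$mean[1, ]), unname(seg[1, ]))
  expect_true(all(tpl3$sd == 0))
  expect_error(beat_template(list(a = seg[0, , drop = FALSE], b = seg)),
               class = "pb_input_error")
})

test_that("hrv_metrics matches the stated formulas", {
  h <- hrv_metrics(c(800, 820, 800, 820))
  expect_equal(h$rmssd, 20, tolerance = 1e-12)
  expect_equal(h$sd1, 20 / sqrt(2), tolerance = 1e-12)
  expect_equal(h$mean_nn, 810)
  expect_equal(h$mean_hr, 60000 / 810, tolerance = 1e-12)
  expect_equal(h$sdnn, sd(c(800, 820, 800, 820)), tolerance = 1e-12)
  h0 <- hrv_metrics(rep(1000, 5))
  expect_equal(h0$rmssd, 0)
  expect_equal(h0$sd1, 0)
  expect_equal(h0$sdnn, 0)
  expect_equal(h0$mean_hr, 60)
  expect_error(hrv_metrics(c(800, 900)), class = "pb_insufficient_data")
})

test_that("hrv_metrics equals an independent reimplementation (property)", {
  set.seed(11)
  for (rep in 1:50) {
    nn <- runif(sample(4:40, 1), 400, 1500)
    h <- hrv_metrics(nn)
    # straight-line reimplementation of each formula
    n <- length(nn)
    mean_nn <- sum(nn) / n
    sdnn <- sqrt(sum((nn - mean_nn)^2) / (n - 1))
    sdnn_pop <- sqrt(sum((nn - mean_nn)^2) / n)
    rmssd <- sqrt(sum((nn[-1] - nn[-n])^2) / (n - 1))
    sd1 <- rmssd / sqrt(2)
    sd2 <- sqrt(max(0, 2 * sdnn_pop^2 - sd1^2))
    expect_equal(h$mean_nn, mean_nn, tolerance = 1e-9)
    expect_equal(h$sdnn, sdnn, tolerance = 1e-9)
    expect_equal(h$rmssd, rmssd, tolerance = 1e-9)
    expect_equal(h$sd1, sd1, tolerance = 1e-9)
    expect_equal(h$sd2, sd2, tolerance = 1e-9)
    expect_equal(h$mean_hr, 60000 / mean_nn, tolerance = 1e-9)
    # algebraic identity
    expect_equal(h$sd1 / h$rmssd, 1 / sqrt(2), tolerance = 1e-12)
  }
})

test_that("hrv window restricts to the leading seconds", {
  nn <- rep(1000, 20)
  h <- hrv_metrics(nn, window = 10)
  expect_equal(h$n_nn, 10)
})
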