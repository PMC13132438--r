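test_that("gen_ecg_signal: zero-variability case is exact", {
  tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 60, rmssd_target = 0,
                                      duration = 10))
  expect_true(all(abs(tr$rr - 1000) < 1e-9))
  expect_true(abs(length(tr$r_peaks) - 10) <= 1)
})

test_that("gen_ecg_signal: absent T wave leaves the T window flat", {
  tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 60, t_amp = 0,
                                      st_offset = 0, duration = 10))
  for (r in tr$r_peaks[-length(tr$r_peaks)]) {
    idx <- tr$t_ms >= r + 120 & tr$t_ms <= r + 340
    expect_lt(max(abs(tr$signal[idx])), 1e-6)
  }
})

test_that("alternating RR generator hits RMSSD exactly; AR(1) within 15%", {
  tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 60, rmssd_target = 20,
                                      rr_method = "alternating",
                                      duration = 30))
  expect_equal(sqrt(mean(diff(tr$rr)^2)), 20, tolerance = 3 / 20)
  # closed form: alternating +/-10 ms gives RMSSD exactly 20
  expect_equal(sqrt(mean(diff(tr$rr)^2)), 20, tolerance = 1e-9)
  for (s in 1:3) {
    tr <- gen_ecg_signal(ecg_sim_params(mean_hr = 70, rmssd_target = 25,
                                        rr_method = "ar1", duration = 300,
                                        seed = s))
    expect_equal(sqrt(mean(diff(tr$rr)^2)), 25, tolerance = 0.15)
  }
})

test_that("infeasible RMSSD targets are rejected", {
  expect_error(
    gen_ecg_signal(ecg_sim_params(mean_hr = 150, rmssd_target = 300,
                                  rr_method = "alternating")),
    class = "pb_infeasible_rr")
  expect_error(ecg_sim_params(mean_hr = 10), class = "pb_input_error")
  expect_error(ecg_sim_params(duration = 0), class = "pb_input_error")
})

test_that("generators are bit-deterministic under a fixed seed", {
  a <- gen_ecg_signal(ecg_sim_params(rmssd_target = 30, seed = 11))
  b <- gen_ecg_signal(ecg_sim_params(rmssd_target = 30, seed = 11))
  expect_identical(a$signal, b$signal)
  expect_identical(a$r_peaks, b$r_peaks)
  ca <- gen_notes_corpus(20, 0.4, fn_plant_rate = 0.2, seed = 5)
  cb <- gen_notes_corpus(20, 0.4, fn_plant_rate = 0.2, seed = 5)
  expect_identical(ca$notes, cb$notes)
  expect_identical(ca$gold, cb$gold)
  la <- gen_lung_activation(c(48, 48), 0.3, 0.1, seed = 7)
  lb <- gen_lung_activation(c(48, 48), 0.3, 0.1, seed = 7)
  expect_identical(la$activation, lb$activation)
  expect_identical(gen_cohort(cohort_sim_params(n = 50, seed = 3)),
                   gen_cohort(cohort_sim_params(n = 50, seed = 3)))
})

test_that("rendered pages carry the stated pixel geometry", {
  spec <- page_render_spec(px_per_mm = 5)
  # flat zero trace draws a horizontal line at the panel baseline row
  flat <- list(t_ms = seq(0, 9999, by = 2), signal = rep(0, 5000), fs = 500)
  pg <- render_ecg_page(flat, spec)
  panel <- pg$manifest$panels[[1]]
  region <- list(rows = panel$y0:panel$y1,
                 cols = panel$x0:(panel$x0 + 200))
  poly <- extract_trace(pg$image, region)
  expect_true(all(abs(poly - panel$baseline_row) <= 1))

  # a 1 mV calibration pulse spans amp_scale * px_per_mm = 50 px
  pulse <- list(t_ms = seq(0, 9999, by = 2),
                signal = rep(c(0, 1), each = 2500), fs = 500)
  pg2 <- render_ecg_page(pulse, spec)
  p2 <- pg2$manifest$panels[[1]]
  reg2 <- list(rows = p2$y0:p2$y1, cols = p2$x0:(p2$x0 + 1200))
  poly2 <- extract_trace(pg2$image, reg2)
  expect_equal(max(poly2) - min(poly2), 50, tolerance = 1 / 50)
  expect_error(page_render_spec(px_per_mm = 2), class = "pb_input_error")
})

test_that("gen_lung_activation plants exact fractions", {
  lug0 <- gen_lung_activation(c(64, 64), 0, 0, seed = 1)
  expect_identical(sum(lug0$activation[lug0$mask] > lug0$threshold), 0L)
  lug1 <- gen_lung_activation(c(64, 64), 1, 1, seed = 1)
  expect_true(all(lug1$activation[lug1$mask] > lug1$threshold))
  lug <- gen_lung_activation(c(80, 80), 0.2, 0.35, seed = 2)
  part <- split_lungs(lug$mask)
  # brute-force pixel counting against the planted truth, per lung
  n_hot_left <- sum(lug$activation > lug$threshold & part$left)
  n_hot_right <- sum(lug$activation > lug$threshold & part$right)
  expect_lte(abs(n_hot_left - 0.2 * sum(part$left)), 1)
  expect_lte(abs(n_hot_right - 0.35 * sum(part$right)), 1)
  expect_error(gen_lung_activation(c(64, 64), 1.2, 0), class = "pb_input_error")
})

test_that("gen_cohort hits the target event rate and planted effects", {
  big <- gen_cohort(cohort_sim_params(n = 10000, event_rate = 0.157,
                                      or_per_sd = c(f = 1.5), seed = 4))
  expect_lt(abs(mean(big$death) - 0.157), 0.015)
  # null model: fitted OR ~ 1
  null <- gen_cohort(cohort_sim_params(n = 2000, event_rate = 0.157,
                                       or_per_sd = c(f = 1.0), seed = 5))
  expect_lt(abs(logistic_or_per_sd(null$f, null$death)$or - 1), 0.1)
  # planted effect recovered
  eff <- gen_cohort(cohort_sim_params(n = 2000, event_rate = 0.157,
                                      or_per_sd = c(f = 2.0), seed = 6))
  expect_true(abs(logistic_or_per_sd(eff$f, eff$death)$or - 2) < 0.25)
  # cohort shape: n = 121 at 15.7% expects ~19 events
  expect_equal(round(121 * 0.157), 19)
})

test_that("gen_notes_corpus respects prevalence-zero and plants FNs", {
  c0 <- gen_notes_corpus(1, criterion_prevalence = 0, seed = 1)
  m <- match_criteria(c0$notes, c0$dictionary, "V2")
  expect_false(any(m$detected))
  expect_equal(c0$gold$gold_score -
                 ifelse(c0$gold$age >= 65, 1, 0), 0)
})
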