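# Shared fixtures, built in code at test time.

# clean synthetic trace + rendered page round trip, one call
make_page <- function(seed = 1, mean_hr = 60, rmssd = 0, px_per_mm = 5,
                      duration = 10, ...) {
  par <- ecg_sim_params(mean_hr = mean_hr, rmssd_target = rmssd,
                        duration = duration, seed = seed, ...)
  truth <- gen_ecg_signal(par)
  page <- render_ecg_page(truth, page_render_spec(px_per_mm = px_per_mm))
  list(truth = truth, image = page$image, manifest = page$manifest)
}

# ground truth resampled on the digitised grid and passed through the
# same band-pass, for pass-band fidelity comparison
reference_signal <- function(truth, t_ms, band = c(0.5, 40), order = 5) {
  y <- stats::approx(truth$t_ms, truth$signal, xout = t_ms, rule = 2)$y
  bandpass_filter(y, 500, band[1], band[2], order = order)
}

mixed_prevalence <- function() {
  c(invasive_ventilation = 0.3, septic_shock = 0.25, tachypnea = 0.5,
    pao2_fio2 = 0.4, multilobar_opacities = 0.35, confusion = 0.3,
    uremia = 0.2, leukopenia = 0.15, hypotension = 0.4)
}
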