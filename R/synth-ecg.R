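# Synthetic ECG signal generator: sum-of-Gaussians PQRST beats on a flat
# TP baseline, with a controllable RR-interval process. Ground truth
# (R-peak times, RR sequence) is exact by construction, which makes the
# generator usable as an oracle for digitisation and feature extraction.

#' Parameters for the synthetic ECG generator
#'
#' @param mean_hr mean heart rate, beats/min (must lie in (20, 300)).
#' @param rmssd_target target RMSSD of the RR series, ms.
#' @param p_amp,r_amp,s_amp,t_amp wave amplitudes, mV. `s_amp` is the
#'   magnitude of the (negative) S deflection.
#' @param st_offset ST-segment plateau offset, mV (negative = depression).
#' @param duration record length, s.
#' @param seed RNG seed for the RR jitter.
#' @param rr_method `"ar1"` (wrapped AR(1) jitter, clipped to 300--2000 ms)
#'   or `"alternating"` (deterministic +/- rmssd/2 alternation, for which
#'   the sample RMSSD is exactly `rmssd_target`).
#' @param noise_sd additive white noise SD, mV (default 0: clean traces).
#' @return an object of class `ecg_sim_params`.
#' @export
ecg_sim_params <- function(mean_hr = 60, rmssd_target = 0,
                           p_amp = 0.15, r_amp = 1.0, s_amp = 0.25,
                           t_amp = 0.3, st_offset = 0,
                           duration = 10, seed = 1L,
                           rr_method = c("ar1", "alternating"),
                           noise_sd = 0) {
  stopifnot_scalar(mean_hr, "mean_hr", 20, 300, strict = TRUE)
  stopifnot_scalar(duration, "duration", 0, Inf, strict = TRUE)
  stopifnot_scalar(rmssd_target, "rmssd_target", 0, Inf)
  for (nm in c("p_amp", "r_amp", "s_amp", "t_amp", "st_offset", "noise_sd")) {
    stopifnot_scalar(get(nm), nm)
  }
  structure(list(
    mean_hr = mean_hr, rmssd_target = rmssd_target,
    p_amp = p_amp, r_amp = r_amp, s_amp = s_amp, t_amp = t_amp,
    st_offset = st_offset, duration = duration, seed = seed,
    rr_method = match.arg(rr_method), noise_sd = noise_sd
  ), class = "ecg_sim_params")
}

# RR sequence with target short-term variability. Alternating method:
# rr_i = mean_rr + (-1)^i * d with d = rmssd/2, so successive differences
# are +/- 2d = +/- rmssd and the sample RMSSD equals the target exactly.
gen_rr_sequence <- function(params, n_beats) {
  mean_rr <- 60000 / params$mean_hr
  rt <- params$rmssd_target
  if (params$rr_method == "alternating") {
    d <- rt / 2
    if (mean_rr - d < 300 || mean_rr + d > 2000) {
      pb_stop("rmssd_target infeasible at this mean_hr: RR would leave 300-2000 ms",
              "pb_infeasible_rr")
    }
    mean_rr + d * (-1)^(seq_len(n_beats))
  } else {
    if (mean_rr < 300 || mean_rr > 2000) {
      pb_stop("mean RR outside the physiological 300-2000 ms range",
              "pb_infeasible_rr")
    }
    if (rt == 0) return(rep(mean_rr, n_beats))
    phi <- 0.5
    v <- rt^2 / (2 * (1 - phi))          # stationary variance giving E[dRR^2]=rt^2
    sigma <- sqrt(v * (1 - phi^2))
    e <- numeric(n_beats)
    e[1] <- stats::rnorm(1, 0, sqrt(v))
    if (n_beats > 1) {
      z <- stats::rnorm(n_beats - 1, 0, sigma)
      for (i in 2:n_beats) e[i] <- phi * e[i - 1] + z[i - 1]
    }
    pmin(2000, pmax(300, mean_rr + e))
  }
}

#' Generate a synthetic single-lead ECG trace with exact ground truth
#'
#' Builds a 500 Hz trace from Gaussian P/QRS/T components plus a smoothed
#' ST plateau on a flat TP baseline. Returned R-peak times are the planted
#' beat centres (exact ground truth, not re-detected).
#'
#' @param params an [ecg_sim_params()] object.
#' @param fs sampling rate, Hz.
#' @return list with `t_ms`, `signal` (mV), `r_peaks` (ms), `rr` (ms),
#'   `fs`, and the `params` used.
#' @export
gen_ecg_signal <- function(params, fs = 500) {
  stopifnot(inherits(params, "ecg_sim_params"))
  dur_ms <- params$duration * 1000
  n_beats <- ceiling(dur_ms / (60000 / params$mean_hr)) + 3L
  rr <- with_seed(params$seed, gen_rr_sequence(params, n_beats))
  first_r <- min(400, 60000 / params$mean_hr * 0.4)
  r_times <- first_r + c(0, cumsum(rr))
  keep <- r_times < dur_ms
  r_times <- r_times[keep]

  n <- round(params$duration * fs)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  sig <- numeric(n)
  gauss <- function(mu, sd, amp) {
    lo <- max(1L, floor((mu - 5 * sd) / 1000 * fs))
    hi <- min(n, ceiling((mu + 5 * sd) / 1000 * fs))
    if (lo > hi) return(invisible(NULL))
    idx <- lo:hi
    sig[idx] <<- sig[idx] + amp * exp(-((t_ms[idx] - mu)^2) / (2 * sd^2))
    invisible(NULL)
  }
  for (r in r_times) {
    gauss(r - 160, 25, params$p_amp)                  # P wave
    gauss(r - 30, 8, -0.15 * params$r_amp)            # Q
    gauss(r, 10, params$r_amp)                        # R
    gauss(r + 30, 8, -params$s_amp)                   # S
    gauss(r + 230, 40, params$t_amp)                  # T wave
    if (params$st_offset != 0) {
      # smooth plateau covering the ST measurement window (+60..+100 ms)
      idx <- which(t_ms > r + 20 & t_ms < r + 150)
      if (length(idx)) {
        edge <- stats::pnorm((t_ms[idx] - (r + 40)) / 5) *
          stats::pnorm(((r + 120) - t_ms[idx]) / 5)
        sig[idx] <- sig[idx] + params$st_offset * edge
      }
    }
  }
  if (params$noise_sd > 0) {
    sig <- sig + with_seed(params$seed + 1L,
                           stats::rnorm(n, 0, params$noise_sd))
  }
  rr_out <- diff(r_times)
  list(t_ms = t_ms, signal = sig, r_peaks = r_times, rr = rr_out,
       fs = fs, params = params)
}
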