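# Beat detection, RR artefact filtering, beat segmentation, morphological
# feature extraction and ultra-short HRV metrics.

#' The ordered beat-feature registry
#'
#' Seventeen morphological/interval features measured per beat, with
#' fixed measurement windows relative to the R-peak (ms). The windows
#' partition the -200..+340 ms beat segment: P wave -200..-60, QRS
#' -60..+60, ST +60..+100, T wave +120..+340.
#'
#' @return character vector of 17 feature names, in canonical order.
#' @export
feature_registry <- function() {
  c("rr_prev", "rr_next", "inst_hr",
    "p_amp", "p_dur", "pr_interval",
    "q_amp", "r_amp", "s_amp", "qrs_dur",
    "st_level", "st_slope",
    "t_amp", "t_dur", "qt_interval", "t_peak_time",
    "beat_rms")
}

#' Pan-Tompkins R-peak detection
#'
#' Classic stages: 5--15 Hz band-pass, derivative, squaring, 150 ms
#' moving-window integration, adaptive dual thresholds with search-back,
#' 200 ms refractory period. Detected locations are refined to the local
#' maximum of the input (already band-passed) signal within +/- 25 ms.
#'
#' @param signal a `calibrated_signal` or list with `samples` and `fs`.
#' @param refine_ms half-width of the refinement window, ms.
#' @param edge_ms peaks closer than this to either record edge are not
#'   reported (the integration window is incomplete there).
#' @return numeric vector of R-peak times in ms (empty, with a warning,
#'   when nothing is detected).
#' @export
detect_r_peaks <- function(signal, refine_ms = 25, edge_ms = 150) {
  x <- signal$samples
  fs <- signal$fs
  n <- length(x)
  if (n < 2 * fs) pb_stop("signal shorter than 2 s", "pb_short_signal")
  if (max(abs(x)) < 1e-9) {
    warning("no R-peaks found (flat signal)")
    return(numeric(0))
  }
  bp <- bandpass_filter(x, fs, 5, 15, order = 2)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  win <- max(1L, round(0.150 * fs))
  kern <- rep(1 / win, win)
  mwi <- as.numeric(stats::filter(sq, kern, sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate local maxima of the integrated signal, >= 200 ms apart
  refr <- round(0.200 * fs)
  is_max <- c(FALSE, diff(sign(diff(mwi))) == -2, FALSE)
  cand <- which(is_max)
  if (!length(cand)) {
    warning("no R-peaks found")
    return(numeric(0))
  }
  o <- order(mwi[cand], decreasing = TRUE)
  keep <- logical(length(cand))
  taken <- integer(0)
  for (k in o) {
    if (!length(taken) || all(abs(cand[k] - taken) >= refr)) {
      keep[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  cand <- sort(cand[keep])

  # adaptive dual thresholds (SPKI/NPKI) over candidates, with search-back
  init <- mwi[seq_len(min(n, 2L * fs))]
  spki <- max(init)
  npki <- mean(init) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_avg <- NA_real_
  miss_limit <- function() if (is.na(rr_avg)) Inf else 1.66 * rr_avg
  pending <- numeric(0)
  for (i in seq_along(cand)) {
    pk <- mwi[cand[i]]
    if (pk >= thr1()) {
      qrs <- c(qrs, cand[i])
      spki <- 0.125 * pk + 0.875 * spki
      pending <- numeric(0)
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      pending <- c(pending, cand[i])
    }
    if (length(qrs) >= 2) {
      rrs <- diff(utils::tail(qrs, 9))
      rr_avg <- mean(rrs)
      # search-back: if a beat seems missed, accept the best pending
      # candidate above half threshold
      if (length(pending) &&
          (cand[i] - utils::tail(qrs, 1)) > miss_limit()) {
        ok <- pending[mwi[pending] >= 0.5 * thr1()]
        if (length(ok)) {
          best <- ok[which.max(mwi[ok])]
          qrs <- sort(c(qrs, best))
          spki <- 0.25 * mwi[best] + 0.75 * spki
          pending <- numeric(0)
        }
      }
    }
  }
  if (!length(qrs)) {
    warning("no R-peaks found")
    return(numeric(0))
  }
  # refine to local maximum of the band-passed input within +/- refine_ms
  half <- round(refine_ms / 1000 * fs)
  ref <- vapply(qrs, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, 0L)
  ref <- sort(unique(ref))
  ref <- ref[c(TRUE, diff(ref) >= refr)]
  times <- (ref - 1L) / fs * 1000
  times[times >= edge_ms & times <= (n - 1L) / fs * 1000 - edge_ms]
}

#' Physiological RR filtering
#'
#' A beat is retained iff both its preceding and following RR interval
#' lie in the physiological range (default 300--2000 ms); the first and
#' last beats lack one RR and are always dropped.
#'
#' @param r_peak_times R-peak times, ms.
#' @param rr_range allowed RR range, ms.
#' @return data.frame with `peak_time`, `rr_prev`, `rr_next` for retained
#'   beats (zero rows when none survive).
#' @export
filter_rr <- function(r_peak_times, rr_range = c(300, 2000)) {
  if (length(r_peak_times) < 3) {
    pb_stop("need at least 3 R-peaks", "pb_input_error")
  }
  r <- sort(r_peak_times)
  rr <- diff(r)
  idx <- 2:(length(r) - 1L)
  rr_prev <- rr[idx - 1L]
  rr_next <- rr[idx]
  ok <- rr_prev >= rr_range[1] & rr_prev <= rr_range[2] &
    rr_next >= rr_range[1] & rr_next <= rr_range[2]
  data.frame(peak_time = r[idx][ok], rr_prev = rr_prev[ok],
             rr_next = rr_next[ok])
}

#' Segment beats around retained R-peaks
#'
#' Extracts baseline-subtracted windows from -200 to +340 ms relative to
#' each R-peak, sample-aligned so the R-peak sits at index
#' `round(0.2 * fs) + 1`. Beats whose window falls off the record are
#' dropped.
#'
#' @param signal a `calibrated_signal`.
#' @param beats data.frame from [filter_rr()].
#' @param baseline per-beat baseline levels (mV); recycled if scalar.
#' @param window window limits relative to R, ms.
#' @return object of class `beat_set`: list with `segments` (beats x
#'   samples matrix), `t_rel` (ms relative to R), `beats` (the retained
#'   rows of `beats`), `fs`.
#' @export
segment_beats <- function(signal, beats, baseline = 0,
                          window = c(-200, 340)) {
  if (!nrow(beats)) pb_stop("no retained beats", "pb_input_error")
  fs <- signal$fs
  x <- signal$samples
  pre <- round(-window[1] / 1000 * fs)
  post <- round(window[2] / 1000 * fs)
  len <- pre + post + 1L
  baseline <- rep_len(baseline, nrow(beats))
  segs <- list(); kept <- integer(0)
  for (b in seq_len(nrow(beats))) {
    ri <- round(beats$peak_time[b] / 1000 * fs) + 1L
    lo <- ri - pre; hi <- ri + post
    if (lo < 1L || hi > length(x)) next
    segs[[length(segs) + 1L]] <- x[lo:hi] - baseline[b]
    kept <- c(kept, b)
  }
  if (!length(kept)) {
    return(structure(list(segments = matrix(0, 0, len),
                          t_rel = seq(-pre, post) / fs * 1000,
                          beats = beats[0, ], fs = fs), class = "beat_set"))
  }
  structure(list(
    segments = do.call(rbind, segs),
    t_rel = seq(-pre, post) / fs * 1000,
    beats = beats[kept, , drop = FALSE],
    fs = fs
  ), class = "beat_set")
}

# duration by 10%-of-peak crossings around an extremum inside a window
dur_at_10pct <- function(t, y, peak_idx) {
  pk <- y[peak_idx]
  if (!is.finite(pk) || abs(pk) < 1e-12) return(NA_real_)
  thr <- 0.1 * abs(pk)
  s <- sign(pk) * y
  left <- peak_idx
  while (left > 1 && s[left - 1] > thr) left <- left - 1
  right <- peak_idx
  while (right < length(s) && s[right + 1] > thr) right <- right + 1
  onset <- t[left]; offset <- t[right]
  c(dur = offset - onset, onset = onset, offset = offset)
}

signed_extremum <- function(y) {
  i <- which.max(abs(y))
  c(idx = i, val = y[i])
}

#' Morphological features for each beat in a beat set
#'
#' Measures the 17 registry features per beat relative to the (already
#' subtracted) isoelectric baseline. Windows (ms relative to R): P wave
#' -200..-60 (signed extremum), Q/R/S within -60..+60 (R = maximum,
#' Q/S = minima before/after R), ST level/slope over +60..+100, T wave
#' +120..+340 (signed extremum). Durations use 10%-of-peak crossings; QT
#' runs from Q onset to T end. Undefined durations on flat segments are
#' returned as `NA`.
#'
#' @param beat_set a `beat_set` from [segment_beats()].
#' @return data.frame, one row per beat, columns in [feature_registry()]
#'   order.
#' @export
beat_features <- function(beat_set) {
  stopifnot(inherits(beat_set, "beat_set"))
  t <- beat_set$t_rel
  segs <- beat_set$segments
  if (!nrow(segs)) pb_stop("beat set has no segments", "pb_input_error")
  win <- function(lo, hi) which(t >= lo & t <= hi)
  iP <- win(-200, -60); iQRS <- win(-60, 60)
  iST <- win(60, 100); iT <- win(120, 340)
  r_idx0 <- which.min(abs(t))
  out <- lapply(seq_len(nrow(segs)), function(b) {
    y <- segs[b, ]
    # QRS
    r_rel <- which.max(y[iQRS]); r_i <- iQRS[r_rel]
    r_amp <- y[r_i]
    pre_i <- iQRS[iQRS < r_i]; post_i <- iQRS[iQRS > r_i]
    q_amp <- if (length(pre_i)) min(y[pre_i]) else NA_real_
    s_amp <- if (length(post_i)) min(y[post_i]) else NA_real_
    q_i <- if (length(pre_i)) pre_i[which.min(y[pre_i])] else r_i
    qrs <- dur_at_10pct(t, y, r_i)
    # P wave
    pe <- signed_extremum(y[iP]); p_i <- iP[pe["idx"]]
    p_amp <- pe["val"]
    pd <- dur_at_10pct(t[iP], y[iP], as.integer(pe["idx"]))
    pr <- if (!anyNA(pd)) -pd["onset"] else NA_real_
    # ST
    st_level <- mean(y[iST])
    st_slope <- unname(stats::coef(stats::lm.fit(
      cbind(1, t[iST] / 1000), y[iST]))[2])          # mV per second
    # T wave
    te <- signed_extremum(y[iT]); t_i <- iT[te["idx"]]
    t_amp <- te["val"]
    td <- dur_at_10pct(t[iT], y[iT], as.integer(te["idx"]))
    qt <- if (!anyNA(td)) td["offset"] - t[q_i] else NA_real_
    flat <- max(abs(y)) < 1e-12
    data.frame(
      p_amp = if (flat) 0 else unname(p_amp),
      p_dur = if (flat) NA_real_ else unname(pd["dur"]),
      pr_interval = if (flat) NA_real_ else unname(pr),
      q_amp = if (flat) 0 else q_amp,
      r_amp = if (flat) 0 else r_amp,
      s_amp = if (flat) 0 else s_amp,
      qrs_dur = if (flat) NA_real_ else unname(qrs["dur"]),
      st_level = st_level,
      st_slope = st_slope,
      t_amp = if (flat) 0 else unname(t_amp),
      t_dur = if (flat) NA_real_ else unname(td["dur"]),
      qt_interval = if (flat) NA_real_ else unname(qt),
      t_peak_time = if (flat) NA_real_ else t[t_i],
      beat_rms = sqrt(mean(y^2))
    )
  })
  feat <- do.call(rbind, out)
  rr_prev <- beat_set$beats$rr_prev
  rr_next <- beat_set$beats$rr_next
  res <- cbind(
    data.frame(rr_prev = rr_prev, rr_next = rr_next,
               inst_hr = 60000 / ((rr_prev + rr_next) / 2)),
    feat
  )
  res[, feature_registry()]
}

#' Group beat templates and pointwise absolute difference
#'
#' @param beat_sets named list of `beat_set` objects (or plain segment
#'   matrices), one per group; exactly two groups for the difference.
#' @return list with per-group `mean` and `sd` matrices (rows = groups)
#'   and `abs_diff` = |mean_1(t) - mean_2(t)| (`delta` keeps the sign,
#'   group1 - group2).
#' @export
beat_template <- function(beat_sets) {
  mats <- lapply(beat_sets, function(b) {
    if (inherits(b, "beat_set")) b$segments else as.matrix(b)
  })
  if (any(vapply(mats, nrow, 0L) == 0L)) {
    pb_stop("empty group in beat_template", "pb_input_error")
  }
  means <- lapply(mats, colMeans)
  sds <- lapply(mats, function(m) apply(m, 2, stats::sd))
  sds <- lapply(sds, function(s) { s[is.na(s)] <- 0; s })
  out <- list(mean = do.call(rbind, means), sd = do.call(rbind, sds))
  if (length(mats) == 2) {
    out$delta <- means[[1]] - means[[2]]
    out$abs_diff <- abs(out$delta)
  }
  out
}

# approximate entropy, Pincus convention (self-matches included)
approx_entropy <- function(x, m = 2, r) {
  n <- length(x)
  if (n < m + 2 || r <= 0) return(NA_real_)
  phi <- function(mm) {
    nm <- n - mm + 1L
    tpl <- sapply(seq_len(mm), function(j) x[j:(j + nm - 1L)])
    tpl <- matrix(tpl, nrow = nm)
    cnt <- vapply(seq_len(nm), function(i) {
      d <- abs(sweep(tpl, 2, tpl[i, ]))
      sum(apply(d, 1, max) <= r)
    }, 0)
    mean(log(cnt / nm))
  }
  phi(m) - phi(m + 1)
}

#' Ultra-short HRV metrics
#'
#' Time-domain and Poincare/non-linear metrics from an NN-interval
#' series: MeanNN, SDNN (sample SD), RMSSD, SD1 = RMSSD/sqrt(2),
#' SD2 = sqrt(max(0, 2 * SDNN_pop^2 - SD1^2)) with SDNN_pop the
#' population SD, approximate entropy (m = 2, r = 0.2 * SDNN_pop), and
#' mean heart rate 60000/MeanNN.
#'
#' @param nn_intervals NN intervals, ms.
#' @param window optional window length in s: only intervals whose
#'   cumulative time falls inside the first `window` seconds are used
#'   (`NULL` = all).
#' @return object of class `hrv_metrics` (named list).
#' @export
hrv_metrics <- function(nn_intervals, window = NULL) {
  nn <- nn_intervals
  if (!is.null(window)) {
    keep <- cumsum(nn) <= window * 1000
    if (any(keep)) nn <- nn[keep]
  }
  if (length(nn) < 3) {
    pb_stop("fewer than 3 NN intervals in window", "pb_insufficient_data")
  }
  mean_nn <- mean(nn)
  sdnn <- stats::sd(nn)
  n <- length(nn)
  sdnn_pop <- sqrt(sum((nn - mean_nn)^2) / n)
  rmssd <- sqrt(mean(diff(nn)^2))
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(0, 2 * sdnn_pop^2 - sd1^2))
  apen <- approx_entropy(nn, m = 2, r = 0.2 * sdnn_pop)
  structure(list(
    mean_nn = mean_nn, sdnn = sdnn, rmssd = rmssd,
    sd1 = sd1, sd2 = sd2, apen = apen,
    mean_hr = 60000 / mean_nn, n_nn = n
  ), class = "hrv_metrics")
}
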