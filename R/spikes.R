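#' Detect spikes on a cell-attached trace
#'
#' High-pass filters the trace (default corner 100 Hz, removing the field
#' oscillation), then marks events where the residual crosses a robust
#' threshold of `threshold_mult` MAD-scaled standard deviations away from the
#' median. Within each supra-threshold excursion the extremum sample is taken
#' as the spike time; detections within the refractory period of a previous
#' one are suppressed. Waveform snippets (2 ms pre, 3 ms post) are cut from
#' the raw trace around each spike.
#'
#' Polarity is auto-detected as the sign of the largest absolute residual
#' excursion in the first 10 s unless given explicitly.
#'
#' @param tr A cell-attached [trace()], fs >= 5 kHz recommended.
#' @param threshold_mult Threshold in robust (MAD/0.6745) SD units; > 0.
#' @param refractory Minimum separation between detections in seconds.
#' @param polarity `"auto"`, `"positive"` or `"negative"`.
#' @param highpass High-pass corner for the detection residual (Hz).
#' @param abs_threshold Optional absolute threshold in uV overriding the
#'   robust one (Clampfit-style fixed threshold).
#' @param snippet_pre,snippet_post Snippet extent around the extremum (s).
#' @return `gp_spiketrain` with `times` (s, strictly increasing), `waveforms`
#'   (matrix, one row per spike), `fs`, `polarity`.
#' @export
detect_spikes <- function(tr, threshold_mult = 5, refractory = 1e-3,
                          polarity = c("auto", "positive", "negative"),
                          highpass = 100, abs_threshold = NULL,
                          snippet_pre = 2e-3, snippet_post = 3e-3) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(tr, "gp_trace"))
  if (threshold_mult <= 0) stop("'threshold_mult' must be positive")
  fs <- tr$fs
  hf <- signal::butter(3, highpass / (fs / 2), type = "high")
  resid <- signal::filtfilt(hf, tr$samples)
  med <- stats::median(resid)
  sigma <- stats::mad(resid)            # MAD scaled by 1/0.6745
  if (polarity == "auto") {
    head_n <- min(length(resid), round(10 * fs))
    dev <- resid[seq_len(head_n)] - med
    polarity <- if (dev[which.max(abs(dev))] >= 0) "positive" else "negative"
  }
  x <- if (polarity == "positive") resid - med else med - resid
  thr <- if (!is.null(abs_threshold)) abs_threshold else threshold_mult * sigma
  above <- x > thr
  if (!any(above)) {
    return(structure(list(times = numeric(0),
                          waveforms = matrix(numeric(0), 0, 0),
                          fs = fs, polarity = polarity, threshold = thr),
                     class = "gp_spiketrain"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_start <- starts[r$values]
  ev_end <- ends[r$values]
  peak_idx <- mapply(function(a, b) a - 1L + which.max(x[a:b]), ev_start, ev_end)
  # refractory suppression, keeping the first of any too-close pair
  keep <- logical(length(peak_idx))
  last <- -Inf
  rf <- refractory * fs
  for (i in seq_along(peak_idx)) {
    if (peak_idx[i] - last >= rf) { keep[i] <- TRUE; last <- peak_idx[i] }
  }
  peak_idx <- peak_idx[keep]
  npre <- round(snippet_pre * fs)
  npost <- round(snippet_post * fs)
  ok <- peak_idx > npre & peak_idx + npost <= length(tr$samples)
  peak_idx <- peak_idx[ok]
  wf <- t(vapply(peak_idx, function(i) tr$samples[(i - npre):(i + npost)],
                 numeric(npre + npost + 1L)))
  structure(list(times = tr$t0 + (peak_idx - 1L) / fs,
                 waveforms = wf, fs = fs, polarity = polarity,
                 threshold = thr, snippet_pre = snippet_pre,
                 snippet_post = snippet_post),
            class = "gp_spiketrain")
}

#' @export
print.gp_spiketrain <- function(x, ...) {
  cat(sprintf("<gp_spiketrain> %d spikes, polarity %s, fs %g Hz\n",
              length(x$times), x$polarity, x$fs))
  invisible(x)
}

#' Spike half-width from a waveform snippet
#'
#' Full width at half amplitude in milliseconds. Amplitude is the detection
#' extremum minus a local baseline taken as the median of the pre-extremum
#' window; the two half-amplitude crossings flanking the extremum are located
#' by linear interpolation.
#'
#' @param wf Numeric snippet with the extremum inside it (one row of
#'   `gp_spiketrain$waveforms`).
#' @param fs Sampling rate in Hz.
#' @param polarity `"positive"` or `"negative"` spike.
#' @param baseline_frac Fraction of the snippet (from its start) used for the
#'   baseline median; defaults to the 2 ms pre-window of the standard snippet.
#' @param noise_floor Minimum amplitude (uV) below which the width is
#'   undefined.
#' @return Half-width in ms.
#' @export
spike_halfwidth <- function(wf, fs, polarity = c("positive", "negative"),
                            baseline_frac = 0.4, noise_floor = 1e-9) {
  polarity <- match.arg(polarity)
  wf <- as.numeric(wf)
  if (polarity == "negative") wf <- -wf
  nb <- max(1L, floor(length(wf) * baseline_frac * 0.75))
  baseline <- stats::median(wf[seq_len(nb)])
  ipk <- which.max(wf)
  amp <- wf[ipk] - baseline
  if (!is.finite(amp) || amp <= noise_floor)
    stop("spike amplitude at or below the noise floor; half-width undefined")
  half <- baseline + amp / 2
  # walk left and right from the peak to the half crossings
  i <- ipk
  while (i > 1L && wf[i - 1L] > half) i <- i - 1L
  if (i == 1L) stop("no pre-peak half-amplitude crossing inside the snippet")
  left <- (i - 1L) + (half - wf[i - 1L]) / (wf[i] - wf[i - 1L])
  j <- ipk
  while (j < length(wf) && wf[j + 1L] > half) j <- j + 1L
  if (j == length(wf)) stop("no post-peak half-amplitude crossing inside the snippet")
  right <- j + (wf[j] - half) / (wf[j] - wf[j + 1L])
  (right - left) / fs * 1e3
}

#' Per-condition spike metrics
#'
#' For each condition annotated on the recording (baseline, drug, washout)
#' takes the first `epoch_length` seconds of the annotation and reports firing
#' rate, inter-spike intervals and per-spike half-widths within it. The
#' default 180 s matches the three-minute analysis epochs used for
#' cell-attached recordings.
#'
#' @param train A `gp_spiketrain`.
#' @param rec The annotated `gp_recording`.
#' @param epoch_length Analysis span per condition in seconds.
#' @return Data frame with one row per condition: `epoch_label`, `rate_hz`,
#'   `n_spikes`, `median_isi_ms`, `median_halfwidth_ms`, `duration_s`; the
#'   full ISI and half-width vectors are attached as list columns `isis_s`
#'   and `halfwidths_ms`.
#' @export
epoch_spike_metrics <- function(train, rec, epoch_length = 180) {
  stopifnot(inherits(train, "gp_spiketrain"), inherits(rec, "gp_recording"))
  if (!nrow(rec$epochs)) stop("recording carries no epoch annotations")
  rows <- lapply(seq_len(nrow(rec$epochs)), function(i) {
    e <- rec$epochs[i, ]
    avail <- e$end - e$start
    if (avail < epoch_length)
      warning(sprintf("epoch '%s' is %.1f s, shorter than the requested %.0f s; using available span",
                      e$label, avail, epoch_length))
    dur <- min(avail, epoch_length)
    sel <- train$times >= e$start & train$times < e$start + dur
    times <- train$times[sel]
    isis <- if (length(times) > 1L) diff(times) else numeric(0)
    hw <- numeric(0)
    if (length(times) && nrow(train$waveforms)) {
      hw <- vapply(which(sel), function(k)
        tryCatch(spike_halfwidth(train$waveforms[k, ], train$fs,
                                 polarity = train$polarity),
                 error = function(e) NA_real_), numeric(1))
      hw <- hw[is.finite(hw)]
    }
    data.frame(epoch_label = e$label,
               rate_hz = length(times) / dur,
               n_spikes = length(times),
               median_isi_ms = if (length(isis)) stats::median(isis) * 1e3 else NA_real_,
               median_halfwidth_ms = if (length(hw)) stats::median(hw) else NA_real_,
               duration_s = dur,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$isis_s <- lapply(seq_len(nrow(rec$epochs)), function(i) {
    e <- rec$epochs[i, ]
    dur <- min(e$end - e$start, epoch_length)
    t <- train$times[train$times >= e$start & train$times < e$start + dur]
    if (length(t) > 1L) diff(t) else numeric(0)
  })
  out
}

#' Detect interictal-like events in an LFP trace
#'
#' Flags spans where the rectified-signal envelope (moving average of the
#' absolute mean-subtracted signal over `smooth` seconds) stays above
#' `k_sd` robust standard deviations of the trace for at least `min_dur`
#' seconds; events separated by less than `merge_gap` are merged. These
#' criteria are configuration keys, not fixed constants.
#'
#' @param tr A filtered LFP [trace()].
#' @param k_sd Envelope threshold in robust-SD units of the trace.
#' @param min_dur Minimum event duration (s).
#' @param merge_gap Events closer than this (s) are merged.
#' @param smooth Envelope smoothing span (s).
#' @return Data frame of events: `start`, `end` (s), `peak_amplitude` (uV);
#'   zero rows for a quiescent trace.
#' @export
detect_iie <- function(tr, k_sd = 5, min_dur = 0.05, merge_gap = 0.1,
                       smooth = 0.01) {
  stopifnot(inherits(tr, "gp_trace"))
  fs <- tr$fs
  x <- tr$samples - stats::median(tr$samples)
  env <- moving_avg(abs(x), max(1L, round(smooth * fs)))
  sigma <- stats::mad(x)
  above <- env > k_sd * sigma
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      peak_amplitude = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- cbind(starts[r$values], ends[r$values])
  # merge gaps
  if (nrow(ev) > 1L) {
    merged <- list(ev[1L, ])
    for (i in 2:nrow(ev)) {
      prev <- merged[[length(merged)]]
      if ((ev[i, 1L] - prev[2L]) / fs < merge_gap)
        merged[[length(merged)]] <- c(prev[1L], ev[i, 2L])
      else merged[[length(merged) + 1L]] <- ev[i, ]
    }
    ev <- do.call(rbind, merged)
  }
  dur_ok <- (ev[, 2L] - ev[, 1L]) / fs >= min_dur
  ev <- ev[dur_ok, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  data.frame(start = tr$t0 + (ev[, 1L] - 1L) / fs,
             end = tr$t0 + (ev[, 2L] - 1L) / fs,
             peak_amplitude = apply(ev, 1L, function(ab)
               max(abs(x[ab[1L]:ab[2L]]))))
}

moving_avg <- function(x, k) {
  if (k <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
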