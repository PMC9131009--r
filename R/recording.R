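#' Sampled signal trace
#'
#' A single channel of a slice recording: a regularly sampled voltage signal in
#' microvolts with its sampling rate and a role label identifying what the
#' electrode recorded (CA3 or CA1 field potential, or a cell-attached pipette).
#'
#' @param samples Numeric vector of samples (uV). Must be finite and non-empty.
#' @param fs Sampling rate in Hz (> 0). Field recordings here are acquired at
#'   10 kHz; any positive rate is accepted.
#' @param role One of `"CA3_LFP"`, `"CA1_LFP"`, `"cell_attached"`.
#' @param t0 Time offset of the first sample in seconds (default 0; t = 0 is
#'   the start of the record).
#' @return An object of class `gp_trace`.
#' @export
trace <- function(samples, fs, role = c("CA3_LFP", "CA1_LFP", "cell_attached"),
                  t0 = 0) {
  role <- match.arg(role)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite (no NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate 'fs' must be a single positive number")
  structure(list(samples = samples, fs = fs, role = role, t0 = t0),
            class = "gp_trace")
}

#' @export
print.gp_trace <- function(x, ...) {
  cat(sprintf("<gp_trace> role=%s  fs=%g Hz  n=%d (%.3f s)  t0=%g s\n",
              x$role, x$fs, length(x$samples), length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param x A `gp_trace`.
#' @return Duration in seconds (n / fs).
#' @export
trace_duration <- function(x) length(x$samples) / x$fs

#' Multi-channel slice recording
#'
#' Bundles the simultaneously acquired channels of one slice experiment with
#' its cohort labels (genotype, age group, inducing drug) and the condition
#' epochs annotated on the record. Epoch annotations are half-open intervals
#' `[start, end)` in seconds from the start of the record.
#'
#' @param channels List of [trace()] objects. All must share one sampling rate.
#' @param subject_id Character identifier for the slice/subject.
#' @param genotype `"control"` or `"mutant"` (amyloid-pathology transgenic).
#' @param age_group `"young"` or `"old"`.
#' @param drug Gamma-inducing agonist: `"carbachol"`, `"kainate"`, or `"none"`.
#' @param epochs Data frame with columns `label` (one of `baseline`, `drug`,
#'   `washout`), `start`, `end` (seconds). May be empty. Annotations must be
#'   non-overlapping and lie within the record duration.
#' @return An object of class `gp_recording`.
#' @export
recording <- function(channels, subject_id = "slice",
                      genotype = c("control", "mutant"),
                      age_group = c("young", "old"),
                      drug = c("none", "carbachol", "kainate"),
                      epochs = NULL) {
  genotype <- match.arg(genotype)
  age_group <- match.arg(age_group)
  drug <- match.arg(drug)
  if (!is.list(channels) || length(channels) < 1L)
    stop("recording needs at least one channel")
  if (!all(vapply(channels, inherits, logical(1), "gp_trace")))
    stop("all channels must be gp_trace objects")
  fs <- vapply(channels, `[[`, numeric(1), "fs")
  if (length(unique(fs)) != 1L)
    stop("all channels must share one sampling rate")
  dur <- max(vapply(channels, trace_duration, numeric(1)))
  if (is.null(epochs)) {
    epochs <- data.frame(label = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  } else {
    epochs <- as.data.frame(epochs)
    stopifnot(all(c("label", "start", "end") %in% names(epochs)))
    if (nrow(epochs)) {
      bad <- !epochs$label %in% c("baseline", "drug", "washout")
      if (any(bad)) stop("epoch labels must be baseline/drug/washout")
      if (any(epochs$end <= epochs$start))
        stop("epoch annotations must have end > start")
      if (any(epochs$start < 0) || any(epochs$end > dur + 1e-9))
        stop("epoch annotations must lie within the record duration")
      o <- order(epochs$start)
      eo <- epochs[o, ]
      if (nrow(eo) > 1L && any(eo$start[-1L] < eo$end[-nrow(eo)] - 1e-9))
        stop("epoch annotations must not overlap")
    }
  }
  structure(list(channels = channels, subject_id = subject_id,
                 genotype = genotype, age_group = age_group, drug = drug,
                 epochs = epochs),
            class = "gp_recording")
}

#' @export
print.gp_recording <- function(x, ...) {
  cat(sprintf("<gp_recording> %s  genotype=%s  age=%s  drug=%s\n",
              x$subject_id, x$genotype, x$age_group, x$drug))
  for (ch in x$channels) print(ch)
  if (nrow(x$epochs))
    cat("epochs:", paste(sprintf("%s[%g,%g)", x$epochs$label, x$epochs$start,
                                 x$epochs$end), collapse = " "), "\n")
  invisible(x)
}

#' Fetch a channel by role
#' @param rec A `gp_recording`.
#' @param role Channel role to look up.
#' @return The matching `gp_trace`, or an error when absent.
#' @export
get_channel <- function(rec, role) {
  roles <- vapply(rec$channels, `[[`, character(1), "role")
  i <- which(roles == role)
  if (!length(i)) stop(sprintf("recording has no channel with role '%s'", role))
  rec$channels[[i[1L]]]
}

#' Analysis configuration
#'
#' Collects the analysis constants in one place with the field-standard
#' defaults: 5-120 Hz pre-filter, 10 s spectral epochs, the 20-80 Hz gamma
#' band used at interface-chamber recording temperature, the slice inclusion
#' thresholds (peak frequency strictly between 19 and 80 Hz; peak power above
#' 1 uV^2/Hz in CA3 and 0.1 uV^2/Hz in CA1), and a 60 Hz mains contamination
#' screen.
#'
#' @param filter_band Low/high corner of the analysis band-pass filter (Hz).
#' @param epoch_length Spectral epoch length in seconds.
#' @param gamma_band Band over which bandwidth power is integrated (Hz).
#' @param qc_freq_range Peak frequency must lie strictly inside this range for
#'   a slice to count as oscillating (Hz).
#' @param qc_min_power Named vector of minimum peak power by region (uV^2/Hz).
#' @param mains_freq Mains line frequency (Hz).
#' @param mains_ratio_max A slice whose mean power in `mains_freq` +/- 2 Hz
#'   exceeds this multiple of the flanking bands is discarded as contaminated.
#' @param exclude_mains_in_search Skip the mains window during the peak search.
#' @param search_band Band searched for the spectral peak (Hz).
#' @param spike_threshold_mult Spike detection threshold in robust SDs.
#' @param spike_refractory Minimum inter-spike interval enforced (s).
#' @param phase_invert Flip LFP polarity before phase extraction.
#' @param min_spikes_per_cell Cells with fewer phase-assigned spikes are
#'   excluded from population (second-order) tests.
#' @param seed Optional integer seed echoed into provenance output.
#' @param out_dir Output directory for result tables.
#' @return A list of class `gp_config`.
#' @export
analysis_config <- function(filter_band = c(5, 120),
                            epoch_length = 10,
                            gamma_band = c(20, 80),
                            qc_freq_range = c(19, 80),
                            qc_min_power = c(CA3 = 1, CA1 = 0.1),
                            mains_freq = 60,
                            mains_ratio_max = 5,
                            exclude_mains_in_search = TRUE,
                            search_band = c(5, 120),
                            spike_threshold_mult = 5,
                            spike_refractory = 1e-3,
                            phase_invert = FALSE,
                            min_spikes_per_cell = 10,
                            seed = NULL,
                            out_dir = ".") {
  chk_band <- function(b, nm) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("'%s' must be a finite (low, high) pair with low < high", nm))
  }
  chk_band(filter_band, "filter_band")
  chk_band(gamma_band, "gamma_band")
  chk_band(qc_freq_range, "qc_freq_range")
  chk_band(search_band, "search_band")
  if (epoch_length <= 0) stop("'epoch_length' must be positive")
  stopifnot(all(is.finite(qc_min_power)), is.finite(mains_freq),
            is.finite(mains_ratio_max))
  structure(list(filter_band = filter_band, epoch_length = epoch_length,
                 gamma_band = gamma_band, qc_freq_range = qc_freq_range,
                 qc_min_power = qc_min_power, mains_freq = mains_freq,
                 mains_ratio_max = mains_ratio_max,
                 exclude_mains_in_search = exclude_mains_in_search,
                 search_band = search_band,
                 spike_threshold_mult = spike_threshold_mult,
                 spike_refractory = spike_refractory,
                 phase_invert = phase_invert,
                 min_spikes_per_cell = min_spikes_per_cell,
                 seed = seed, out_dir = out_dir),
            class = "gp_config")
}

#' Cut contiguous analysis windows from a labelled epoch
#'
#' Returns non-overlapping windows of `length` seconds taken from the start of
#' the first annotation carrying `label`; a partial tail window is discarded.
#' This implements the convention of analysing the leading span of a condition
#' (e.g. the first 5 min of washout) in fixed 10 s epochs.
#'
#' @param rec A `gp_recording`.
#' @param label Epoch label to select (`baseline`, `drug`, `washout`).
#' @param length Window length in seconds.
#' @param role Channel role to window (default CA3 LFP).
#' @param max_span Optional cap in seconds on how much of the epoch is used
#'   (e.g. 300 for "first 5 min"); `Inf` uses the whole annotated span.
#' @return List of `gp_trace` windows (possibly empty, with a warning, when
#'   the span is shorter than one window).
#' @export
select_epoch <- function(rec, label, length, role = "CA3_LFP",
                         max_span = Inf) {
  stopifnot(inherits(rec, "gp_recording"), length > 0)
  e <- rec$epochs[rec$epochs$label == label, , drop = FALSE]
  if (!nrow(e))
    stop(sprintf("no epoch labelled '%s' on this recording", label))
  tr <- get_channel(rec, role)
  span_start <- e$start[1L]
  span_end <- min(e$end[1L], span_start + max_span)
  fs <- tr$fs
  i0 <- round((span_start - tr$t0) * fs) + 1L
  i1 <- min(round((span_end - tr$t0) * fs), base::length(tr$samples))
  nwin <- floor((i1 - i0 + 1L) / (length * fs))
  if (nwin < 1L) {
    warning("annotated span shorter than one window; returning no windows")
    return(list())
  }
  wlen <- round(length * fs)
  lapply(seq_len(nwin), function(k) {
    a <- i0 + (k - 1L) * wlen
    trace(tr$samples[a:(a + wlen - 1L)], fs, tr$role,
          t0 = tr$t0 + (a - 1L) / fs)
  })
}
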