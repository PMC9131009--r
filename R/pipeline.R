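#' Split a trace into fixed-length windows
#'
#' Contiguous non-overlapping windows from the start of the trace; a partial
#' tail is dropped.
#'
#' @param tr A [trace()].
#' @param length Window length in seconds.
#' @return List of `gp_trace` windows.
#' @export
split_windows <- function(tr, length) {
  stopifnot(inherits(tr, "gp_trace"), length > 0)
  wlen <- round(length * tr$fs)
  nwin <- floor(base::length(tr$samples) / wlen)
  if (nwin < 1L) {
    warning("trace shorter than one window")
    return(list())
  }
  lapply(seq_len(nwin), function(k) {
    a <- (k - 1L) * wlen + 1L
    trace(tr$samples[a:(a + wlen - 1L)], tr$fs, tr$role,
          t0 = tr$t0 + (a - 1L) / tr$fs)
  })
}

#' Per-slice gamma metrics for both regions
#'
#' Runs the spectral pipeline on one recording: band-pass filter each LFP
#' channel (5-120 Hz), cut the drug epoch into 10 s windows, estimate the
#' Welch spectrum, extract the gamma peak and bandwidth power, apply the
#' inclusion rules, and (for CA3) compute the coefficient of rhythmicity plus
#' the CA3-CA1 cross-correlation peak and delay.
#'
#' @param rec A [recording()] carrying CA3_LFP (and optionally CA1_LFP).
#' @param cfg An [analysis_config()].
#' @param epoch_label Which annotated condition to analyse (default `drug`);
#'   when the recording carries no annotations the whole record is used.
#' @param nperseg Welch segment length in samples.
#' @return Data frame with one row per region: slice/cohort labels, peak
#'   frequency (Hz), peak power (uV^2/Hz), bandwidth power (uV^2), QC verdict
#'   and reasons, Cr and cross-correlation columns (CA3 rows only).
#' @export
slice_gamma_metrics <- function(rec, cfg = analysis_config(),
                                epoch_label = "drug", nperseg = 2^14) {
  stopifnot(inherits(rec, "gp_recording"))
  roles <- vapply(rec$channels, `[[`, character(1), "role")
  regions <- intersect(c("CA3_LFP", "CA1_LFP"), roles)
  if (!length(regions)) stop("recording has no LFP channels")

  filtered <- list()
  windows <- list()
  for (role in regions) {
    tr <- bandpass(get_channel(rec, role), cfg$filter_band[1],
                   cfg$filter_band[2])
    filtered[[role]] <- tr
    windows[[role]] <- if (nrow(rec$epochs)) {
      e <- rec$epochs[rec$epochs$label == epoch_label, , drop = FALSE]
      if (!nrow(e)) stop(sprintf("no epoch labelled '%s'", epoch_label))
      i0 <- round((e$start[1] - tr$t0) * tr$fs) + 1L
      i1 <- min(round((e$end[1] - tr$t0) * tr$fs), length(tr$samples))
      split_windows(trace(tr$samples[i0:i1], tr$fs, tr$role), cfg$epoch_length)
    } else split_windows(tr, cfg$epoch_length)
  }

  rows <- lapply(regions, function(role) {
    region <- if (role == "CA3_LFP") "CA3" else "CA1"
    ps <- power_spectrum(windows[[role]], nperseg = nperseg)
    m <- gamma_metrics(ps, band = cfg$gamma_band,
                       search_band = cfg$search_band,
                       mains = cfg$mains_freq,
                       exclude_mains = cfg$exclude_mains_in_search,
                       region = region)
    m <- qc_slice(m, ps, cfg)
    cr <- NA_real_; xp <- NA_real_; xl <- NA_real_
    if (region == "CA3" && length(windows[[role]])) {
      rr <- coefficient_of_rhythmicity(
        autocorrelogram(windows[[role]][[1L]], max_lag = 0.1))
      cr <- rr$cr
      if ("CA1_LFP" %in% regions && length(windows[["CA1_LFP"]])) {
        cc <- cross_correlogram(windows[["CA3_LFP"]][[1L]],
                                windows[["CA1_LFP"]][[1L]], max_lag = 0.05)
        xp <- cc$peak_value; xl <- cc$peak_lag * 1e3
      }
    }
    data.frame(slice_id = rec$subject_id, region = region, drug = rec$drug,
               genotype = rec$genotype, age_group = rec$age_group,
               peak_frequency_hz = m$peak_frequency,
               peak_power_uv2hz = m$peak_power,
               bandwidth_power_uv2 = m$bandwidth_power,
               qc_pass = m$qc_pass,
               qc_reasons = paste(m$qc_reasons, collapse = ";"),
               cr = cr, xcorr_peak = xp, xcorr_lag_ms = xl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyse a cohort of recordings end to end
#'
#' Computes per-slice gamma metrics for every recording, then the CA1
#' participation contingency analysis (control vs mutant within each age
#' group) and a per-group power summary.
#'
#' @param recordings List of [recording()] objects (e.g. from
#'   [gen_cohort()]).
#' @param cfg An [analysis_config()].
#' @param nperseg Welch segment length in samples.
#' @return List with `slice_metrics` (data frame), `participation` (named
#'   list per age group of [participation_summary()] frames), and
#'   `group_power` (median CA3 peak power and bandwidth power per group).
#' @export
analyze_cohort <- function(recordings, cfg = analysis_config(),
                           nperseg = 2^14) {
  sm <- do.call(rbind, lapply(recordings, slice_gamma_metrics, cfg = cfg,
                              nperseg = nperseg))
  participation <- list()
  for (ag in unique(sm$age_group)) {
    sub <- sm[sm$age_group == ag, , drop = FALSE]
    if (all(c("control", "mutant") %in% sub$genotype)) {
      tab <- participation_table(sub, "genotype", "control", "mutant")
      participation[[ag]] <- participation_summary(tab)
    }
  }
  ca3 <- sm[sm$region == "CA3", , drop = FALSE]
  group_power <- stats::aggregate(
    cbind(peak_power_uv2hz, bandwidth_power_uv2) ~ genotype + age_group,
    data = ca3, FUN = stats::median)
  names(group_power)[3:4] <- c("median_peak_power_uv2hz",
                               "median_bandwidth_power_uv2")
  list(slice_metrics = sm, participation = participation,
       group_power = group_power)
}
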